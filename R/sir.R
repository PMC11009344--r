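#' Configuration for SIR immunization experiments
#'
#' @param beta Per-contact, per-step infection probability.  When `NULL`
#'   (the default), experiments use `alpha_mult` times the network's
#'   [epidemic_threshold()].
#' @param gamma Per-step recovery probability.  With `gamma = 0` the
#'   simulator uses independent-cascade semantics: an infected node gets
#'   exactly one round of infection attempts and is then removed, so every
#'   run terminates (see Details).
#' @param alpha_mult Multiplier on the epidemic threshold used when `beta`
#'   is `NULL`; 0.5 is the conventional sub-threshold setting.
#' @param reps Number of independent replicates per immunization fraction.
#' @param seed Master seed; per-replicate streams are derived from it.
#'
#' @details A literal SIR process with `gamma = 0` never removes infected
#' nodes and so never reaches the stopping condition "no infected nodes
#' left".  The independent-cascade reading --- one infection round per
#' infected node, then removal --- terminates in at most `n` steps and
#' produces the same final ever-infected set as an SI process run to
#' saturation, which is the quantity reported.
#'
#' @return An object of class `sir_config`.
#' @export
sir_config <- function(beta = NULL, gamma = 0, alpha_mult = 0.5,
                       reps = 500L, seed = 1L) {
  if (!is.null(beta)) stopifnot(beta >= 0, beta <= 1)
  stopifnot(gamma >= 0, gamma <= 1, reps >= 1)
  structure(list(beta = beta, gamma = gamma, alpha_mult = alpha_mult,
                 reps = as.integer(reps), seed = as.integer(seed)),
            class = "sir_config")
}

#' Run one SIR replicate with immunized nodes
#'
#' Simulates discrete-time SIR spread from a single seed node on a network
#' with a fixed set of immunized (permanently protected) nodes.  Updates
#' are synchronous: at each step every currently infected node attempts to
#' infect each susceptible neighbour independently with probability `beta`,
#' then recoveries are applied (all infected recover when `gamma = 0`,
#' giving independent-cascade semantics; otherwise each recovers with
#' probability `gamma`).  The run ends when no infected nodes remain.
#'
#' @param net An undirected igraph graph.
#' @param immune Character vector of immunized node labels (never change
#'   state).
#' @param config An [sir_config]; its `beta` must be set.
#' @param seed_node Label of the initially infected node, or `NULL` to
#'   draw one uniformly from the non-immune nodes.
#' @param trace Keep the S/I/R trajectory as an attribute (used by tests).
#' @return The final ever-infected fraction: number of nodes that were
#'   infected at any point (the seed included, immune nodes excluded by
#'   construction) divided by the total node count `n`.
#' @export
sir_run <- function(net, immune = character(0), config = sir_config(beta = 0.1),
                    seed_node = NULL, trace = FALSE) {
  stop_if_not_network(net)
  stopifnot(inherits(config, "sir_config"))
  beta <- config$beta
  if (is.null(beta)) stop("config$beta must be set for sir_run()")
  labels <- node_labels(net)
  n <- length(labels)
  immune <- as.character(immune)
  if (!all(immune %in% labels)) {
    stop("immune set contains unknown node(s)")
  }
  if (is.null(seed_node)) {
    candidates <- setdiff(labels, immune)
    if (length(candidates) == 0L) stop("all nodes are immunized")
    seed_node <- sample(candidates, 1L)
  }
  seed_node <- as.character(seed_node)
  if (seed_node %in% immune) stop("seed node is immunized")
  if (!seed_node %in% labels) stop("unknown seed node: ", seed_node)

  adj <- igraph::as_adj_list(net)
  # states: 0 susceptible, 1 infected, 2 removed, 3 immune
  state <- integer(n)
  state[match(immune, labels)] <- 3L
  state[match(seed_node, labels)] <- 1L
  traj <- NULL
  if (trace) traj <- list()
  repeat {
    infected <- which(state == 1L)
    if (trace) {
      traj[[length(traj) + 1L]] <- c(S = sum(state == 0L), I = length(infected),
                                     R = sum(state == 2L))
    }
    if (length(infected) == 0L) break
    # synchronous infection from the state at step start
    new_inf <- integer(0)
    for (v in infected) {
      nb <- as.integer(adj[[v]])
      sus <- nb[state[nb] == 0L]
      if (length(sus) > 0L) {
        hit <- sus[stats::runif(length(sus)) < beta]
        new_inf <- c(new_inf, hit)
      }
    }
    # recoveries applied to the nodes infected at step start
    if (config$gamma == 0) {
      state[infected] <- 2L
    } else {
      rec <- infected[stats::runif(length(infected)) < config$gamma]
      state[rec] <- 2L
    }
    state[unique(new_inf)] <- 1L
  }
  out <- sum(state == 2L) / n
  if (trace) attr(out, "trajectory") <- do.call(rbind, traj)
  out
}

#' SIR immunization experiment over a score-table ranking
#'
#' For each immunization fraction, protects the top-ranked nodes of the
#' supplied score table, then repeatedly seeds an epidemic at a uniformly
#' random non-immune node and records the final ever-infected fraction.
#' Unless `config$beta` is set explicitly, the infection probability is
#' `config$alpha_mult * epidemic_threshold(net)`.
#'
#' @param net An undirected igraph graph.
#' @param st A `score_table` ranking the nodes.
#' @param immune_fractions Fractions of top nodes to immunize, each in
#'   `[0, 1)`.
#' @param config An [sir_config].
#' @return A data frame of class `sir_result` with columns
#'   `immune_fraction`, `mean_infected_fraction`, `stderr`, `reps`.
#' @export
sir_experiment <- function(net, st, immune_fractions = c(0, 0.03),
                           config = sir_config()) {
  stop_if_not_network(net)
  stopifnot(inherits(st, "score_table"), inherits(config, "sir_config"),
            all(immune_fractions >= 0), all(immune_fractions < 1))
  beta <- if (is.null(config$beta)) {
    config$alpha_mult * epidemic_threshold(net)
  } else config$beta
  cfg <- config
  cfg$beta <- min(beta, 1)
  n <- igraph::vcount(net)
  rows <- lapply(seq_along(immune_fractions), function(fi) {
    f <- immune_fractions[fi]
    immune <- if (f > 0) top_k(st, f) else character(0)
    if (length(immune) >= n) stop("immunization fraction leaves no seed candidates")
    finals <- vapply(seq_len(cfg$reps), function(r) {
      with_seed(derive_seed(cfg$seed, fi * 100003L + r),
                sir_run(net, immune, cfg))
    }, numeric(1L))
    data.frame(immune_fraction = f,
               mean_infected_fraction = mean(finals),
               stderr = stats::sd(finals) / sqrt(length(finals)),
               reps = cfg$reps)
  })
  structure(do.call(rbind, rows), beta = cfg$beta,
            class = c("sir_result", "data.frame"))
}
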
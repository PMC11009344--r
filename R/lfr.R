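#' Generate an LFR-style benchmark graph with planted communities
#'
#' Generates a synthetic network in the spirit of the LFR benchmark
#' (Lancichinetti, Fortunato and Radicchi): node degrees follow a truncated
#' discrete power law with exponent `gamma`, community sizes follow a
#' truncated power law with exponent `beta`, and each node places a
#' fraction `mu` of its edges outside its own community (the mixing
#' parameter).  Small `mu` yields pronounced, high-modularity community
#' structure; `mu` near 1 destroys it.
#'
#' The construction samples degrees and community sizes, assigns nodes to
#' communities so that each node's internal degree fits its community,
#' wires each community internally as a uniform simple graph with the exact
#' internal degree sequence (falling back to configuration-model pairing
#' when a sequence is not graphical), pairs external stubs across
#' communities, and repairs residual pairing collisions.  A small number of
#' stubs can remain unmatched, so realized degrees may fall marginally
#' below their targets.  Identical seeds reproduce identical graphs.
#'
#' @param n Number of nodes.
#' @param avg_deg Target average degree.
#' @param max_deg Maximum degree.
#' @param mu Mixing parameter in `[0, 1]`: fraction of each node's edges
#'   leaving its community.
#' @param gamma Degree power-law exponent (conventionally 2--3).
#' @param beta Community-size power-law exponent.
#' @param cmin,cmax Minimum and maximum community size.
#' @param seed Integer seed; identical seeds give identical realizations.
#' @param max_tries Bounded retries for the stochastic assignment stages.
#' @return A list with components `network` (igraph graph, nodes named
#'   `"1"` to `"n"`) and `partition` (the planted [community_partition]).
#' @examples
#' lfr <- generate_lfr(n = 120, avg_deg = 8, max_deg = 30, mu = 0.1,
#'                     gamma = 3, beta = 2, cmin = 10, cmax = 50, seed = 1)
#' igraph::vcount(lfr$network)
#' @export
generate_lfr <- function(n, avg_deg, max_deg, mu, gamma = 3, beta = 2,
                         cmin, cmax, seed = 1L, max_tries = 200L) {
  if (mu < 0 || mu > 1) stop("mu must lie in [0, 1]")
  if (!(cmin <= cmax && cmax <= n)) stop("need cmin <= cmax <= n")
  if (avg_deg > max_deg) stop("need avg_deg <= max_deg")
  with_seed(seed, {
    for (try in seq_len(max_tries)) {
      g <- try_lfr_once(n, avg_deg, max_deg, mu, gamma, beta, cmin, cmax)
      if (!is.null(g)) return(g)
    }
    stop(sprintf(
      "LFR generation did not converge (n=%d, avg_deg=%g, max_deg=%d, mu=%g, gamma=%g, beta=%g, cmin=%d, cmax=%d)",
      n, avg_deg, max_deg, mu, gamma, beta, cmin, cmax))
  })
}

try_lfr_once <- function(n, avg_deg, max_deg, mu, gamma, beta, cmin, cmax) {
  deg <- sample_powerlaw_degrees(n, gamma, avg_deg, max_deg)
  sizes <- sample_community_sizes(n, beta, cmin, cmax)
  if (is.null(sizes)) return(NULL)
  d_int <- round((1 - mu) * deg)
  assign <- assign_communities(d_int, sizes)
  if (is.null(assign)) return(NULL)

  # Internal edges wired per community as a simple graph with the exact
  # internal degree sequence where that sequence is graphical; otherwise
  # configuration-model pairing with collisions dropped.
  edges_from <- integer(0)
  edges_to <- integer(0)
  d_int_real <- d_int
  for (c_id in seq_along(sizes)) {
    members <- which(assign == c_id)
    stubs_per <- d_int_real[members]
    if (sum(stubs_per) %% 2L == 1L) {
      # drop one internal stub (it becomes external) to restore parity
      j <- members[which.max(stubs_per)]
      d_int_real[j] <- d_int_real[j] - 1L
      stubs_per <- d_int_real[members]
    }
    if (sum(stubs_per) == 0L) next
    sub <- if (igraph::is_graphical(stubs_per)) {
      tryCatch(
        igraph::sample_degseq(stubs_per, method = "edge.switching.simple"),
        error = function(e) NULL)
    } else NULL
    if (!is.null(sub)) {
      el <- igraph::as_edgelist(sub, names = FALSE)
      edges_from <- c(edges_from, members[el[, 1L]])
      edges_to <- c(edges_to, members[el[, 2L]])
    } else {
      stubs <- sample(rep(members, stubs_per))
      half <- length(stubs) / 2L
      edges_from <- c(edges_from, stubs[seq_len(half)])
      edges_to <- c(edges_to, stubs[half + seq_len(half)])
    }
  }

  # External stubs wired across communities; within-community pairs are
  # re-shuffled a bounded number of times, remaining collisions dropped.
  d_ext <- deg - d_int_real
  if (sum(d_ext) %% 2L == 1L) {
    j <- which.max(d_ext)
    d_ext[j] <- d_ext[j] - 1L
  }
  stubs <- sample(rep(seq_len(n), d_ext))
  if (length(stubs) >= 2L) {
    half <- length(stubs) / 2L
    a <- stubs[seq_len(half)]
    b <- stubs[half + seq_len(half)]
    for (pass in 1:50) {
      same <- assign[a] == assign[b]
      if (!any(same)) break
      k <- which(same)
      if (length(k) < 2L) break
      b[k] <- b[sample(k)]
    }
    ok <- assign[a] != assign[b]
    edges_from <- c(edges_from, a[ok])
    edges_to <- c(edges_to, b[ok])
  }

  g <- igraph::graph_from_edgelist(cbind(edges_from, edges_to),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  g <- igraph::simplify(g)
  g <- repair_degree_deficit(g, deg, assign)
  igraph::V(g)$name <- as.character(seq_len(n))
  membership <- stats::setNames(as.character(assign), as.character(seq_len(n)))
  list(network = g, partition = community_partition(membership))
}

# Pair leftover degree deficits across communities (stubs lost to pairing
# collisions), avoiding existing edges; a few rounds, remainder dropped.
repair_degree_deficit <- function(g, deg, assign) {
  for (round in 1:20) {
    deficit <- pmax(deg - igraph::degree(g), 0L)
    stubs <- rep(seq_along(deg), deficit)
    if (length(stubs) < 2L) break
    stubs <- sample(stubs)
    half <- floor(length(stubs) / 2L)
    a <- stubs[seq_len(half)]
    b <- stubs[half + seq_len(half)]
    keep <- assign[a] != assign[b] & a != b
    if (!any(keep)) break
    cand <- unique(cbind(pmin(a[keep], b[keep]), pmax(a[keep], b[keep])))
    new <- cand[!apply(cand, 1L, function(p)
      igraph::are_adjacent(g, p[1L], p[2L])), , drop = FALSE]
    if (nrow(new) == 0L) break
    # respect per-node deficit when the same node appears in several pairs
    take <- logical(nrow(new))
    left <- deficit
    for (i in seq_len(nrow(new))) {
      u <- new[i, 1L]; v <- new[i, 2L]
      if (left[u] > 0L && left[v] > 0L) {
        take[i] <- TRUE
        left[u] <- left[u] - 1L
        left[v] <- left[v] - 1L
      }
    }
    if (!any(take)) break
    g <- igraph::add_edges(g, t(new[take, , drop = FALSE]))
  }
  igraph::simplify(g)
}

# Truncated discrete power law P(k) ~ k^-gamma on [kmin, kmax], kmin chosen
# (probabilistically mixed between two integers) so the expectation matches
# avg_deg.  Degree sum is forced even.
sample_powerlaw_degrees <- function(n, gamma, avg_deg, max_deg) {
  mean_for_kmin <- function(kmin) {
    k <- kmin:max_deg
    w <- k^(-gamma)
    sum(k * w) / sum(w)
  }
  means <- vapply(1:max_deg, mean_for_kmin, numeric(1))
  k0 <- findInterval(avg_deg, means)   # means increase with kmin
  if (k0 < 1L) k0 <- 1L
  if (k0 >= max_deg) k0 <- max_deg - 1L
  # mix kmin = k0 and k0 + 1 to hit avg_deg in expectation
  w_hi <- (avg_deg - means[k0]) / (means[k0 + 1L] - means[k0])
  w_hi <- min(max(w_hi, 0), 1)
  kmin <- k0 + (stats::runif(n) < w_hi)
  deg <- vapply(kmin, function(km) {
    k <- km:max_deg
    p <- k^(-gamma)
    sample(k, 1L, prob = p)
  }, numeric(1))
  deg <- as.integer(deg)
  if (sum(deg) %% 2L == 1L) {
    j <- sample.int(n, 1L)
    deg[j] <- deg[j] + if (deg[j] < max_deg) 1L else -1L
  }
  deg
}

# Community sizes from a truncated power law, resized so they sum to n.
sample_community_sizes <- function(n, beta, cmin, cmax) {
  k <- cmin:cmax
  p <- k^(-beta)
  sizes <- integer(0)
  while (sum(sizes) < n) {
    sizes <- c(sizes, sample(k, 1L, prob = p))
  }
  excess <- sum(sizes) - n
  last <- sizes[length(sizes)] - excess
  if (last >= cmin) {
    sizes[length(sizes)] <- last
  } else {
    # fold the undersized remainder into earlier communities if possible
    sizes <- sizes[-length(sizes)]
    short <- n - sum(sizes)
    room <- cmax - sizes
    if (sum(room) < short) return(NULL)
    while (short > 0L) {
      i <- which(room > 0L)[1L]
      add <- min(short, room[i])
      sizes[i] <- sizes[i] + add
      room[i] <- room[i] - add
      short <- short - add
    }
  }
  if (length(sizes) == 0L || any(sizes < cmin | sizes > cmax)) return(NULL)
  sizes
}

# Random assignment of nodes to communities honouring capacity and the
# constraint that a node's internal degree fits its community.
assign_communities <- function(d_int, sizes) {
  n <- length(d_int)
  assign <- integer(n)
  room <- sizes
  for (i in order(d_int, decreasing = TRUE)) {
    ok <- which(room > 0L & sizes - 1L >= d_int[i])
    if (length(ok) == 0L) return(NULL)
    c_id <- if (length(ok) == 1L) ok else sample(ok, 1L, prob = room[ok])
    assign[i] <- c_id
    room[c_id] <- room[c_id] - 1L
  }
  assign
}
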
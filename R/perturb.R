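#' Edge perturbation schemes
#'
#' Describes a random modification of a network's edge set, emulating noise
#' and inaccuracies in empirically measured networks: `"delete"` removes a
#' proportion of existing edges, `"add"` inserts currently absent pairs,
#' and `"mixed"` does both, splitting the change budget evenly.
#'
#' @param mode One of `"delete"`, `"add"`, `"mixed"`.
#' @param fraction Proportion of the edge count `m` affected, in `[0, 1]`.
#' @param seed Integer seed for the random choice of edges.
#' @return An object of class `perturbation_scheme`.
#' @seealso [perturb_edges()]
#' @export
perturbation_scheme <- function(mode = c("delete", "add", "mixed"),
                                fraction, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(fraction), length(fraction) == 1L,
            fraction >= 0, fraction <= 1)
  structure(list(mode = mode, fraction = fraction, seed = as.integer(seed)),
            class = "perturbation_scheme")
}

# round-half-away-from-zero, with a floor of one change when fraction > 0
round_count <- function(x, floor_one) {
  k <- floor(x + 0.5)
  if (floor_one && k < 1) k <- 1
  as.integer(k)
}

#' Randomly perturb the edges of a network
#'
#' Applies a [perturbation_scheme]: `"delete"` removes
#' `round(fraction * m)` uniformly chosen edges, `"add"` inserts
#' `round(fraction * m)` uniformly chosen absent (non-loop) pairs, and
#' `"mixed"` deletes and adds `round(fraction * m / 2)` each so the total
#' change is about `fraction * m`.  Rounding is half-away-from-zero with a
#' floor of one change when `fraction > 0`.  For `"mixed"` the added pairs
#' are drawn from pairs absent in the *original* graph, so an edge is never
#' deleted and immediately re-inserted.  The input graph is not modified.
#'
#' @param net An undirected igraph graph.
#' @param scheme A [perturbation_scheme].
#' @return A perturbed copy of `net` (same vertex set).
#' @export
perturb_edges <- function(net, scheme) {
  stop_if_not_network(net)
  stopifnot(inherits(scheme, "perturbation_scheme"))
  m <- igraph::ecount(net)
  n <- igraph::vcount(net)
  if (scheme$fraction == 0 || m == 0L) {
    return(net)
  }
  with_seed(scheme$seed, {
    g <- net
    if (scheme$mode == "delete") {
      k <- min(round_count(scheme$fraction * m, TRUE), m)
      g <- igraph::delete_edges(g, sample.int(m, k))
    } else if (scheme$mode == "add") {
      k <- round_count(scheme$fraction * m, TRUE)
      g <- add_absent_edges(g, k)
    } else {
      k <- round_count(scheme$fraction * m / 2, TRUE)
      pairs <- absent_pairs_sample(net, k)      # sampled before deletion
      g <- igraph::delete_edges(g, sample.int(m, min(k, m)))
      g <- igraph::add_edges(g, t(pairs))
    }
    g
  })
}

# Insert k uniformly chosen absent non-loop pairs into g.
add_absent_edges <- function(g, k) {
  pairs <- absent_pairs_sample(g, k)
  igraph::add_edges(g, t(pairs))
}

# Sample k distinct vertex pairs absent from g, by index.  Errors when the
# complement of the edge set is too small.
absent_pairs_sample <- function(g, k) {
  n <- igraph::vcount(g)
  m <- igraph::ecount(g)
  capacity <- n * (n - 1) / 2 - m
  if (k > capacity) {
    stop("cannot add ", k, " edges: only ", capacity,
         " absent pairs available")
  }
  chosen <- matrix(integer(0), ncol = 2)
  seen <- character(0)
  while (nrow(chosen) < k) {
    u <- sample.int(n, 1L)
    v <- sample.int(n, 1L)
    if (u == v) next
    a <- min(u, v); b <- max(u, v)
    key <- paste(a, b)
    if (key %in% seen) next
    if (igraph::are_adjacent(g, a, b)) next
    chosen <- rbind(chosen, c(a, b))
    seen <- c(seen, key)
  }
  chosen
}
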
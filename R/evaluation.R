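#' Largest connected subgraph size (LCSS)
#'
#' Size of the largest connected component divided by the *original* node
#' count: \eqn{LCSS = n_{max} / n}.  Keeping the denominator fixed at the
#' pre-attack network size makes attack curves comparable across removal
#' fractions and guarantees monotonicity.
#'
#' @param net The (possibly truncated) network.
#' @param original_n Node count of the network before any removals.
#' @return A value in `[0, 1]`; 0 for an empty graph.
#' @export
lcss <- function(net, original_n) {
  stop_if_not_network(net)
  stopifnot(original_n >= 1)
  if (igraph::vcount(net) > original_n) {
    stop("original_n (", original_n, ") is smaller than the current node count")
  }
  if (igraph::vcount(net) == 0L) return(0)
  max(igraph::components(net)$csize) / original_n
}

#' Network efficiency
#'
#' Mean reciprocal geodesic distance over ordered node pairs,
#' \deqn{NE(G) = \frac{1}{n(n-1)} \sum_{i \ne j} \frac{1}{l_{ij}},}
#' with unreachable pairs contributing 0.  Lies in `[0, 1]` and equals 1
#' exactly for a complete graph.
#'
#' @param net An undirected igraph graph with at least two nodes.
#' @return A single numeric value.
#' @examples
#' network_efficiency(toy_network())
#' @export
network_efficiency <- function(net) {
  stop_if_not_network(net)
  n <- igraph::vcount(net)
  if (n < 2L) stop("network efficiency requires at least two nodes")
  d <- igraph::distances(net, weights = NA)
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

#' Static targeted-attack curve
#'
#' Ranks nodes once on the intact graph by the supplied score table and,
#' for each removal fraction `p`, deletes the top `ceiling(p * n)` nodes of
#' that fixed ranking, recording the LCSS (against the original `n`) and
#' the network efficiency of the remainder.  The ranking is static --- it
#' is not recomputed as nodes disappear --- so the curve is deterministic
#' given the score table.
#'
#' @param net An undirected igraph graph.
#' @param st A `score_table` on `net`.
#' @param fractions Increasing removal fractions in `[0, 1]`.
#' @return A data frame of class `attack_curve` with columns `metric`, `p`,
#'   `lcss`, `ne`.
#' @examples
#' attack_curve(toy_network(), don(toy_network()), c(0, 0.2, 0.5))
#' @export
attack_curve <- function(net, st, fractions = seq(0, 1, by = 0.05)) {
  stop_if_not_network(net)
  stopifnot(inherits(st, "score_table"),
            all(diff(fractions) > 0), all(fractions >= 0), all(fractions <= 1))
  n <- igraph::vcount(net)
  ranking <- top_k(st, 1)
  rows <- lapply(fractions, function(p) {
    k <- as.integer(ceiling(p * n))
    g <- if (k > 0L) {
      igraph::delete_vertices(net, ranking[seq_len(k)])
    } else net
    data.frame(
      metric = attr(st, "metric"), p = p,
      lcss = lcss(g, n),
      ne = if (igraph::vcount(g) < 2L) 0 else network_efficiency(g))
  })
  structure(do.call(rbind, rows),
            class = c("attack_curve", "data.frame"))
}

#' Overlap (Jaccard) coefficient of two node sets
#'
#' \eqn{p = |A \cap B| / |A \cup B|}: 1 for identical sets, 0 for disjoint
#' ones; symmetric in its arguments.
#'
#' @param a,b Character vectors of node labels (at least one non-empty).
#' @return A value in `[0, 1]`.
#' @export
overlap <- function(a, b) {
  a <- unique(as.character(a))
  b <- unique(as.character(b))
  if (length(a) == 0L && length(b) == 0L) {
    stop("overlap of two empty sets is undefined")
  }
  length(intersect(a, b)) / length(union(a, b))
}

#' Degree-based epidemic threshold
#'
#' The SIR outbreak threshold estimated from the degree distribution,
#' \eqn{\beta_{th} = \langle k \rangle / (\langle k^2 \rangle - \langle k
#' \rangle)}.  Immunization experiments conventionally run at a fixed
#' multiple of this threshold.
#'
#' @param net An undirected igraph graph.
#' @return A positive numeric value.
#' @examples
#' epidemic_threshold(toy_network())
#' @export
epidemic_threshold <- function(net) {
  stop_if_not_network(net)
  k <- igraph::degree(net)
  m1 <- mean(k)
  m2 <- mean(k^2)
  if (m2 <= m1) {
    stop("epidemic threshold undefined: <k^2> <= <k> (degrees too small)")
  }
  m1 / (m2 - m1)
}

#' Stability of a ranking under random edge perturbation
#'
#' Measures how robust a metric's top-`top_fraction` node set is to noise
#' in the edge data: for each perturbation fraction, the network is
#' independently perturbed `reps` times (see [perturb_edges()]), the metric
#' is recomputed --- with communities re-detected on the perturbed graph
#' for partition-based metrics --- and the Jaccard overlap between the
#' original and perturbed top sets is averaged.
#'
#' @param net An undirected igraph graph.
#' @param metric Metric name (see [top_k()] and the `compute` CLI) or a
#'   function `(net, part) -> score_table`.
#' @param mode Perturbation mode: `"delete"`, `"add"` or `"mixed"`.
#' @param fractions Perturbation fractions (proportion of `m` changed).
#' @param top_fraction Fraction of top nodes compared (default 3%).
#' @param reps Replicates per fraction.
#' @param seed Master seed; per-replicate seeds are derived from it.
#' @return A data frame with columns `fraction`, `mean_overlap`.
#' @export
stability_experiment <- function(net, metric, mode = "delete",
                                 fractions = c(0.01, 0.05, 0.1),
                                 top_fraction = 0.03, reps = 10L,
                                 seed = 1L) {
  stop_if_not_network(net)
  stopifnot(reps >= 1)
  fn <- resolve_metric(metric)
  part0 <- if (needs_partition(metric)) detect_communities(net, seed) else NULL
  base_top <- top_k(fn(net, part0), top_fraction)
  rows <- lapply(seq_along(fractions), function(fi) {
    f <- fractions[fi]
    if (f == 0) {
      return(data.frame(fraction = 0, mean_overlap = 1))
    }
    ov <- vapply(seq_len(reps), function(r) {
      s <- derive_seed(seed, fi * 1000L + r)
      pert <- perturb_edges(net, perturbation_scheme(mode, f, seed = s))
      part <- if (needs_partition(metric)) {
        detect_communities(pert, derive_seed(s, 1L))
      } else NULL
      overlap(base_top, top_k(fn(pert, part), top_fraction))
    }, numeric(1L))
    data.frame(fraction = f, mean_overlap = mean(ov))
  })
  do.call(rbind, rows)
}

# Derive a bounded child seed from a master seed (kept below 2^31).
derive_seed <- function(seed, idx) {
  as.integer((as.numeric(seed) * 48271 + idx) %% 2147483647)
}
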
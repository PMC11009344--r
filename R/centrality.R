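#' Score tables
#'
#' All centrality metrics in the package return a *score table*: a data
#' frame with columns `node` and `score`, one row per network node, carrying
#' the metric name and the parameters used (partition provenance, seeds) as
#' attributes.  [top_k()] extracts a deterministic head of the ranking.
#'
#' @param metric Metric name.
#' @param scores Named numeric vector (names are node labels).
#' @param provenance List of parameters relevant for reproducing the
#'   scores.
#' @return A data frame of class `score_table`.
#' @keywords internal
score_table <- function(metric, scores, provenance = list()) {
  stopifnot(!is.null(names(scores)), all(is.finite(scores)))
  structure(
    data.frame(node = names(scores), score = unname(scores),
               row.names = NULL, stringsAsFactors = FALSE),
    metric = metric, provenance = provenance,
    class = c("score_table", "data.frame"))
}

#' @export
print.score_table <- function(x, n = 6L, ...) {
  cat(sprintf("<score_table: %s, %d nodes>\n", attr(x, "metric"), nrow(x)))
  print.data.frame(utils::head(x[order(-x$score, x$node), ], n),
                   row.names = FALSE)
  if (nrow(x) > n) cat("...\n")
  invisible(x)
}

#' Disassortativity of node (DoN)
#'
#' Counts, for each node, the neighbours whose degree does not exceed the
#' node's own degree:
#' \deqn{DoN_i = \sum_{j \in N_i} f(D_i - D_j), \qquad
#'   f(x) = 1 \text{ if } x \ge 0, \text{ else } 0.}
#' The score is integer-valued with \eqn{0 \le DoN_i \le D_i}: a node
#' scoring its full degree locally dominates all of its neighbourhood
#' (a star-like pattern), while a score of 0 marks a node all of whose
#' neighbours are better connected.  Ties in degree count in the node's
#' favour, so on a k-regular graph every node scores k.
#'
#' @param net An undirected igraph graph.
#' @return A `score_table`.
#' @examples
#' don(toy_network())
#' @export
don <- function(net) {
  stop_if_not_network(net)
  deg <- igraph::degree(net)
  adj <- igraph::as_adj_list(net)
  scores <- vapply(seq_along(adj), function(i) {
    sum(deg[as.integer(adj[[i]])] <= deg[[i]])
  }, numeric(1L))
  names(scores) <- node_labels(net)
  score_table("don", scores)
}

#' mDC: influence from disassortativity and community structure
#'
#' Blends the local disassortativity score with the community boundary
#' popularity, weighting by the node's community coefficient:
#' \deqn{mDC(i) = (1 - \alpha_i)\, DoN_i + \alpha_i\, f_c(i).}
#' In partitions with clear, closed communities (\eqn{\alpha_i} near 1) the
#' boundary term dominates; in well-mixed partitions (\eqn{\alpha_i} near
#' 0) the metric falls back towards pure DoN.
#'
#' When the partition is one single community every \eqn{\alpha_i} is 1 and
#' every \eqn{f_c} is 0, so all scores collapse to zero; a warning is
#' emitted, and `fallback_don = TRUE` returns the DoN scores instead.
#'
#' @param net An undirected igraph graph.
#' @param part A [community_partition] covering `net`.
#' @param fallback_don Return DoN scores when the partition is degenerate
#'   (a single community)?
#' @return A `score_table`.
#' @examples
#' mdc(toy_network(), toy_partition())
#' @export
mdc <- function(net, part, fallback_don = FALSE) {
  mem <- membership_for(net, part)
  if (length(unique(mem)) == 1L) {
    warning("partition has a single community: all mDC scores are 0",
            if (fallback_don) "; falling back to DoN" else "")
    if (fallback_don) return(don(net))
  }
  dt <- don(net)
  alpha <- community_coefficient(community_edge_sets(net, part))
  fc <- boundary_popularity(net, part)
  a <- alpha[mem[dt$node]]
  scores <- (1 - a) * dt$score + a * fc$f_c[match(dt$node, fc$node)]
  names(scores) <- dt$node
  score_table("mdc", scores,
              provenance = list(communities = length(part$communities)))
}

#' Degree centrality
#'
#' \eqn{D(i) = d_i / (n - 1)}.
#'
#' @param net An undirected igraph graph with at least two nodes.
#' @return A `score_table`.
#' @export
degree_centrality <- function(net) {
  stop_if_not_network(net)
  n <- igraph::vcount(net)
  if (n < 2L) stop("degree centrality requires at least two nodes")
  scores <- igraph::degree(net) / (n - 1)
  names(scores) <- node_labels(net)
  score_table("dc", scores)
}

#' Shortest-path betweenness centrality
#'
#' Fraction of geodesics passing through each node, summed over unordered
#' node pairs excluding the node itself; unreachable pairs contribute 0.
#'
#' @param net An undirected igraph graph.
#' @return A `score_table`.
#' @export
betweenness_centrality <- function(net) {
  stop_if_not_network(net)
  scores <- igraph::betweenness(net, directed = FALSE, weights = NA)
  names(scores) <- node_labels(net)
  score_table("bc", scores)
}

#' Closeness as the sum of reciprocal distances
#'
#' \eqn{CC(i) = \sum_{j \ne i} 1 / d_{ji}} with unreachable pairs
#' contributing 0.  This is the reciprocal-distance (harmonic) form rather
#' than the classical inverse-mean-distance closeness; the harmonic form is
#' well defined on disconnected graphs, which the classical form is not.
#'
#' @param net An undirected igraph graph.
#' @return A `score_table`.
#' @export
closeness_as_printed <- function(net) {
  stop_if_not_network(net)
  scores <- igraph::harmonic_centrality(net, mode = "all", weights = NA,
                                        normalized = FALSE)
  names(scores) <- node_labels(net)
  score_table("cc", scores)
}

#' Modularity vitality
#'
#' \eqn{MV(i) = Q(G) - Q(G \setminus \{i\})}: the drop in partition
#' modularity when node \eqn{i} is deleted.  The partition is held fixed
#' under deletion (the node is simply removed from its community); if
#' removing a node leaves the graph without edges, \eqn{Q(G \setminus
#' \{i\})} is defined as 0.  Scores are signed; `absolute = TRUE` returns
#' magnitudes, for use with ranking conventions that treat large negative
#' vitality as importance.
#'
#' @param net An undirected igraph graph with at least one edge.
#' @param part A [community_partition] covering `net`.
#' @param absolute Rank by magnitude instead of signed value?
#' @return A `score_table`.
#' @export
modularity_vitality <- function(net, part, absolute = FALSE) {
  mem <- membership_for(net, part)
  if (igraph::ecount(net) < 1L) stop("modularity undefined for an empty edge set")
  q0 <- igraph::modularity(net, as.integer(factor(mem)))
  labels <- node_labels(net)
  codes <- as.integer(factor(mem))
  scores <- vapply(seq_along(labels), function(vi) {
    g2 <- igraph::delete_vertices(net, vi)
    q1 <- if (igraph::ecount(g2) < 1L) 0 else
      igraph::modularity(g2, codes[-vi])
    q0 - q1
  }, numeric(1L))
  if (absolute) scores <- abs(scores)
  names(scores) <- labels
  score_table("mv", scores, provenance = list(absolute = absolute))
}

#' Community hub-bridge centrality
#'
#' \eqn{CHB(i) = |C_k| \, d^{in}_i + \beta_{NNC}(i) \, d^{out}_i}, where
#' \eqn{|C_k|} is the size of the node's community and
#' \eqn{\beta_{NNC}(i)} is the number of distinct other communities found
#' among the node's neighbours (communities reachable within one hop).
#' The first term favours hubs of large communities, the second bridge
#' nodes touching many communities.
#'
#' @inheritParams modularity_vitality
#' @return A `score_table`.
#' @export
community_hub_bridge <- function(net, part) {
  mem <- membership_for(net, part)
  labels <- node_labels(net)
  dd <- internal_external_degree(net, part)
  adj <- igraph::as_adj_list(net)
  beta_nnc <- vapply(seq_along(labels), function(vi) {
    nb <- labels[as.integer(adj[[vi]])]
    length(setdiff(unique(mem[nb]), mem[[labels[vi]]]))
  }, numeric(1L))
  csize <- part$sizes[mem[labels]]
  scores <- unlist(csize) * dd$d_in + beta_nnc * dd$d_out
  names(scores) <- labels
  score_table("chb", scores)
}

#' Community-based mediator centrality
#'
#' Weights each node's normalized degree by the entropy of its
#' internal/external connection mix:
#' \deqn{CBM(i) = H_i \frac{d_i}{\sum_j d_j}, \qquad
#'   H_i = -\rho^{in}_i \ln \rho^{in}_i - \rho^{out}_i \ln \rho^{out}_i,}
#' with \eqn{\rho^{in}_i = d^{in}_i / d_i}, \eqn{\rho^{out}_i = d^{out}_i /
#' d_i} and \eqn{0 \ln 0 = 0}.  Nodes whose edges are all internal (or all
#' external) have zero entropy and score 0; isolated nodes score 0.  The
#' logarithm base only rescales all scores, leaving rankings unchanged;
#' natural logarithms are used.
#'
#' @inheritParams modularity_vitality
#' @return A `score_table`.
#' @export
community_based_mediator <- function(net, part) {
  mem <- membership_for(net, part)
  dd <- internal_external_degree(net, part)
  d <- dd$d_in + dd$d_out
  m2 <- sum(d)
  xlx <- function(p) ifelse(p > 0, -p * log(p), 0)
  h <- ifelse(d > 0, xlx(dd$d_in / pmax(d, 1)) + xlx(dd$d_out / pmax(d, 1)), 0)
  scores <- ifelse(d > 0, h * d / m2, 0)
  names(scores) <- dd$node
  score_table("cbm", scores)
}

#' Deterministic top-k extraction from a score table
#'
#' Returns the `ceiling(fraction * n)` highest-scoring nodes, sorted by
#' score descending with ties broken by ascending node label (plain string
#' comparison), so the result is reproducible across platforms and runs.
#'
#' @param st A `score_table`.
#' @param fraction Fraction of nodes to keep, in `(0, 1]`.
#' @return Character vector of node labels.
#' @examples
#' top_k(don(toy_network()), 0.1)
#' @export
top_k <- function(st, fraction) {
  stopifnot(inherits(st, "score_table"),
            is.numeric(fraction), length(fraction) == 1L,
            fraction > 0, fraction <= 1)
  k <- as.integer(ceiling(fraction * nrow(st)))
  ord <- order(-st$score, st$node, method = "radix")
  st$node[ord][seq_len(k)]
}

# Registry used by experiments and the CLI: metric name -> function of
# (net, part).  Partition-free metrics ignore `part`.
metric_registry <- function() {
  list(
    don = function(net, part) don(net),
    mdc = function(net, part) mdc(net, part),
    dc  = function(net, part) degree_centrality(net),
    bc  = function(net, part) betweenness_centrality(net),
    cc  = function(net, part) closeness_as_printed(net),
    mv  = function(net, part) modularity_vitality(net, part),
    chb = function(net, part) community_hub_bridge(net, part),
    cbm = function(net, part) community_based_mediator(net, part)
  )
}

# Resolve a metric given by name, checking whether it needs a partition.
resolve_metric <- function(metric) {
  reg <- metric_registry()
  if (is.function(metric)) return(metric)
  if (!metric %in% names(reg)) {
    stop("unknown metric '", metric, "'; available: ",
         paste(names(reg), collapse = ", "))
  }
  reg[[metric]]
}

needs_partition <- function(metric) {
  is.character(metric) && metric %in% c("mdc", "mv", "chb", "cbm")
}
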
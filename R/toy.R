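#' The 17-node demonstration network
#'
#' A small two-community network used throughout the package documentation
#' and tests to illustrate the disassortativity score and the mDC metric.
#' Community `C1` contains nodes 1--7, community `C2` contains nodes 8--17;
#' node 8 is the hub of `C2` and node 2 is a boundary node of `C1` whose
#' removal disturbs inter-community reachability more than the removal of
#' much better-connected nodes.
#'
#' The wiring is reconstructed from the published drawing of this network
#' so that the reported node degrees, the disassortativity scores of the
#' discussed nodes (11, 12, 13 and 16), and the network efficiencies after
#' deleting node 13 (0.5549) and node 2 (0.5449) are reproduced.  The
#' published degree table is internally inconsistent for two nodes (see the
#' methods vignette); the reconstruction resolves this by giving nodes 14
#' and 15 degree 7.
#'
#' @return An undirected igraph graph with 17 vertices named `"1"` to
#'   `"17"`.
#' @seealso [toy_partition()] for the two-community split.
#' @examples
#' g <- toy_network()
#' igraph::vcount(g)
#' don(g)
#' @export
toy_network <- function() {
  edges <- toy_edges()
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  igraph::permute(g, match(igraph::V(g)$name, as.character(1:17)))
}

# Edge list of the demonstration network, one row per edge.
toy_edges <- function() {
  e <- matrix(c(
    1, 8,   1, 9,   1, 10,  1, 12,  1, 13,
    2, 5,   2, 8,   2, 13,
    3, 4,   3, 6,
    4, 5,
    5, 6,
    6, 7,
    7, 9,
    8, 9,   8, 10,  8, 11,  8, 12,  8, 14,  8, 15,  8, 16,  8, 17,
    10, 12, 10, 14, 10, 15,
    11, 12, 11, 13, 11, 14, 11, 15, 11, 17,
    12, 16, 12, 17,
    13, 14, 13, 15, 13, 16, 13, 17,
    14, 15, 14, 16, 14, 17,
    15, 16, 15, 17
  ), ncol = 2, byrow = TRUE)
  cbind(as.character(e[, 1]), as.character(e[, 2]))
}

#' Two-community partition of the demonstration network
#'
#' The published split of [toy_network()]: community `"C1"` holds nodes
#' 1--7 and community `"C2"` holds nodes 8--17.  Fixture experiments use
#' this partition directly rather than re-detecting communities, so that
#' metric values do not depend on detector randomness.
#'
#' @return A [community_partition] covering the 17 nodes.
#' @export
toy_partition <- function() {
  membership <- c(rep("C1", 7L), rep("C2", 10L))
  names(membership) <- as.character(1:17)
  community_partition(membership)
}
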
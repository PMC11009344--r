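#' Community partition objects
#'
#' A community partition assigns every node of a network to exactly one
#' community (a non-overlapping cover).  Partitions are created from a
#' named membership vector, a two-column data frame, or by
#' [detect_communities()]; they can be stored to and read from two-column
#' TSV files.
#'
#' @param x A named character/numeric vector mapping node label to
#'   community id, or a data frame whose first two columns are node label
#'   and community id.
#' @return An object of class `community_partition` with components
#'   `membership` (named character vector), `communities` (list of node
#'   label vectors per community), `sizes` (named integer vector) and
#'   `cmax_size` (size of the largest community).
#' @examples
#' p <- community_partition(c(a = 1, b = 1, c = 2))
#' p$sizes
#' @export
community_partition <- function(x) {
  if (is.data.frame(x)) {
    if (ncol(x) < 2L) stop("partition data frame needs two columns: node, community")
    membership <- as.character(x[[2L]])
    names(membership) <- as.character(x[[1L]])
  } else {
    if (is.null(names(x))) stop("membership vector must be named by node label")
    membership <- as.character(x)
    names(membership) <- names(x)
  }
  if (anyDuplicated(names(membership))) {
    stop("node(s) assigned to more than one community: ",
         paste(unique(names(membership)[duplicated(names(membership))]), collapse = ", "))
  }
  communities <- split(names(membership), membership)
  sizes <- vapply(communities, length, 1L)
  structure(
    list(membership = membership,
         communities = communities,
         sizes = sizes,
         cmax_size = max(sizes)),
    class = "community_partition")
}

#' @export
print.community_partition <- function(x, ...) {
  cat("Community partition:", length(x$communities), "communities,",
      length(x$membership), "nodes\n")
  cat("sizes:", paste(sort(x$sizes, decreasing = TRUE), collapse = " "), "\n")
  invisible(x)
}

#' Read / write a partition as two-column TSV
#'
#' The file format is one node per line: node label, TAB, community id.
#'
#' @param path File path.
#' @return `read_partition()` returns a [community_partition];
#'   `write_partition()` returns `path` invisibly.
#' @export
read_partition <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          colClasses = "character", comment.char = "#")
  community_partition(df)
}

#' @rdname read_partition
#' @param part A `community_partition`.
#' @export
write_partition <- function(part, path) {
  stopifnot(inherits(part, "community_partition"))
  utils::write.table(
    data.frame(node = names(part$membership), community = part$membership),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Validate that `part` covers every node of `net`; returns the membership
# vector indexed in vertex order.
membership_for <- function(net, part) {
  stop_if_not_network(net)
  if (!inherits(part, "community_partition")) {
    stop("expected a community_partition; see community_partition()")
  }
  labels <- node_labels(net)
  missing <- setdiff(labels, names(part$membership))
  if (length(missing) > 0L) {
    stop("node(s) missing from partition: ", paste(missing, collapse = ", "))
  }
  part$membership[labels]
}

#' Detect communities with the Louvain algorithm
#'
#' Runs Louvain modularity maximization (as implemented in igraph) under a
#' fixed random seed, so that repeated calls with the same seed return the
#' same partition.  Users who have an externally curated partition can
#' bypass detection entirely by constructing a [community_partition]
#' themselves.
#'
#' @param net An undirected igraph graph.
#' @param seed Integer seed controlling the detector's randomness.
#' @return A [community_partition].
#' @export
detect_communities <- function(net, seed = 1L) {
  stop_if_not_network(net)
  if (igraph::vcount(net) < 1L) stop("empty graph")
  cl <- with_seed(seed, igraph::cluster_louvain(net))
  membership <- as.character(igraph::membership(cl))
  names(membership) <- node_labels(net)
  community_partition(membership)
}

#' Internal and external edge counts per community
#'
#' For each community \eqn{C_i} counts the edges with both endpoints inside
#' the community (\eqn{|E^{in}_{C_i}|}) and the edges with exactly one
#' endpoint inside (\eqn{|E^{out}_{C_i}|}).  Each internal edge is counted
#' once; boundary edges appear in the `e_out` of both incident
#' communities, so the counts satisfy
#' \eqn{\sum_i e_{in}(C_i) + \frac{1}{2}\sum_i e_{out}(C_i) = m}.
#'
#' @param net An undirected igraph graph.
#' @param part A [community_partition] covering `net`.
#' @return A data frame with one row per community and columns `community`,
#'   `e_in`, `e_out`, of class `community_edge_sets`.
#' @export
community_edge_sets <- function(net, part) {
  mem <- membership_for(net, part)
  el <- igraph::as_edgelist(net, names = TRUE)
  cf <- mem[el[, 1L]]
  ct <- mem[el[, 2L]]
  ids <- sort(unique(mem))
  internal <- cf == ct
  e_in <- vapply(ids, function(cc) sum(internal & cf == cc), 1L)
  e_out <- vapply(ids, function(cc) sum(!internal & (cf == cc | ct == cc)), 1L)
  structure(
    data.frame(community = ids, e_in = e_in, e_out = e_out,
               row.names = NULL, stringsAsFactors = FALSE),
    class = c("community_edge_sets", "data.frame"))
}

#' Community coefficient
#'
#' The fraction of a community's incident edges that are internal,
#' \eqn{\alpha_i = |E^{in}_{C_i}| / (|E^{in}_{C_i}| + |E^{out}_{C_i}|)}.
#' \eqn{\alpha_i = 1} means a closed community with no edges to the rest of
#' the network.  An isolated empty community (no incident edges at all) is
#' assigned \eqn{\alpha_i = 0} with a warning; Louvain partitions never
#' produce such communities, but user-supplied partitions may.
#'
#' @param ces A `community_edge_sets` data frame from
#'   [community_edge_sets()].
#' @param community Community id(s); defaults to all communities.
#' @return Named numeric vector of coefficients in `[0, 1]`.
#' @export
community_coefficient <- function(ces, community = NULL) {
  stopifnot(inherits(ces, "community_edge_sets"))
  if (is.null(community)) community <- ces$community
  idx <- match(as.character(community), ces$community)
  if (anyNA(idx)) {
    stop("unknown community id: ",
         paste(community[is.na(idx)], collapse = ", "))
  }
  tot <- ces$e_in[idx] + ces$e_out[idx]
  alpha <- ifelse(tot > 0, ces$e_in[idx] / tot, 0)
  if (any(tot == 0)) {
    warning("community with no incident edges; coefficient set to 0")
  }
  names(alpha) <- ces$community[idx]
  alpha
}

#' Internal and external degree of nodes
#'
#' Splits each node's degree into `d_in` (neighbours in the node's own
#' community) and `d_out` (neighbours elsewhere); `d_in + d_out` equals the
#' node degree for every partition.
#'
#' @param net An undirected igraph graph.
#' @param part A [community_partition] covering `net`.
#' @param node Optional node label(s); defaults to all nodes.
#' @return A data frame with columns `node`, `d_in`, `d_out`.
#' @export
internal_external_degree <- function(net, part, node = NULL) {
  mem <- membership_for(net, part)
  labels <- node_labels(net)
  el <- igraph::as_edgelist(net, names = TRUE)
  internal <- mem[el[, 1L]] == mem[el[, 2L]]
  din <- dout <- stats::setNames(integer(length(labels)), labels)
  for (col in 1:2) {
    tab_in <- table(el[internal, col])
    tab_out <- table(el[!internal, col])
    din[names(tab_in)] <- din[names(tab_in)] + as.integer(tab_in)
    dout[names(tab_out)] <- dout[names(tab_out)] + as.integer(tab_out)
  }
  out <- data.frame(node = labels, d_in = as.integer(din),
                    d_out = as.integer(dout), row.names = NULL,
                    stringsAsFactors = FALSE)
  if (!is.null(node)) {
    idx <- match(as.character(node), out$node)
    if (anyNA(idx)) stop("unknown node: ",
                         paste(node[is.na(idx)], collapse = ", "))
    out <- out[idx, , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Community boundary popularity of nodes
#'
#' For a boundary node \eqn{i} (one with at least one neighbour outside its
#' own community) the popularity is
#' \deqn{f_c(i) = \sum_{C_j \in \mathrm{com}(i)} \alpha_i \left(1 +
#'   \frac{|C_i| + |C_j|}{2 |C_{max}|}\right),}
#' where \eqn{\mathrm{com}(i)} is the set of *distinct* other communities
#' containing at least one neighbour of \eqn{i} (one term per community,
#' however many edges lead there), \eqn{\alpha_i} is the community
#' coefficient of \eqn{i}'s own community, and \eqn{|C_{max}|} is the size
#' of the largest community in the partition.  Internal nodes score 0.
#'
#' @inheritParams internal_external_degree
#' @return A data frame with columns `node`, `f_c`.
#' @export
boundary_popularity <- function(net, part, node = NULL) {
  mem <- membership_for(net, part)
  labels <- node_labels(net)
  ces <- community_edge_sets(net, part)
  alpha <- community_coefficient(ces)
  sizes <- part$sizes
  cmax <- part$cmax_size
  adj <- igraph::as_adj_list(net)
  fc <- vapply(seq_along(labels), function(vi) {
    own <- mem[[labels[vi]]]
    nb <- node_labels(net)[as.integer(adj[[vi]])]
    others <- unique(mem[nb])
    others <- setdiff(others, own)
    if (length(others) == 0L) return(0)
    a <- alpha[[own]]
    sum(a * (1 + (sizes[[own]] + unlist(sizes[others])) / (2 * cmax)))
  }, numeric(1L))
  out <- data.frame(node = labels, f_c = fc, row.names = NULL,
                    stringsAsFactors = FALSE)
  if (!is.null(node)) {
    idx <- match(as.character(node), out$node)
    if (anyNA(idx)) stop("unknown node: ",
                         paste(node[is.na(idx)], collapse = ", "))
    out <- out[idx, , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Newman-Girvan modularity of a partition
#'
#' Standard modularity \eqn{Q} of a partition, computed through igraph.
#'
#' @inheritParams internal_external_degree
#' @return A single numeric value in `[-0.5, 1]`.
#' @export
modularity_q <- function(net, part) {
  mem <- membership_for(net, part)
  if (igraph::ecount(net) < 1L) stop("modularity undefined for an empty edge set")
  igraph::modularity(net, as.integer(factor(mem)))
}
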
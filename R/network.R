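#' Read an undirected network from a plain-text edge list
#'
#' Parses the canonical interchange format used throughout the package: one
#' edge per line, two whitespace-separated node labels, lines starting with
#' `#` treated as comments.  Extra columns after the first two tokens are
#' ignored.  The graph is simplified on read: duplicate edges (in either
#' orientation) are collapsed and self-loops are dropped with a warning.
#'
#' Node labels are opaque strings and are preserved verbatim; labels that
#' look numeric are not reinterpreted, so node `"01"` and node `"1"` are
#' distinct.
#'
#' @param path Path to the edge-list file.
#' @return An undirected simple [igraph::igraph] graph with a `name` vertex
#'   attribute.
#' @examples
#' f <- tempfile()
#' writeLines(c("a b", "b c", "# comment", "c a"), f)
#' g <- read_edge_list(f)
#' igraph::vcount(g)  # 3
#' @export
read_edge_list <- function(path) {
  if (!file.exists(path)) {
    stop("edge-list file does not exist: ", path)
  }
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0L) {
    stop("edge list is empty: ", path)
  }
  tokens <- strsplit(trimws(lines[idx]), "\\s+")
  bad <- which(vapply(tokens, length, 1L) < 2L)
  if (length(bad) > 0L) {
    stop("malformed edge list line ", idx[bad[1L]], " in ", path,
         ": expected at least two whitespace-separated labels")
  }
  ends <- t(vapply(tokens, function(tk) tk[1:2], character(2L)))
  network_from_edges(ends[, 1L], ends[, 2L])
}

#' Build a simple undirected network from two label vectors
#'
#' @param from,to Character vectors of equal length giving edge endpoints.
#' @return An undirected simple igraph graph.
#' @keywords internal
network_from_edges <- function(from, to) {
  from <- as.character(from)
  to <- as.character(to)
  loops <- from == to
  if (any(loops)) {
    warning(sum(loops), " self-loop(s) dropped")
    from <- from[!loops]
    to <- to[!loops]
  }
  if (length(from) == 0L) {
    stop("no edges remain after dropping self-loops")
  }
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' Write a network to a plain-text edge list
#'
#' Inverse of [read_edge_list()]: one edge per line, two space-separated
#' labels.
#'
#' @param net An undirected igraph graph.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  stop_if_not_network(net)
  el <- igraph::as_edgelist(net, names = TRUE)
  writeLines(paste(el[, 1L], el[, 2L]), path)
  invisible(path)
}

#' @keywords internal
stop_if_not_network <- function(net) {
  if (!igraph::is_igraph(net)) {
    stop("expected an igraph graph; got ", class(net)[1L])
  }
  if (igraph::is_directed(net)) {
    stop("expected an undirected graph")
  }
  invisible(net)
}

#' Node labels of a network
#'
#' @param net An igraph graph.
#' @return Character vector of vertex names (vertex indices as strings when
#'   the graph carries no `name` attribute).
#' @keywords internal
node_labels <- function(net) {
  nm <- igraph::vertex_attr(net, "name")
  if (is.null(nm)) as.character(seq_len(igraph::vcount(net))) else nm
}

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG
# state.  All seeded entry points in the package route through this.
with_seed <- function(seed, expr) {
  if (is.null(seed)) {
    return(expr)
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}
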
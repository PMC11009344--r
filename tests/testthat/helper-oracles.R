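# Shared fixtures and independent brute-force oracles.
#
# The oracles below use only base R (adjacency matrices and breadth-first
# search) so that they are independent of the igraph-backed code paths they
# check.

# -- fixture builders --------------------------------------------------------

graph_from_pairs <- function(from, to) {
  igraph::graph_from_edgelist(cbind(as.character(from), as.character(to)),
                              directed = FALSE)
}

# Two triangles {a,b,c} and {d,e,f} joined by the bridge c--d.
two_triangle_bridge <- function() {
  graph_from_pairs(c("a", "a", "b", "c", "d", "d", "e"),
                   c("b", "c", "c", "d", "e", "f", "f"))
}

two_triangle_partition <- function() {
  community_partition(c(a = "T1", b = "T1", c = "T1",
                        d = "T2", e = "T2", f = "T2"))
}

star_graph <- function(n_leaves, center = "c") {
  leaves <- paste0("l", seq_len(n_leaves))
  graph_from_pairs(rep(center, n_leaves), leaves)
}

cycle_graph <- function(n) {
  v <- as.character(seq_len(n))
  graph_from_pairs(v, v[c(2:n, 1)])
}

path_graph <- function(n) {
  v <- as.character(seq_len(n))
  graph_from_pairs(v[-n], v[-1])
}

complete_graph <- function(n) {
  idx <- t(utils::combn(n, 2))
  graph_from_pairs(as.character(idx[, 1]), as.character(idx[, 2]))
}

# Erdos-Renyi sampler used as a *test-case generator* (not an oracle).
random_graph <- function(n, p, seed) {
  g <- mdcnet:::with_seed(seed, igraph::sample_gnp(n, p))
  igraph::V(g)$name <- as.character(seq_len(n))
  g
}

# -- base-R oracles ----------------------------------------------------------

adjacency_of <- function(net) {
  labels <- mdcnet:::node_labels(net)
  n <- length(labels)
  A <- matrix(FALSE, n, n, dimnames = list(labels, labels))
  el <- igraph::as_edgelist(net, names = TRUE)
  A[el] <- TRUE
  A[el[, 2:1, drop = FALSE]] <- TRUE
  A
}

# All-pairs BFS distances (Inf for unreachable), base R only.
bfs_distances <- function(net) {
  A <- adjacency_of(net)
  n <- nrow(A)
  D <- matrix(Inf, n, n, dimnames = dimnames(A))
  for (s in seq_len(n)) {
    dist <- rep(Inf, n)
    dist[s] <- 0
    frontier <- s
    d <- 0
    while (length(frontier) > 0) {
      d <- d + 1
      nxt <- which(apply(A[frontier, , drop = FALSE], 2, any) & !is.finite(dist))
      dist[nxt] <- d
      frontier <- nxt
    }
    D[s, ] <- dist
  }
  D
}

# Geodesic-count betweenness oracle via the path-counting identity
# sigma_st(i) = sigma_si * sigma_it when d(s,i) + d(i,t) = d(s,t).
betweenness_oracle <- function(net) {
  D <- bfs_distances(net)
  A <- adjacency_of(net)
  n <- nrow(A)
  # sigma[s, t]: number of geodesics, by dynamic programming over distance
  sigma <- matrix(0, n, n)
  diag(sigma) <- 1
  for (s in seq_len(n)) {
    ord <- order(D[s, ])
    for (v in ord) {
      if (!is.finite(D[s, v]) || D[s, v] == 0) next
      pred <- which(A[, v] & D[s, ] == D[s, v] - 1)
      sigma[s, v] <- sum(sigma[s, pred])
    }
  }
  bc <- stats::setNames(numeric(n), rownames(A))
  for (i in seq_len(n)) {
    for (s in seq_len(n - 1)) {
      for (t in (s + 1):n) {
        if (s == i || t == i || !is.finite(D[s, t])) next
        if (is.finite(D[s, i]) && is.finite(D[i, t]) &&
            D[s, i] + D[i, t] == D[s, t]) {
          bc[i] <- bc[i] + sigma[s, i] * sigma[i, t] / sigma[s, t]
        }
      }
    }
  }
  bc
}

harmonic_oracle <- function(net) {
  D <- bfs_distances(net)
  inv <- 1 / D
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  rowSums(inv)
}

efficiency_oracle <- function(net) {
  D <- bfs_distances(net)
  inv <- 1 / D
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  n <- nrow(D)
  sum(inv) / (n * (n - 1))
}

# Hand-written Newman-Girvan modularity (independent of igraph).
modularity_oracle <- function(net, membership) {
  el <- igraph::as_edgelist(net, names = TRUE)
  m <- nrow(el)
  labels <- mdcnet:::node_labels(net)
  deg <- stats::setNames(numeric(length(labels)), labels)
  tab <- table(c(el[, 1], el[, 2]))
  deg[names(tab)] <- as.numeric(tab)
  q <- 0
  for (cc in unique(membership)) {
    inside <- names(membership)[membership == cc]
    e_in <- sum(el[, 1] %in% inside & el[, 2] %in% inside)
    q <- q + e_in / m - (sum(deg[inside]) / (2 * m))^2
  }
  q
}

# All set partitions of a small vector (Bell-number enumeration).
set_partitions <- function(v) {
  if (length(v) == 1) return(list(list(v)))
  rest <- set_partitions(v[-1])
  out <- list()
  for (p in rest) {
    for (i in seq_along(p)) {
      q <- p
      q[[i]] <- c(v[1], q[[i]])
      out[[length(out) + 1]] <- q
    }
    out[[length(out) + 1]] <- c(list(v[1]), p)
  }
  out
}
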
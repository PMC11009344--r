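test_that("Louvain recovers the two triangles of the bridge graph", {
  g <- two_triangle_bridge()
  part <- detect_communities(g, seed = 7)

  # oracle: exhaustive modularity maximization over all 203 partitions
  labels <- igraph::V(g)$name
  best_q <- -Inf
  best <- NULL
  for (p in set_partitions(labels)) {
    mem <- stats::setNames(rep(seq_along(p), lengths(p)), unlist(p))
    q <- modularity_oracle(g, stats::setNames(as.character(mem), names(mem)))
    if (q > best_q) {
      best_q <- q
      best <- p
    }
  }
  canon <- function(groups) {
    paste(sort(vapply(groups, function(v) paste(sort(v), collapse = ","), "")),
          collapse = "|")
  }
  expect_equal(canon(part$communities), canon(best))
  expect_equal(canon(part$communities), "a,b,c|d,e,f")
})

test_that("detection is seed-reproducible and an edgeless graph gives singletons", {
  g <- random_graph(40, 0.15, seed = 2)
  p1 <- detect_communities(g, seed = 5)
  p2 <- detect_communities(g, seed = 5)
  expect_identical(p1$membership, p2$membership)

  e <- igraph::make_empty_graph(3, directed = FALSE)
  igraph::V(e)$name <- c("u", "v", "w")
  expect_equal(length(detect_communities(e, seed = 1)$communities), 3L)
})

test_that("community edge sets match hand counts and the counting identity", {
  g <- two_triangle_bridge()
  ces <- community_edge_sets(g, two_triangle_partition())
  expect_equal(ces$e_in, c(3L, 3L))
  expect_equal(ces$e_out, c(1L, 1L))

  whole <- community_partition(
    stats::setNames(rep("all", 6), igraph::V(g)$name))
  ces1 <- community_edge_sets(g, whole)
  expect_equal(ces1$e_in, igraph::ecount(g))
  expect_equal(ces1$e_out, 0L)

  # identity on random graphs under detected partitions
  for (s in 1:5) {
    gg <- random_graph(30, 0.15, seed = s)
    pp <- detect_communities(gg, seed = s)
    cc <- community_edge_sets(gg, pp)
    expect_equal(sum(cc$e_in) + sum(cc$e_out) / 2, igraph::ecount(gg))
  }
})

test_that("community_edge_sets names nodes missing from the partition", {
  g <- two_triangle_bridge()
  bad <- community_partition(c(a = "T1", b = "T1", c = "T1",
                               d = "T2", e = "T2"))
  expect_error(community_edge_sets(g, bad), "f")
})

test_that("community coefficient covers the closed, balanced and empty cases", {
  g <- two_triangle_bridge()
  alpha <- community_coefficient(community_edge_sets(g, two_triangle_partition()))
  expect_equal(unname(alpha), c(0.75, 0.75))

  whole <- community_partition(
    stats::setNames(rep("all", 6), igraph::V(g)$name))
  expect_equal(unname(community_coefficient(community_edge_sets(g, whole))), 1)

  ces <- structure(
    data.frame(community = c("x", "empty"), e_in = c(2L, 0L),
               e_out = c(2L, 0L)),
    class = c("community_edge_sets", "data.frame"))
  expect_warning(a <- community_coefficient(ces), "no incident edges")
  expect_equal(unname(a), c(0.5, 0))
})

test_that("internal/external degree splits match hand counts and sum to degree", {
  g <- two_triangle_bridge()
  part <- two_triangle_partition()
  expect_equal(internal_external_degree(g, part, "c")[, c("d_in", "d_out")],
               data.frame(d_in = 2L, d_out = 1L))
  expect_equal(internal_external_degree(g, part, "a")[, c("d_in", "d_out")],
               data.frame(d_in = 2L, d_out = 0L))
  expect_error(internal_external_degree(g, part, "zz"), "unknown node")

  whole <- community_partition(
    stats::setNames(rep("all", 6), igraph::V(g)$name))
  dd <- internal_external_degree(g, whole)
  expect_equal(dd$d_out, rep(0L, 6))
  expect_equal(dd$d_in, unname(igraph::degree(g)[dd$node]))

  for (s in 1:5) {
    gg <- random_graph(25, 0.2, seed = s + 10)
    pp <- detect_communities(gg, seed = s)
    dd <- internal_external_degree(gg, pp)
    expect_equal(dd$d_in + dd$d_out,
                 unname(igraph::degree(gg)[dd$node]))
  }
})

test_that("boundary popularity follows the distinct-communities rule", {
  g <- two_triangle_bridge()
  part <- two_triangle_partition()
  expect_equal(boundary_popularity(g, part, "c")$f_c, 0.75 * (1 + 6 / 6))
  expect_equal(boundary_popularity(g, part, "a")$f_c, 0)

  # a second bridge into the same community must not add a second term
  g2 <- igraph::add_edges(g, c("c", "e"))
  alpha2 <- community_coefficient(community_edge_sets(g2, part))[["T1"]]
  expect_equal(boundary_popularity(g2, part, "c")$f_c,
               alpha2 * (1 + 6 / 6))

  # a bridge into a *new* community adds exactly one term
  g3 <- igraph::add_vertices(g, 2, name = c("x", "y"))
  g3 <- igraph::add_edges(g3, c("x", "y", "c", "x"))
  part3 <- community_partition(c(a = "T1", b = "T1", c = "T1", d = "T2",
                                 e = "T2", f = "T2", x = "T3", y = "T3"))
  alpha3 <- community_coefficient(community_edge_sets(g3, part3))[["T1"]]
  fc <- boundary_popularity(g3, part3, "c")$f_c
  expect_equal(fc, alpha3 * (1 + (3 + 3) / 6) + alpha3 * (1 + (3 + 2) / 6))
})

test_that("boundary popularity is zero exactly for internal nodes", {
  for (s in 1:5) {
    gg <- random_graph(25, 0.15, seed = s + 20)
    pp <- detect_communities(gg, seed = s)
    # isolated nodes form empty singleton communities, which warn by design
    fc <- suppressWarnings(boundary_popularity(gg, pp))
    dd <- internal_external_degree(gg, pp)
    expect_equal(fc$f_c == 0, dd$d_out[match(fc$node, dd$node)] == 0)
  }
})

test_that("modularity matches the hand formula and its degenerate cases", {
  g <- two_triangle_bridge()
  expect_equal(modularity_q(g, two_triangle_partition()),
               2 * (3 / 7 - (7 / 14)^2))
  expect_equal(modularity_q(g, two_triangle_partition()), 0.357142857,
               tolerance = 1e-9)

  whole <- community_partition(
    stats::setNames(rep("all", 6), igraph::V(g)$name))
  expect_equal(modularity_q(g, whole), 0)

  singletons <- community_partition(
    stats::setNames(igraph::V(g)$name, igraph::V(g)$name))
  expect_lte(modularity_q(g, singletons), 0)

  e <- igraph::make_empty_graph(2, directed = FALSE)
  igraph::V(e)$name <- c("u", "v")
  expect_error(modularity_q(e, community_partition(c(u = "a", v = "a"))),
               "empty")
})

test_that("alpha is invariant under node relabelling", {
  g <- two_triangle_bridge()
  perm <- c(a = "p", b = "q", c = "r", d = "s", e = "t", f = "u")
  el <- igraph::as_edgelist(g, names = TRUE)
  g2 <- graph_from_pairs(perm[el[, 1]], perm[el[, 2]])
  part2 <- community_partition(stats::setNames(
    two_triangle_partition()$membership[names(perm)], unname(perm)))
  a1 <- sort(unname(community_coefficient(community_edge_sets(g, two_triangle_partition()))))
  a2 <- sort(unname(community_coefficient(community_edge_sets(g2, part2))))
  expect_equal(a1, a2)
})

test_that("partition TSV round-trips", {
  part <- toy_partition()
  f <- withr::local_tempfile()
  write_partition(part, f)
  part2 <- read_partition(f)
  expect_identical(part2$membership[names(part$membership)], part$membership)
})
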
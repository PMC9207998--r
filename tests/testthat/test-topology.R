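# Graph topology measures against closed forms and brute-force oracles.

test_that("degrees follow the handshake identity", {
  n <- 5
  complete <- binary_network(!diag(n))
  d <- degrees(complete)
  expect_equal(unname(d$out), rep(n - 1, n))
  expect_equal(unname(d$in_), rep(n - 1, n))

  single <- matrix(FALSE, 3, 3)
  single[1, 2] <- TRUE
  ds <- degrees(binary_network(single))
  expect_equal(unname(ds$out), c(1, 0, 0))
  expect_equal(unname(ds$in_), c(0, 1, 0))

  set.seed(1)
  for (i in 1:10) {
    a <- random_adjacency(6, 0.4)
    dg <- degrees(binary_network(a))
    expect_equal(sum(dg$out), sum(a))
    expect_equal(sum(dg$in_), sum(a))
  }
})

test_that("shortest paths respect direction and match Floyd-Warshall", {
  # undirected path 1-2-3
  p3 <- matrix(FALSE, 3, 3)
  p3[1, 2] <- p3[2, 1] <- p3[2, 3] <- p3[3, 2] <- TRUE
  d <- shortest_paths(binary_network(p3, directed = FALSE))
  expect_equal(unname(d[1, 3]), 2)

  # directed single edge
  e12 <- matrix(FALSE, 2, 2)
  e12[1, 2] <- TRUE
  dd <- shortest_paths(binary_network(e12))
  expect_equal(unname(dd[1, 2]), 1)
  expect_identical(unname(dd[2, 1]), Inf)

  set.seed(2)
  for (i in 1:50) {
    a <- random_adjacency(sample(3:8, 1), runif(1, 0.1, 0.6))
    expect_equal(unname(shortest_paths(binary_network(a))),
                 unname(fw_distances(a)))
  }
})

test_that("global efficiency closed forms hold", {
  expect_equal(global_efficiency(binary_network(!diag(4))), 1)
  expect_equal(global_efficiency(binary_network(matrix(FALSE, 4, 4))), 0)

  p3 <- matrix(FALSE, 3, 3)
  p3[1, 2] <- p3[2, 1] <- p3[2, 3] <- p3[3, 2] <- TRUE
  expect_equal(global_efficiency(binary_network(p3, directed = FALSE)),
               5 / 6)
})

test_that("adding an edge never decreases global efficiency", {
  set.seed(3)
  for (i in 1:10) {
    a <- random_adjacency(6, 0.2)
    e0 <- global_efficiency(binary_network(a))
    free <- which(!a & row(a) != col(a))
    a2 <- a
    a2[sample(free, 1)] <- TRUE
    expect_gte(global_efficiency(binary_network(a2)), e0)
  }
})

test_that("triangle counts match Table-style closed forms", {
  tri <- matrix(FALSE, 3, 3)
  tri[lower.tri(tri)] <- tri[upper.tri(tri)] <- TRUE
  expect_equal(unname(triangles(binary_network(tri, directed = FALSE))),
               rep(1, 3))

  # fully bidirectional 3-clique, treated as directed: t_i = 8
  expect_equal(unname(triangles(binary_network(tri, directed = TRUE))),
               rep(8, 3))

  star <- matrix(FALSE, 5, 5)
  star[1, 2:5] <- star[2:5, 1] <- TRUE
  expect_equal(unname(triangles(binary_network(star, directed = FALSE))),
               rep(0, 5))
})

test_that("clustering and transitivity match the triple-enumeration oracle", {
  comp <- binary_network(!diag(5), directed = FALSE)
  ct <- clustering_transitivity(comp)
  expect_equal(ct$clustering, 1)
  expect_equal(ct$transitivity, 1)

  cyc <- matrix(FALSE, 4, 4)
  cyc[cbind(1:4, c(2, 3, 4, 1))] <- TRUE
  cyc <- cyc | t(cyc)
  ct4 <- clustering_transitivity(binary_network(cyc, directed = FALSE))
  expect_equal(ct4$clustering, 0)
  expect_equal(ct4$transitivity, 0)

  set.seed(4)
  for (i in 1:40) {
    directed <- i %% 2 == 0
    a <- random_adjacency(sample(3:7, 1), runif(1, 0.2, 0.7), directed)
    got <- clustering_transitivity(binary_network(a, directed = directed))
    want <- enum_clustering(a, directed)
    expect_equal(got$clustering, want$clustering, tolerance = 1e-12)
    expect_equal(got$transitivity, want$transitivity, tolerance = 1e-12)
    expect_equal(unname(triangles(binary_network(a, directed = directed))),
                 enum_triangles(a, directed), tolerance = 1e-12)
  }
})

test_that("local efficiency equals the neighbour-subgraph oracle", {
  expect_equal(local_efficiency(binary_network(!diag(5),
                                               directed = FALSE)), 1)

  star <- matrix(FALSE, 5, 5)
  star[1, 2:5] <- star[2:5, 1] <- TRUE
  expect_equal(local_efficiency(binary_network(star, directed = FALSE)), 0)

  # oracle: mean over nodes of the induced neighbour-subgraph efficiency
  set.seed(5)
  for (i in 1:25) {
    n <- sample(4:8, 1)
    a <- random_adjacency(n, runif(1, 0.3, 0.7), directed = FALSE)
    want <- mean(vapply(seq_len(n), function(v) {
      nb <- which(a[v, ])
      if (length(nb) < 2) return(0)
      sub <- a[nb, nb, drop = FALSE]
      d <- fw_distances(sub)
      inv <- 1 / d
      diag(inv) <- 0
      sum(inv) / (length(nb) * (length(nb) - 1))
    }, numeric(1)))
    expect_equal(local_efficiency(binary_network(a, directed = FALSE)),
                 want, tolerance = 1e-12)
  }
})

test_that("modularity matches closed forms and the edge-count oracle", {
  # single module: Q = 0
  set.seed(6)
  a <- random_adjacency(6, 0.4)
  expect_equal(modularity_q(binary_network(a), rep(1, 6)), 0)

  # two disconnected 4-cliques, component partition: Q = 0.5
  blocks <- matrix(FALSE, 8, 8)
  blocks[1:4, 1:4] <- !diag(4)
  blocks[5:8, 5:8] <- !diag(4)
  part <- rep(1:2, each = 4)
  expect_equal(modularity_q(binary_network(blocks, directed = FALSE), part),
               0.5)

  # printed bracket-squared variant differs but is available
  expect_equal(modularity_q(binary_network(blocks, directed = FALSE), part,
                            printed_form = TRUE), 0)

  for (i in 1:30) {
    n <- sample(4:8, 1)
    a <- random_adjacency(n, runif(1, 0.2, 0.7))
    p <- sample(1:3, n, replace = TRUE)
    expect_equal(modularity_q(binary_network(a), p),
                 enum_modularity(a, p), tolerance = 1e-12)
  }
})

test_that("greedy partition search recovers planted communities", {
  blocks <- matrix(FALSE, 8, 8)
  blocks[1:4, 1:4] <- !diag(4)
  blocks[5:8, 5:8] <- !diag(4)
  net <- binary_network(blocks, directed = FALSE)
  part <- find_partition(net, seed = 1)
  expect_equal(length(unique(part)), 2)
  expect_true(all(part[1:4] == part[1]) && all(part[5:8] == part[5]))
  expect_equal(modularity_q(net, part), 0.5)

  # complete graph has no community structure
  comp <- binary_network(!diag(6), directed = FALSE)
  expect_lte(modularity_q(comp, find_partition(comp, seed = 1)), 1e-12)

  # never worse than the single-module partition
  set.seed(7)
  for (i in 1:10) {
    a <- random_adjacency(7, runif(1, 0.1, 0.5))
    if (sum(a) == 0) next
    net_i <- binary_network(a)
    expect_gte(modularity_q(net_i, find_partition(net_i, seed = 2)), 0)
  }
})

test_that("directed formulas reduce to undirected ones on symmetric graphs", {
  set.seed(8)
  for (i in 1:30) {
    a <- random_adjacency(sample(4:8, 1), runif(1, 0.2, 0.6),
                          directed = FALSE)
    u <- binary_network(a, directed = FALSE)
    d <- binary_network(a, directed = TRUE)
    expect_equal(global_efficiency(d), global_efficiency(u))
    cu <- clustering_transitivity(u)
    cd <- clustering_transitivity(d)
    expect_equal(cd$clustering, cu$clustering, tolerance = 1e-12)
    expect_equal(cd$transitivity, cu$transitivity, tolerance = 1e-12)
    expect_equal(local_efficiency(d), local_efficiency(u),
                 tolerance = 1e-12)
    p <- sample(1:2, nrow(a), replace = TRUE)
    expect_equal(modularity_q(d, p), modularity_q(u, p), tolerance = 1e-12)
  }
})

test_that("scalar measures are isomorphism invariant", {
  set.seed(9)
  a <- random_adjacency(7, 0.35)
  perm <- sample(7)
  ap <- a[perm, perm]
  expect_equal(global_efficiency(binary_network(a)),
               global_efficiency(binary_network(ap)))
  expect_equal(clustering_transitivity(binary_network(a))$clustering,
               clustering_transitivity(binary_network(ap))$clustering)
  expect_equal(local_efficiency(binary_network(a)),
               local_efficiency(binary_network(ap)))
  expect_equal(sort(unname(triangles(binary_network(a)))),
               sort(unname(triangles(binary_network(ap)))))
})

test_that("measures agree with igraph on undirected graphs", {
  skip_if_not_installed("igraph")
  set.seed(10)
  for (i in 1:10) {
    a <- random_adjacency(7, 0.4, directed = FALSE)
    g <- igraph::graph_from_adjacency_matrix(a, mode = "undirected")
    tg <- igraph::transitivity(g, type = "global")
    if (is.nan(tg)) tg <- 0  # igraph's triangle-free convention
    expect_equal(clustering_transitivity(
      binary_network(a, directed = FALSE))$transitivity, tg,
      tolerance = 1e-12)
    di <- igraph::distances(g)
    expect_equal(unname(shortest_paths(binary_network(a,
                                                      directed = FALSE))),
                 unname(di))
  }
})

test_that("topology_report assembles all measures and sink-convention input", {
  set.seed(11)
  a <- random_adjacency(6, 0.4)
  rep_src <- topology_report(binary_network(a, convention = "source"))
  rep_snk <- topology_report(binary_network(t(a), convention = "sink"))
  expect_equal(rep_src$out_degree, rep_snk$out_degree)
  expect_equal(rep_src$global_efficiency, rep_snk$global_efficiency)
  g <- glance(rep_src)
  expect_s3_class(g, "tbl_df")
  expect_equal(g$n_edges, sum(a))
})
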
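two_cliques_graph <- function() {
  g <- igraph::make_full_graph(5) + igraph::make_full_graph(5)
  g <- igraph::add_edges(g, c(1, 6))
  igraph::E(g)$weight <- 1
  g
}

test_that("planted two-clique graph is split exactly at the bridge, at optimal Q", {
  g <- two_cliques_graph()
  part <- leading_eigenvector_partition(g)
  expect_equal(part$n_modules, 2L)
  expect_equal(unname(part$assignment[1:5]), rep(1L, 5))
  expect_equal(unname(part$assignment[6:10]), rep(2L, 5))
  q_opt <- oracle_best_modularity(g, max_groups = 3)
  expect_equal(part$Q, q_opt, tolerance = 1e-12)
  # Q agrees with the independent implementation on the same partition
  expect_equal(part$Q,
               igraph::modularity(g, part$assignment,
                                  weights = igraph::E(g)$weight),
               tolerance = 1e-12)
  expect_equal(sum(part$q_contrib), part$Q, tolerance = 1e-10)
})

test_that("complete graphs are indivisible and disconnected edges split at Q = 0.5", {
  k6 <- igraph::make_full_graph(6)
  igraph::E(k6)$weight <- 1
  part <- leading_eigenvector_partition(k6)
  expect_equal(part$n_modules, 1L)
  expect_equal(part$Q, 0, tolerance = 1e-12)

  two_edges <- igraph::make_graph(c(1, 2, 3, 4), directed = FALSE)
  igraph::E(two_edges)$weight <- 1
  p2 <- leading_eigenvector_partition(two_edges)
  expect_equal(p2$n_modules, 2L)
  expect_equal(p2$Q, 0.5, tolerance = 1e-12)
})

test_that("isolated nodes become singleton modules and labels stay contiguous", {
  g <- two_cliques_graph()
  g <- igraph::add_vertices(g, 2)
  part <- leading_eigenvector_partition(g)
  expect_equal(part$n_modules, 4L)
  expect_setequal(unique(part$assignment), 1:4)
  sizes <- table(part$assignment)
  expect_equal(sort(as.integer(sizes)), c(1L, 1L, 5L, 5L))
  expect_equal(sum(part$q_contrib), part$Q, tolerance = 1e-10)
})

test_that("accepted recursive splits never push Q outside its bounds", {
  set.seed(41)
  for (rep in 1:5) {
    g <- igraph::sample_gnp(30, 0.15)
    igraph::E(g)$weight <- runif(igraph::ecount(g), 0.1, 1)
    part <- leading_eigenvector_partition(g)
    expect_gte(part$Q, -0.5)
    expect_lte(part$Q, 1)
    expect_equal(part$Q,
                 igraph::modularity(g, part$assignment,
                                    weights = igraph::E(g)$weight),
                 tolerance = 1e-10)
    single_q <- igraph::modularity(g, rep(1, 30),
                                   weights = igraph::E(g)$weight)
    expect_gte(part$Q, single_q - 1e-12)
  }
})

test_that("star and complete graphs match the closed-form centralities", {
  star <- igraph::make_star(5, mode = "undirected")  # centre is vertex 1
  igraph::E(star)$weight <- 1
  c_star <- eigenvector_centrality(star)
  expect_equal(unname(c_star), c(1, rep(0.5, 4)), tolerance = 1e-10)

  k5 <- igraph::make_full_graph(5)
  igraph::E(k5)$weight <- 1
  expect_equal(unname(eigenvector_centrality(k5)), rep(1, 5),
               tolerance = 1e-10)
})

test_that("weighted centralities match the power-iteration oracle", {
  tri <- igraph::make_graph(c(1, 2, 2, 3, 1, 3), directed = FALSE)
  igraph::E(tri)$weight <- c(2, 1, 1)
  A <- igraph::as_adjacency_matrix(tri, attr = "weight", sparse = FALSE)
  expect_equal(unname(eigenvector_centrality(tri)),
               unname(oracle_power_iteration(A)), tolerance = 1e-8)

  set.seed(42)
  g <- igraph::sample_gnp(12, 0.5)
  while (igraph::components(g)$no > 1) g <- igraph::sample_gnp(12, 0.5)
  igraph::E(g)$weight <- runif(igraph::ecount(g), 0.2, 2)
  A <- igraph::as_adjacency_matrix(g, attr = "weight", sparse = FALSE)
  expect_equal(unname(eigenvector_centrality(g)),
               unname(oracle_power_iteration(A)), tolerance = 1e-8)
})

test_that("centrality is invariant under uniform weight scaling, per component", {
  g <- two_cliques_graph()
  igraph::E(g)$weight <- runif(21, 0.5, 2)
  c1 <- eigenvector_centrality(g)
  g2 <- g
  igraph::E(g2)$weight <- igraph::E(g)$weight * 10
  expect_equal(c1, eigenvector_centrality(g2), tolerance = 1e-10)

  # disconnected graph: each analysed component carries a maximum of 1
  gd <- igraph::make_full_graph(3) + igraph::make_full_graph(4)
  igraph::E(gd)$weight <- 1
  cd <- eigenvector_centrality(gd)
  comp <- igraph::components(gd)$membership
  expect_equal(max(cd[comp == 1]), 1)
  expect_equal(max(cd[comp == 2]), 1)
})

test_that("module matching maps by maximal Jaccard with deterministic ties", {
  mk <- function(assign) structure(list(assignment = assign), class = "module_partition")
  ids <- sprintf("m%02d", 1:9)
  a <- setNames(c(1, 1, 1, 2, 2, 2, 3, 3, 3), ids)
  res <- match_modules(mk(a), mk(a))
  expect_true(all(res$mapping$jaccard == 1))
  expect_false(any(res$membership_change))

  b <- a; b["m04"] <- 1   # one metabolite moves
  res2 <- match_modules(mk(a), mk(b))
  expect_identical(sum(res2$membership_change), 1L)
  expect_true(res2$membership_change[["m04"]])
})

test_that("matching agrees with a brute-force Jaccard matrix on random partitions", {
  set.seed(43)
  ids <- sprintf("m%03d", 1:322)
  a <- setNames(sample(1:14, 322, replace = TRUE), ids)
  b <- setNames(sample(1:12, 322, replace = TRUE), ids)
  mk <- function(assign) structure(list(assignment = assign), class = "module_partition")
  res <- match_modules(mk(b), mk(a))
  for (i in seq_len(nrow(res$mapping))) {
    fl <- res$mapping$fasted_module[i]
    jrow <- vapply(sort(unique(b)), function(pl) {
      fi <- ids[a == fl]; pj <- ids[b == pl]
      length(intersect(fi, pj)) / length(union(fi, pj))
    }, numeric(1))
    best <- sort(unique(b))[which(jrow == max(jrow))]
    expect_identical(res$mapping$post_module[i], min(best))
    expect_equal(res$mapping$jaccard[i], max(jrow), tolerance = 1e-12)
  }
})
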
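# Independent oracles used across the suite. Each is a deliberately naive
# implementation (brute force / direct rule application) kept separate from
# the package's own algorithms.

# Power-iteration eigenvector centrality on a (connected) weighted adjacency.
oracle_power_iteration <- function(A, tol = 1e-13, max_iter = 1e6) {
  v <- rep(1, nrow(A))
  for (i in seq_len(max_iter)) {
    v_new <- drop(A %*% v)
    v_new <- v_new / sqrt(sum(v_new^2))
    if (max(abs(v_new - v)) < tol) break
    v <- v_new
  }
  v_new / max(v_new)
}

# Exhaustive maximum-modularity partition into at most `max_groups` groups,
# scored by igraph::modularity (an implementation independent of the
# package's own Q computation). Returns the best Q.
oracle_best_modularity <- function(graph, max_groups = 3, weighted = TRUE) {
  n <- igraph::vcount(graph)
  stopifnot(n <= 10)
  w <- if (weighted && !is.null(igraph::E(graph)$weight))
    igraph::E(graph)$weight else NULL
  best <- -Inf
  for (code in 0:(max_groups^n - 1)) {
    membership <- integer(n)
    c0 <- code
    for (i in seq_len(n)) {
      membership[i] <- c0 %% max_groups
      c0 <- c0 %/% max_groups
    }
    q <- igraph::modularity(graph, membership + 1, weights = w)
    if (q > best) best <- q
  }
  best
}

# Direct triple-rule DPI: drop (i,j) iff some k has
# min(M[i,k], M[j,k]) - eps > M[i,j]; all decisions against the input matrix.
oracle_dpi <- function(m, eps = 0) {
  n <- nrow(m)
  keep <- matrix(TRUE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    for (k in seq_len(n)) {
      if (k == i || k == j) next
      if (m[i, j] < min(m[i, k], m[j, k]) - eps) {
        keep[i, j] <- FALSE
        break
      }
    }
  }
  out <- ifelse(keep, m, 0)
  diag(out) <- 0
  out
}

# One-way ANOVA F by explicit sums of squares.
oracle_anova_f <- function(y, g) {
  g <- as.factor(g)
  grand <- mean(y)
  ss_between <- sum(tapply(y, g, function(v) length(v) * (mean(v) - grand)^2))
  ss_within <- sum(unlist(tapply(y, g, function(v) (v - mean(v))^2)))
  df1 <- nlevels(g) - 1L
  df2 <- length(y) - nlevels(g)
  list(F = (ss_between / df1) / (ss_within / df2), df1 = df1, df2 = df2)
}

# Scalar moderated-variance formula, evaluated independently.
oracle_posterior_var <- function(d0, s0_sq, d, s2) (d0 * s0_sq + d * s2) / (d0 + d)

# Convenience: small weighted graph from an edge list matrix.
graph_from_edges <- function(edges, weights, n = NULL) {
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  igraph::E(g)$weight <- weights
  if (!is.null(n) && igraph::vcount(g) < n)
    g <- igraph::add_vertices(g, n - igraph::vcount(g))
  g
}

# Networks -> DNM report, the sub-pipeline used by recovery studies (skips
# diffexpr / PLS-DA / HOSVD for speed).
run_dnm_path <- function(tensor) {
  net_post <- infer_network(tensor, "post_absorptive")
  net_fast <- infer_network(tensor, "fasted")
  p_post <- leading_eigenvector_partition(net_post)
  p_fast <- leading_eigenvector_partition(net_fast)
  cent <- centrality_table(net_post, net_fast)
  rank_dnm_candidates(tensor, p_post, p_fast, centrality = cent)
}
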
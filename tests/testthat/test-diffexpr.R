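toy_tensor <- function(post, fasted, ids = NULL) {
  G <- nrow(post)
  ids <- ids %||% sprintf("m%d", seq_len(G))
  values <- array(c(post, fasted), c(G, ncol(post), 2))
  metabodnm::intensity_tensor(values, ids, sprintf("s%d", seq_len(ncol(post))))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("paired differences and fold changes follow the log2 arithmetic", {
  post <- matrix(c(100, 200), 1, 2)
  fasted <- matrix(c(200, 800), 1, 2)
  d <- paired_differences(toy_tensor(post, fasted))
  expect_equal(unname(d[1, ]), c(1, 2))
  expect_equal(unname(rowMeans(d)), 1.5)

  post2 <- matrix(runif(12, 50, 150), 3, 4)
  expect_equal(unname(paired_differences(toy_tensor(post2, 2 * post2))),
               matrix(1, 3, 4))
  expect_equal(unname(paired_differences(toy_tensor(post2, post2))),
               matrix(0, 3, 4))
  expect_error(paired_differences(toy_tensor(post2 * 0, post2)),
               class = "mdnm_value_error")
})

test_that("prior estimation recovers known hyperparameters and degenerates sanely", {
  set.seed(11)
  d0 <- 4; s0 <- 0.5; d <- 7
  s2 <- (s0 * d0 / rchisq(10000, d0)) * rchisq(10000, d) / d
  pr <- estimate_prior(s2, d)
  expect_lt(abs(pr$d0 - d0) / d0, 0.10)
  expect_lt(abs(pr$s0_sq - s0) / s0, 0.05)

  # agreement with the reference empirical-Bayes fit
  fd <- limma::fitFDist(s2, df1 = d)
  expect_equal(pr$d0, fd$df2, tolerance = 1e-6)
  expect_equal(pr$s0_sq, fd$scale, tolerance = 1e-6)

  # no spread beyond the chi-square floor -> infinite prior df
  expect_true(is.infinite(estimate_prior(rep(0.3, 50), 7)$d0))

  # single common scale: s0^2 recovers the scale
  set.seed(12)
  s2c <- 0.8 * rchisq(20000, 7) / 7
  expect_lt(abs(estimate_prior(s2c, 7)$s0_sq - 0.8) / 0.8, 0.05)

  expect_error(estimate_prior(rep(0, 50), 7), class = "mdnm_value_error")
})

test_that("moderated t reduces to the classical paired t at d0 = 0", {
  set.seed(13)
  d <- matrix(rnorm(5 * 8, sd = 0.5), 5, 8,
              dimnames = list(sprintf("m%d", 1:5), NULL))
  prior0 <- structure(list(d0 = 0, s0_sq = 1), class = "moderation_prior")
  got <- moderated_paired_test(d, prior0)
  for (g in 1:5) {
    tt <- t.test(d[g, ])
    expect_equal(got$t_mod[g], unname(tt$statistic), tolerance = 1e-12)
    expect_equal(got$p[g], tt$p.value, tolerance = 1e-12)
  }
})

test_that("moderated t matches the scalar posterior-variance formula", {
  d <- matrix(c(1, 2), 1, 2)
  prior <- structure(list(d0 = 2, s0_sq = 0.25), class = "moderation_prior")
  got <- moderated_paired_test(d, prior)
  s2 <- var(c(1, 2))
  st <- oracle_posterior_var(2, 0.25, 1, s2)
  expect_equal(st, 1 / 3)
  expect_equal(got$t_mod, 1.5 / sqrt(st / 2), tolerance = 1e-12)
  expect_equal(got$df, 3)
  expect_equal(got$p, 2 * pt(-abs(got$t_mod), 3), tolerance = 1e-12)

  # zero fold change gives t = 0, p = 1
  d0m <- matrix(c(-1, 1), 1, 2)
  expect_equal(moderated_paired_test(d0m, prior)$t_mod, 0)
  expect_equal(moderated_paired_test(d0m, prior)$p, 1)
})

test_that("moderation shrinks every variance toward the prior", {
  # heteroscedastic differences with a genuinely finite variance prior
  set.seed(14)
  G <- 400; n <- 8
  sigma <- sqrt(0.5 * 4 / rchisq(G, 4))
  d <- matrix(rnorm(G * n, sd = rep(sigma, n)), G, n,
              dimnames = list(sprintf("m%03d", 1:G), NULL))
  s2 <- apply(d, 1, var)
  pr <- estimate_prior(s2, n - 1)
  expect_true(is.finite(pr$d0))
  tab <- moderated_paired_test(d, pr)
  s2_tilde <- (pr$d0 * pr$s0_sq + (n - 1) * s2) / (pr$d0 + n - 1)
  expect_true(all(s2_tilde >= pmin(s2, pr$s0_sq) - 1e-12))
  expect_true(all(s2_tilde <= pmax(s2, pr$s0_sq) + 1e-12))
  # and the full moderated fit agrees with the reference implementation
  fit <- limma::lmFit(d, design = matrix(1, n, 1))
  eb <- limma::eBayes(fit)
  expect_equal(unname(tab$t_mod), unname(eb$t[, 1]), tolerance = 1e-8)
  expect_equal(unname(tab$p), unname(eb$p.value[, 1]), tolerance = 1e-8)
})

test_that("BH adjustment reproduces the hand-computed step-up values", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.04)), c(0.02, 0.04))
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  p <- c(0.005, 0.011, 0.02, 0.04, 0.9)
  expect_true(all(bh_adjust(p) >= p))
  expect_error(bh_adjust(c(0.5, 1.2)), class = "mdnm_value_error")
})

test_that("classification uses strict inequality at the alpha boundary", {
  expect_identical(metabodnm:::classify_changes(0.04, 0.3), "increase")
  expect_identical(metabodnm:::classify_changes(0.04, -0.3), "decrease")
  expect_identical(metabodnm:::classify_changes(0.05, 0.3), "no_change")
  expect_identical(metabodnm:::classify_changes(0.06, -2), "no_change")
})

test_that("change-class summary counts sum to the catalogue size", {
  sim <- generate_paired_metabolome(synth_config(seed = 15))
  de <- diff_expr(sim$tensor)
  counts <- classify_and_summarize(de, sim$tensor)
  expect_identical(sum(counts$overall), 322L)
  expect_true(all(rowSums(counts$per_pathway) >= 1))
})

test_that("volcano labelling flags exactly the metabolites outside the quantiles", {
  set.seed(16)
  sim <- generate_paired_metabolome(synth_config(n_metabolites = 100L,
                                                 n_modules = 5L,
                                                 dnm_module_size = 20L,
                                                 seed = 16))
  de <- diff_expr(sim$tensor)
  v <- volcano_table(de)
  qs <- quantile(de$lfc, c(0.025, 0.975), type = 7)
  expect_identical(sum(v$extreme), sum(de$lfc < qs[1] | de$lfc > qs[2]))
  expect_gt(sum(v$extreme), 0)

  # permutation invariance of the labelled set
  perm <- sample(nrow(de))
  de2 <- de[perm, ]
  class(de2) <- class(de)
  v2 <- volcano_table(de2)
  expect_setequal(v$metabolite_id[v$extreme], v2$metabolite_id[v2$extreme])

  # all-equal fold changes label nothing
  de3 <- de; de3$lfc <- 1
  v3 <- volcano_table(de3)
  expect_identical(sum(v3$extreme), 0L)
})
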
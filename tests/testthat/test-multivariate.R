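test_that("multilevel centering zeroes each subject and halves paired differences", {
  set.seed(21)
  x <- matrix(rnorm(6 * 10), 6, 10)
  subj <- rep(c("a", "b", "c"), 2)
  dev <- multilevel_center(x, subj)
  for (s in unique(subj))
    expect_equal(unname(colSums(dev[subj == s, ])), rep(0, 10),
                 tolerance = 1e-12)
  d_paired <- x[4, ] - x[1, ]      # subject a: rows 1 (post) and 4 (fasted)
  expect_equal(unname(dev[4, ]), unname(d_paired / 2), tolerance = 1e-12)
  expect_equal(unname(dev[1, ]), unname(-d_paired / 2), tolerance = 1e-12)

  expect_equal(multilevel_center(rbind(x[1:3, ], x[1:3, ]), subj),
               matrix(0, 6, 10), ignore_attr = TRUE)
  expect_error(multilevel_center(x[1:5, ], subj[1:5]),
               class = "mdnm_design_error")
})

make_separable_tensor <- function(n = 8, G = 30, delta = 4, seed = 22) {
  set.seed(seed)
  post <- matrix(2^rnorm(G * n, 10, 0.2), G, n)
  fasted <- post * 2^matrix(rnorm(G * n, 0, 0.2), G, n)
  fasted[1, ] <- fasted[1, ] * 2^delta      # one metabolite carries the split
  values <- array(c(post, fasted), c(G, n, 2))
  intensity_tensor(values, sprintf("m%02d", 1:G), sprintf("s%d", 1:n))
}

test_that("PLS-DA concentrates loadings on the discriminating metabolite", {
  tensor <- make_separable_tensor()
  fit <- plsda_fit(tensor)
  expect_equal(unname(sqrt(colSums(fit$loadings^2))), c(1, 1),
               tolerance = 1e-10)
  expect_identical(names(which.max(abs(fit$loadings[, 1]))), "m01")
  expect_gt(abs(fit$loadings["m01", 1]), 0.9)
  s1 <- fit$scores[fit$condition == "fasted", 1]
  s0 <- fit$scores[fit$condition == "post_absorptive", 1]
  expect_gt(min(s1), max(s0))   # zero overlap, fasted positive
})

test_that("permuting condition labels collapses the discriminant separation", {
  tensor <- make_separable_tensor()
  dev <- metabodnm:::tensor_deviations(tensor)
  x <- dev$x
  real <- plsda_fit(x = x, subject = dev$subject, condition = dev$condition)
  real_sep <- diff(range(real$centroids[, 1]))
  set.seed(23)
  perm_sep <- replicate(30, {
    cond <- dev$condition
    flip <- runif(8) < 0.5     # permute within subject to keep pairing
    for (i in which(flip)) cond[c(i, i + 8)] <- cond[c(i + 8, i)]
    if (length(unique(cond)) < 2) return(NA_real_)
    f <- plsda_fit(x = x, subject = dev$subject, condition = cond)
    mean(f$scores[cond == "fasted", 1]) -
      mean(f$scores[cond == "post_absorptive", 1])
  })
  expect_lt(mean(abs(perm_sep), na.rm = TRUE), real_sep / 3)
})

test_that("duplicating every sample leaves the loading directions unchanged", {
  tensor <- make_separable_tensor()
  dev <- metabodnm:::tensor_deviations(tensor)
  fit1 <- plsda_fit(x = dev$x, subject = dev$subject,
                    condition = dev$condition)
  fit2 <- plsda_fit(x = rbind(dev$x, dev$x),
                    subject = c(dev$subject, paste0(dev$subject, "_dup")),
                    condition = c(dev$condition, dev$condition))
  expect_equal(fit1$loadings, fit2$loadings, tolerance = 1e-8)
})

test_that("multilevel deviations and scores agree with the reference implementation", {
  tensor <- make_separable_tensor()
  fit <- plsda_fit(tensor)
  y <- log2(tensor$values)
  X <- rbind(t(y[, , 1]), t(y[, , 2]))
  dev_ref <- suppressMessages(
    mixOmics::withinVariation(X, design = data.frame(sample = rep(1:8, 2))))
  expect_equal(unname(multilevel_center(X, rep(1:8, 2))), unname(dev_ref),
               tolerance = 1e-10)
  Y <- factor(rep(c("post", "fasted"), each = 8), levels = c("post", "fasted"))
  rownames(dev_ref) <- sprintf("s%02d", 1:16)
  ml <- suppressMessages(mixOmics::plsda(dev_ref, Y, ncomp = 2,
                                         scale = FALSE))
  expect_gt(abs(cor(fit$scores[, 1], ml$variates$X[, 1])), 0.99)
})

test_that("top-loading selection is a pure quantile rule", {
  tensor <- make_separable_tensor(G = 100, seed = 24)
  fit <- plsda_fit(tensor)
  sel <- select_top_loadings(fit)
  for (k in 1:2) {
    l <- fit$loadings[, k]
    qs <- quantile(l, c(0.05, 0.95), type = 7)
    expect_setequal(sel[[k]], names(l)[l < qs[1] | l > qs[2]])
    expect_gte(length(sel[[k]]), 5)
  }
  const <- fit
  const$loadings[, 1] <- 0.1
  expect_length(select_top_loadings(const)$comp1, 0)
})

test_that("group score ellipses separate under strong planted effects", {
  sim <- generate_paired_metabolome(strong_effect_config(seed = 25))
  fit <- plsda_fit(sim$tensor)
  e1 <- fit$ellipses$post_absorptive
  e2 <- fit$ellipses$fasted
  maha <- function(pts, e) {
    d <- sweep(pts, 2, e$centre)
    rowSums((d %*% solve(e$cov)) * d)
  }
  crit <- qchisq(0.95, 2)
  expect_true(all(maha(e1$boundary, e2) > crit))
  expect_true(all(maha(e2$boundary, e1) > crit))
})

test_that("HOSVD is exact, orthonormal, and matches direct unfolding SVDs", {
  set.seed(26)
  a <- array(rnorm(20 * 6 * 2), c(20, 6, 2))
  h <- hosvd(a, center = FALSE)
  for (m in 1:3) {
    U <- h$factors[[m]]
    expect_equal(crossprod(U), diag(ncol(U)), tolerance = 1e-10)
  }
  expect_lt(sqrt(sum((hosvd_reconstruct(h) - a)^2) / sum(a^2)), 1e-10)
  # core norm equals tensor norm
  expect_equal(sum(h$core^2), sum(a^2), tolerance = 1e-10)

  # independent mode-1 unfolding by explicit loops
  unf <- matrix(0, 20, 12)
  for (i in 1:20) for (j in 1:6) for (k in 1:2)
    unf[i, j + (k - 1) * 6] <- a[i, j, k]
  expect_equal(h$mode_singular_values[[1]], svd(unf)$d, tolerance = 1e-10)
})

test_that("rank-1 tensors yield single singular values and proportional contributions", {
  u <- c(3, 1, 2); v <- c(1, 2); w <- c(2, 1)
  a <- outer(u, outer(v, w))
  h <- hosvd(a, center = FALSE)
  for (m in 1:3) {
    sv <- h$mode_singular_values[[m]]
    expect_gt(sv[1], 0)
    if (length(sv) > 1) expect_lt(max(sv[-1]), 1e-10)
  }
  expect_equal(unname(sort(h$contributions, decreasing = TRUE)) /
                 max(h$contributions),
               sort(abs(u), decreasing = TRUE) / max(abs(u)),
               tolerance = 1e-10)
})

test_that("contribution ranking is invariant to scaling and permutation", {
  sim <- generate_paired_metabolome(synth_config(n_metabolites = 50L,
                                                 n_modules = 5L,
                                                 dnm_module_size = 10L,
                                                 seed = 27))
  h1 <- hosvd(sim$tensor)
  t2 <- sim$tensor
  t2$values <- t2$values * 7
  h2 <- hosvd(intensity_tensor(t2$values, t2$metabolite_ids,
                               t2$individual_ids))
  expect_identical(names(h1$contributions), names(h2$contributions))

  perm <- sample(50)
  t3 <- intensity_tensor(sim$tensor$values[perm, , ],
                         sim$tensor$metabolite_ids[perm],
                         sim$tensor$individual_ids)
  h3 <- hosvd(t3)
  expect_equal(h3$contributions[names(h1$contributions)], h1$contributions,
               tolerance = 1e-8)
})
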
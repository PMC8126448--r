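#' Multilevel (within-subject) centering
#'
#' Splits paired data into subject means and within-subject deviations and
#' returns the deviations: each sample's log2 profile minus its subject's
#' mean over the two conditions. Supervised analysis on these deviations acts
#' on the paired differences, which is the standard multilevel treatment of a
#' paired design. Per-subject sums are exactly zero for every metabolite.
#'
#' @param x Samples x metabolites matrix of log2 intensities.
#' @param subject Subject label per row of `x`.
#' @return Matrix of within-subject deviations, same shape as `x`.
#' @export
multilevel_center <- function(x, subject) {
  x <- as.matrix(x)
  subject <- as.character(subject)
  if (length(subject) != nrow(x))
    design_error("one subject label per sample row is required")
  counts <- base::table(subject)
  if (any(counts != 2))
    design_error(sprintf("unpaired subject(s): %s",
                         paste(names(counts)[counts != 2], collapse = ", ")))
  means <- rowsum(x, subject) / 2
  x - means[subject, , drop = FALSE]
}

# Deviation matrix straight from a tensor: rows are the 2N samples
# (post-absorptive block first), columns metabolites.
tensor_deviations <- function(tensor) {
  y <- log2_tensor(tensor)
  N <- dim(y)[2]
  x <- rbind(t(y[, , 1]), t(y[, , 2]))
  rownames(x) <- c(paste0(tensor$individual_ids, "_", conditions()[1]),
                   paste0(tensor$individual_ids, "_", conditions()[2]))
  list(x = x,
       subject = rep(tensor$individual_ids, 2),
       condition = rep(conditions(), each = N))
}

#' Paired (multilevel) PLS-DA
#'
#' Fits a two-component PLS discriminant model by NIPALS on the
#' within-subject deviation matrix with a single +/-1 dummy response
#' (+1 = fasted). Loadings (the NIPALS weight vectors) are unit-norm;
#' component signs are fixed so the fasted centroid is positive on
#' component 1 (and, when distinguishable, on component 2), which makes
#' output reproducible. Explained variance is the fraction of the deviation
#' matrix's total sum of squares captured by each component's rank-1
#' approximation; because PLS maximises covariance with the response rather
#' than X-variance, the fractions need not decrease across components.
#'
#' @param tensor An [intensity_tensor()], or `NULL` when `x`, `subject` and
#'   `condition` are given directly.
#' @param n_components Number of latent components (default 2).
#' @param x,subject,condition Optional explicit sample matrix (samples x
#'   metabolites, log2), subject labels and condition labels.
#' @return An object of class `plsda_model` with `scores`, `loadings`,
#'   `explained_variance`, `centroids`, `ellipses` and the sample metadata.
#' @export
plsda_fit <- function(tensor = NULL, n_components = 2, x = NULL,
                      subject = NULL, condition = NULL) {
  if (!is.null(tensor)) {
    dev <- tensor_deviations(tensor)
    x <- multilevel_center(dev$x, dev$subject)
    subject <- dev$subject
    condition <- dev$condition
  } else {
    condition <- normalize_condition(condition)
    x <- multilevel_center(x, subject)
  }
  if (length(unique(condition)) < 2)
    design_error("both conditions must be present")
  if (min(base::table(condition)) < 2)
    design_error("need >= 2 samples per condition")

  y <- ifelse(condition == "fasted", 1, -1)
  X <- scale(x, center = TRUE, scale = FALSE)
  y_c <- y - mean(y)
  ss_total <- sum(X^2)

  n_comp <- min(n_components, ncol(X), nrow(X) - 1L)
  scores <- matrix(0, nrow(X), n_comp)
  loadings <- matrix(0, ncol(X), n_comp)
  expl <- numeric(n_comp)
  Xk <- X
  for (k in seq_len(n_comp)) {
    w <- drop(crossprod(Xk, y_c))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) {
      n_comp <- k - 1L
      break
    }
    w <- w / nw
    t_k <- drop(Xk %*% w)
    p_k <- drop(crossprod(Xk, t_k)) / sum(t_k^2)
    expl[k] <- sum(t_k^2) * sum(p_k^2) / ss_total
    Xk <- Xk - tcrossprod(t_k, p_k)
    scores[, k] <- t_k
    loadings[, k] <- w
  }
  scores <- scores[, seq_len(n_comp), drop = FALSE]
  loadings <- loadings[, seq_len(n_comp), drop = FALSE]
  expl <- expl[seq_len(n_comp)]

  # sign convention: fasted centroid positive on each component
  for (k in seq_len(n_comp)) {
    sep <- mean(scores[condition == "fasted", k]) -
      mean(scores[condition == "post_absorptive", k])
    if (sep < 0 || (sep == 0 && sum(loadings[, k]) < 0)) {
      scores[, k] <- -scores[, k]
      loadings[, k] <- -loadings[, k]
    }
  }
  rownames(scores) <- rownames(x)
  colnames(scores) <- colnames(loadings) <- paste0("comp", seq_len(n_comp))
  rownames(loadings) <- colnames(x)

  centroids <- rowsum(scores, condition) / as.vector(base::table(condition))
  ellipses <- if (n_comp >= 2)
    lapply(split(seq_along(condition), condition), function(idx)
      normal_ellipse(scores[idx, 1:2, drop = FALSE])) else NULL

  structure(list(scores = scores, loadings = loadings,
                 explained_variance = expl, centroids = centroids,
                 ellipses = ellipses, subject = subject,
                 condition = condition),
            class = "plsda_model")
}

# 95% bivariate-normal ellipse from a 2-column score matrix: centre,
# covariance and a closed polygon of boundary points.
normal_ellipse <- function(s, level = 0.95, n_points = 181L) {
  centre <- colMeans(s)
  S <- stats::cov(s)
  r <- sqrt(stats::qchisq(level, df = 2))
  eig <- eigen(S, symmetric = TRUE)
  eig$values <- pmax(eig$values, 0)
  theta <- seq(0, 2 * pi, length.out = n_points)
  circle <- rbind(cos(theta), sin(theta))
  pts <- t(eig$vectors %*% (sqrt(eig$values) * circle) * r) +
    matrix(centre, n_points, 2, byrow = TRUE)
  list(centre = centre, cov = S, level = level, boundary = pts)
}

#' @export
print.plsda_model <- function(x, ...) {
  cat(sprintf("plsda_model: %d samples, %d metabolites, %d components\n",
              nrow(x$scores), nrow(x$loadings), ncol(x$scores)))
  cat(sprintf("  explained X-variance: %s\n",
              paste(sprintf("%.1f%%", 100 * x$explained_variance),
                    collapse = ", ")))
  invisible(x)
}

#' Metabolites with extreme loadings per component
#'
#' Selects, per component, the metabolites whose loadings fall strictly
#' outside the lower/upper quantiles of that component's loading
#' distribution (type-7 linear interpolation).
#'
#' @param model A `plsda_model`.
#' @param lower_q,upper_q Quantile bounds (defaults 0.05 and 0.95).
#' @return Named list (one character vector of metabolite IDs per component).
#' @export
select_top_loadings <- function(model, lower_q = 0.05, upper_q = 0.95) {
  stopifnot(inherits(model, "plsda_model"))
  lapply(setNames(seq_len(ncol(model$loadings)),
                  colnames(model$loadings)), function(k) {
    l <- model$loadings[, k]
    qs <- stats::quantile(l, c(lower_q, upper_q), type = 7, names = FALSE)
    names(l)[l < qs[1] | l > qs[2]]
  })
}

# ---- HOSVD ------------------------------------------------------------------

unfold <- function(a, mode) {
  d <- dim(a)
  perm <- c(mode, setdiff(seq_along(d), mode))
  matrix(aperm(a, perm), nrow = d[mode])
}

refold <- function(m, mode, dims) {
  perm <- c(mode, setdiff(seq_along(dims), mode))
  a <- array(m, dim = dims[perm])
  aperm(a, order(perm))
}

# multiply tensor by matrix along a mode
ttm <- function(a, mat, mode) {
  d <- dim(a)
  res <- mat %*% unfold(a, mode)
  d[mode] <- nrow(mat)
  refold(res, mode, d)
}

#' Higher-order SVD of the metabolite x individual x condition tensor
#'
#' Computes one orthonormal factor matrix per mode via the SVD of each mode
#' unfolding of the (optionally metabolite-centred) log2 tensor, together
#' with the core tensor. The untruncated decomposition reconstructs the
#' input exactly (to numerical tolerance). Per-metabolite contribution
#' scores summarise how much of the tensor's total variance each metabolite
#' carries: the row norms of the metabolite-mode factor weighted by the
#' mode-1 singular values (equivalently, the row norms of the mode-1
#' unfolding projected on its own singular basis).
#'
#' @param tensor An [intensity_tensor()], or a plain 3-d array of log2
#'   values.
#' @param center Subtract each metabolite's grand mean first (default TRUE).
#' @return An object of class `hosvd_result` with `core`, `factors` (list of
#'   3 orthonormal matrices), `mode_singular_values` and `contributions`
#'   (named, sorted decreasing).
#' @export
hosvd <- function(tensor, center = TRUE) {
  if (inherits(tensor, "intensity_tensor")) {
    a <- log2_tensor(tensor)
  } else {
    a <- as.array(tensor)
  }
  if (any(!is.finite(a))) value_error("tensor values must be finite")
  if (length(dim(a)) != 3L) format_error("a 3-mode tensor is required")
  if (center) a <- a - as.vector(rowMeans(a, dims = 1))

  factors <- vector("list", 3L)
  sv <- vector("list", 3L)
  for (m in 1:3) {
    s <- svd(unfold(a, m))
    factors[[m]] <- s$u
    sv[[m]] <- s$d
  }
  core <- ttm(ttm(ttm(a, t(factors[[1]]), 1), t(factors[[2]]), 2),
              t(factors[[3]]), 3)

  u1 <- factors[[1]]
  contrib <- sqrt(rowSums((u1 %*% diag(sv[[1]], length(sv[[1]])))^2))
  names(contrib) <- dimnames(a)[[1]]
  structure(list(core = core, factors = factors,
                 mode_singular_values = sv,
                 contributions = sort(contrib, decreasing = TRUE),
                 centered = center, dims = dim(a)),
            class = "hosvd_result")
}

#' Reconstruct the tensor from an HOSVD
#' @param x An `hosvd_result`.
#' @return 3-d array; equals the (centred) input to numerical tolerance.
#' @export
hosvd_reconstruct <- function(x) {
  stopifnot(inherits(x, "hosvd_result"))
  ttm(ttm(ttm(x$core, x$factors[[1]], 1), x$factors[[2]], 2),
      x$factors[[3]], 3)
}

#' @export
print.hosvd_result <- function(x, ...) {
  cat(sprintf("hosvd_result: tensor %s (%s)\n",
              paste(x$dims, collapse = " x "),
              if (x$centered) "metabolite-centred" else "uncentred"))
  cat("  top contributing metabolites:\n")
  print(utils::head(round(x$contributions, 3), 5))
  invisible(x)
}
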
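#' Within-subject paired log2 differences
#'
#' For every metabolite g and subject i, computes
#' `d[g,i] = log2(fasted) - log2(post-absorptive)`. The row means of this
#' matrix are the per-metabolite log2 fold changes.
#'
#' @param tensor An [intensity_tensor()] with strictly positive intensities.
#' @return Numeric matrix, metabolites x individuals.
#' @export
paired_differences <- function(tensor) {
  stopifnot(inherits(tensor, "intensity_tensor"))
  y <- log2_tensor(tensor)
  matrix(y[, , 2] - y[, , 1], nrow = dim(y)[1],
         dimnames = dimnames(y)[1:2])
}

# Newton inversion of trigamma, as used when moment-matching the variance
# prior: solves trigamma(y) = x for y > 0.
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (iter in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2L)
    y <- y + dif
    if (abs(dif) / y < 1e-10) break
  }
  y
}

#' Moment-match a scaled inverse-chi-square prior to observed variances
#'
#' Empirical-Bayes hyperparameter estimation for variance moderation: assumes
#' `s2_g * d_g / sigma2_g ~ chi2(d_g)` with `sigma2_g` drawn from a scaled
#' inverse-chi-square prior with `d0` degrees of freedom and scale `s0_sq`,
#' and fits `(d0, s0_sq)` from the mean and variance of `log(s2_g)`. When the
#' spread of `log(s2_g)` does not exceed its sampling floor `trigamma(d/2)`,
#' the prior is degenerate and `d0 = Inf` is returned with `s0_sq` from the
#' geometric mean.
#'
#' @param s2 Per-metabolite sample variances of the paired differences.
#' @param df Residual degrees of freedom per metabolite (scalar; `n - 1`).
#' @return A list of class `moderation_prior` with `d0` and `s0_sq`.
#' @export
estimate_prior <- function(s2, df) {
  s2 <- as.numeric(s2)
  stopifnot_scalar_number(df, "df")
  if (df < 1) design_error("residual df must be >= 1")
  ok <- is.finite(s2) & s2 > 0
  if (all(s2[is.finite(s2)] == 0))
    value_error("all variances are zero: degenerate data")
  if (sum(ok) < 10)
    design_error("need >= 10 metabolites with positive variance and df >= 1")
  z <- log(s2[ok])
  # E log(chi2_d / d) = digamma(d/2) - log(d/2); Var log chi2_d = trigamma(d/2)
  e_bias <- digamma(df / 2) - log(df / 2)
  mean_z <- mean(z)
  var_z <- stats::var(z)
  excess <- var_z - trigamma(df / 2)
  if (excess <= 0) {
    d0 <- Inf
    s0_sq <- exp(mean_z - e_bias)
  } else {
    d0 <- 2 * trigamma_inverse(excess)
    s0_sq <- exp(mean_z - e_bias + digamma(d0 / 2) - log(d0 / 2))
  }
  structure(list(d0 = d0, s0_sq = s0_sq), class = "moderation_prior")
}

#' @export
print.moderation_prior <- function(x, ...) {
  cat(sprintf("moderation_prior: d0 = %s, s0^2 = %.6g\n",
              if (is.infinite(x$d0)) "Inf" else sprintf("%.4g", x$d0),
              x$s0_sq))
  invisible(x)
}

#' Moderated paired t-test
#'
#' Shrinks each metabolite's paired-difference variance toward the prior,
#' `s2_tilde = (d0*s0_sq + d*s2) / (d0 + d)`, and tests the mean difference
#' with `t = lfc / sqrt(s2_tilde / n)` on `d0 + d` degrees of freedom
#' (two-sided). With `d0 = 0` this is the ordinary paired t-test; with
#' `d0 = Inf` every metabolite is tested against the common prior variance
#' and a normal reference.
#'
#' @param differences Matrix of paired log2 differences
#'   (see [paired_differences()]).
#' @param prior A `moderation_prior`, or `NULL` to estimate one from the data.
#' @return data.frame with `metabolite_id`, `lfc`, `s2`, `t_mod`, `df`, `p`.
#' @export
moderated_paired_test <- function(differences, prior = NULL) {
  d <- as.matrix(differences)
  n <- ncol(d)
  if (n < 2) design_error("need >= 2 individuals for a paired test")
  dg <- n - 1
  lfc <- rowMeans(d)
  s2 <- apply(d, 1, stats::var)
  if (is.null(prior)) prior <- estimate_prior(s2, dg)
  d0 <- prior$d0
  s0 <- prior$s0_sq
  if (is.infinite(d0)) {
    s2_tilde <- rep(s0, length(lfc))
    df_tot <- Inf
  } else {
    s2_tilde <- (d0 * s0 + dg * s2) / (d0 + dg)
    df_tot <- d0 + dg
  }
  t_mod <- lfc / sqrt(s2_tilde / n)
  t_mod[s2_tilde == 0 & lfc == 0] <- 0
  p <- 2 * stats::pt(-abs(t_mod), df = df_tot)
  data.frame(metabolite_id = rownames(d) %||% as.character(seq_along(lfc)),
             lfc = lfc, s2 = s2, t_mod = t_mod, df = df_tot, p = p,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment (monotone-enforced, capped at 1).
#'
#' @param p Vector of raw P values in `[0, 1]`.
#' @return Adjusted P values, same order as input.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    value_error("P values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Paired differential metabolite expression
#'
#' Runs the full moderated paired analysis on a tensor: paired log2
#' differences, empirical-Bayes variance prior, moderated t-tests, BH
#' adjustment, and classification of each metabolite as `increase`,
#' `decrease` or `no_change` (adjusted P strictly below `alpha`, signed by
#' the fold change).
#'
#' @param tensor An [intensity_tensor()].
#' @param alpha Significance threshold on the adjusted P (default 0.05).
#' @param prior Optional `moderation_prior` override.
#' @return A `diff_expr_table` data.frame with columns `metabolite_id`,
#'   `lfc`, `s2`, `t_mod`, `df`, `p`, `p_adj`, `class`, plus the prior as an
#'   attribute.
#' @export
diff_expr <- function(tensor, alpha = 0.05, prior = NULL) {
  d <- paired_differences(tensor)
  tab <- moderated_paired_test(d, prior)
  if (is.null(prior)) prior <- estimate_prior(tab$s2, ncol(d) - 1)
  tab$p_adj <- bh_adjust(tab$p)
  tab$class <- classify_changes(tab$p_adj, tab$lfc, alpha)
  attr(tab, "prior") <- prior
  attr(tab, "alpha") <- alpha
  class(tab) <- c("diff_expr_table", "data.frame")
  tab
}

classify_changes <- function(p_adj, lfc, alpha = 0.05) {
  ifelse(p_adj < alpha & lfc > 0, "increase",
         ifelse(p_adj < alpha & lfc < 0, "decrease", "no_change"))
}

#' Summarise change classes, overall and per super pathway
#'
#' @param table A `diff_expr_table`.
#' @param tensor Optional [intensity_tensor()] whose annotations supply the
#'   super-pathway grouping.
#' @return A list with `overall` (named counts summing to the number of
#'   metabolites) and, when annotations are available, `per_pathway` (a
#'   data.frame of counts by super pathway).
#' @export
classify_and_summarize <- function(table, tensor = NULL) {
  stopifnot(inherits(table, "diff_expr_table"))
  lev <- c("no_change", "decrease", "increase")
  overall <- base::table(factor(table$class, levels = lev))
  out <- list(overall = setNames(as.integer(overall), lev))
  if (!is.null(tensor) && !is.null(tensor$annotations)) {
    ann <- tensor$annotations
    sp <- ann$super_pathway[match(table$metabolite_id, ann$metabolite_id)]
    sp[is.na(sp)] <- "unidentified"
    tab <- base::table(super_pathway = sp,
                       class = factor(table$class, levels = lev))
    out$per_pathway <- as.data.frame.matrix(tab)
  }
  out
}

#' Volcano table with extreme-fold-change labelling
#'
#' Returns the per-metabolite coordinates of a volcano plot (log2 fold change
#' against -log10 adjusted P) and flags metabolites whose fold change lies
#' strictly outside the 2.5% / 97.5% quantiles of all fold changes
#' (type-7 linear-interpolation quantiles).
#'
#' @param table A `diff_expr_table`.
#' @param lower_q,upper_q Quantile bounds (defaults 0.025 and 0.975).
#' @return data.frame with `metabolite_id`, `lfc`, `neg_log10_p_adj`,
#'   `extreme` (logical).
#' @export
volcano_table <- function(table, lower_q = 0.025, upper_q = 0.975) {
  stopifnot(inherits(table, "diff_expr_table"))
  qs <- stats::quantile(table$lfc, c(lower_q, upper_q), type = 7, names = FALSE)
  data.frame(metabolite_id = table$metabolite_id,
             lfc = table$lfc,
             neg_log10_p_adj = -log10(pmax(table$p_adj, .Machine$double.xmin)),
             extreme = table$lfc < qs[1] | table$lfc > qs[2],
             stringsAsFactors = FALSE)
}

#' @export
print.diff_expr_table <- function(x, ...) {
  cat(sprintf("diff_expr_table: %d metabolites (alpha = %g)\n",
              nrow(x), attr(x, "alpha") %||% 0.05))
  print(table(x$class))
  pr <- attr(x, "prior")
  if (!is.null(pr)) print(pr)
  invisible(x)
}
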
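#' Between-individual coefficient of variation per metabolite and condition
#'
#' `CV = sd / mean` of natural-scale intensity across individuals (sample
#' sd, n-1 denominator), the package's proxy for expression stochasticity:
#' by the central limit theorem a larger between-individual variance
#' reflects a larger variance of the underlying expression process.
#'
#' @param tensor An [intensity_tensor()] with >= 2 individuals.
#' @return data.frame `metabolite_id`, `cv_post`, `cv_fasted`.
#' @export
between_individual_cv <- function(tensor) {
  stopifnot(inherits(tensor, "intensity_tensor"))
  if (length(tensor$individual_ids) < 2)
    design_error("need >= 2 individuals for a between-individual CV")
  cv_one <- function(m) apply(m, 1, stats::sd) / rowMeans(m)
  data.frame(metabolite_id = tensor$metabolite_ids,
             cv_post = unname(cv_one(condition_slice(tensor, "post_absorptive"))),
             cv_fasted = unname(cv_one(condition_slice(tensor, "fasted"))),
             stringsAsFactors = FALSE)
}

#' One-way GLM of a per-metabolite response on module membership
#'
#' Fixed-effects one-way linear model with an F-test of the module factor.
#' With `log_transform = TRUE` the response is log-transformed first
#' (values below `floor` are floored, since eigenvector centrality can be
#' numerically zero off the dominant component) and the per-module
#' predictions are back-transformed with a naive `exp`. Singleton modules
#' can be excluded, which removes both their metabolites and their factor
#' levels, so with N responses and k retained modules the F degrees of
#' freedom are (k - 1, N' - k).
#'
#' @param response Numeric response per metabolite.
#' @param modules Module label per metabolite.
#' @param log_transform Log the response before fitting?
#' @param exclude_singletons Drop modules containing a single metabolite?
#' @param floor Lower floor applied before log (default 1e-12).
#' @return An object of class `module_glm`: `F`, `df1`, `df2`, `p`,
#'   `means` (per-module prediction and 95% CI, back-transformed when
#'   logged), `excluded_modules`, `log_transform`.
#' @export
module_glm <- function(response, modules, log_transform = FALSE,
                       exclude_singletons = TRUE, floor = 1e-12) {
  if (length(response) != length(modules))
    align_error("response and module labels differ in length")
  modules <- as.character(modules)
  sizes <- base::table(modules)
  excluded <- character(0)
  if (exclude_singletons) {
    excluded <- names(sizes)[sizes == 1]
    keep <- !(modules %in% excluded)
    response <- response[keep]
    modules <- modules[keep]
  }
  if (length(unique(modules)) < 2)
    design_error("need >= 2 (non-singleton) modules for the GLM")
  y <- response
  if (log_transform) {
    y <- log(pmax(response, floor))
  }
  f <- factor(modules)
  fit <- stats::lm(y ~ f)
  df1 <- nlevels(f) - 1L
  df2 <- length(y) - nlevels(f)
  if (all(y == y[1])) {
    # identical responses: no heterogeneity, by definition
    Fv <- 0; p <- 1
  } else {
    an <- stats::anova(fit)
    Fv <- an[1, "F value"]
    p <- an[1, "Pr(>F)"]
    if (!is.finite(Fv)) { Fv <- 0; p <- 1 }
  }

  nd <- data.frame(f = factor(levels(f), levels = levels(f)))
  pr <- stats::predict(fit, nd, interval = "confidence", level = 0.95)
  if (log_transform) pr <- exp(pr)
  means <- data.frame(module = levels(f), fit = pr[, "fit"],
                      lwr = pr[, "lwr"], upr = pr[, "upr"],
                      stringsAsFactors = FALSE)
  structure(list(F = Fv, df1 = df1, df2 = df2, p = p,
                 means = means, excluded_modules = excluded,
                 log_transform = log_transform),
            class = "module_glm")
}

#' @export
print.module_glm <- function(x, ...) {
  cat(sprintf("module_glm: F(%d, %d) = %.2f, p = %.3g%s\n",
              x$df1, x$df2, x$F, x$p,
              if (length(x$excluded_modules))
                sprintf(" (excluded singleton modules: %s)",
                        paste(x$excluded_modules, collapse = ", ")) else ""))
  invisible(x)
}

#' Rank fasted modules and select the dynamic network marker
#'
#' A DNM module is expected to show, ahead of a physiological state shift:
#' the largest eigenvector centrality, the largest paired increase in
#' centrality, the largest between-individual CV in the fasted state, and a
#' leading contribution to the fasted network's modularity. Each eligible
#' (non-singleton) fasted module is ranked on those four statistics (rank 1
#' = largest); the composite score is the mean of the four ranks and the
#' module with the best composite is selected. Ties are broken by larger
#' module size, then smaller label. Three module GLMs accompany the
#' ranking: log centrality ~ module, paired centrality change ~ module, and
#' log fasted CV ~ module, plus the baseline (post-absorptive) log CV GLM.
#' If the fasted CV GLM is not significant at `gate_alpha` the report is
#' flagged `no DNM detected` (stochasticity heterogeneity is a requirement,
#' not just a ranking input), while ranks are still listed. The baseline CV
#' GLM is advisory: weak or absent baseline heterogeneity corroborates a
#' forming DNM but does not veto it.
#'
#' @param tensor An [intensity_tensor()].
#' @param p_post,p_fast `module_partition` objects for the two conditions.
#' @param centrality Optional precomputed [centrality_table()] data.frame.
#' @param cv Optional precomputed [between_individual_cv()] data.frame.
#' @param gate_alpha Significance gate on the fasted CV GLM (default 0.05).
#' @return An object of class `dnm_report`.
#' @export
rank_dnm_candidates <- function(tensor, p_post, p_fast, centrality = NULL,
                                cv = NULL, gate_alpha = 0.05) {
  assign <- p_fast$assignment
  ids <- names(assign)
  if (!setequal(ids, tensor$metabolite_ids))
    align_error("partition and tensor cover different metabolites")
  if (is.null(cv)) cv <- between_individual_cv(tensor)
  cv <- cv[match(ids, cv$metabolite_id), ]
  if (is.null(centrality))
    align_error("a centrality table is required (see centrality_table())")
  centrality <- centrality[match(ids, centrality$metabolite_id), ]

  sizes <- base::table(assign)
  singletons <- names(sizes)[sizes == 1]
  eligible <- setdiff(names(sizes), singletons)

  glm_cent <- module_glm(centrality$centrality_fasted, assign,
                         log_transform = TRUE, exclude_singletons = TRUE)
  glm_delta <- module_glm(centrality$delta_centrality, assign,
                          log_transform = FALSE, exclude_singletons = TRUE)
  glm_cv_fast <- module_glm(cv$cv_fasted, assign,
                            log_transform = TRUE, exclude_singletons = TRUE)
  glm_cv_post <- module_glm(cv$cv_post, p_post$assignment[ids],
                            log_transform = TRUE, exclude_singletons = TRUE)

  stats_df <- do.call(rbind, lapply(eligible, function(m) {
    idx <- assign == as.integer(m)
    data.frame(module = as.integer(m),
               size = sum(idx),
               mean_centrality = mean(centrality$centrality_fasted[idx]),
               mean_delta_centrality = mean(centrality$delta_centrality[idx]),
               mean_cv_fasted = mean(cv$cv_fasted[idx]),
               mean_cv_post = mean(cv$cv_post[idx]),
               q_contrib = unname(p_fast$q_contrib[as.character(m)]))
  }))

  flagged <- "none"
  selected <- NA_integer_
  if (is.null(stats_df) || nrow(stats_df) < 2) {
    flagged <- "fewer than 2 eligible modules"
  } else {
    rk <- function(v) rank(-v, ties.method = "average")  # rank 1 = largest
    stats_df$rank_centrality <- rk(stats_df$mean_centrality)
    stats_df$rank_delta <- rk(stats_df$mean_delta_centrality)
    stats_df$rank_cv <- rk(stats_df$mean_cv_fasted)
    stats_df$rank_q <- rk(stats_df$q_contrib)
    stats_df$composite <- rowMeans(stats_df[, c("rank_centrality", "rank_delta",
                                                "rank_cv", "rank_q")])
    ord <- order(stats_df$composite, -stats_df$size, stats_df$module)
    stats_df <- stats_df[ord, ]
    selected <- stats_df$module[1]
    if (glm_cv_fast$p >= gate_alpha) {
      flagged <- "no DNM detected"
      selected <- NA_integer_
    }
  }

  structure(list(candidates = stats_df,
                 selected_module = selected,
                 flag = flagged,
                 glm_centrality = glm_cent,
                 glm_delta_centrality = glm_delta,
                 glm_cv_fasted = glm_cv_fast,
                 glm_cv_post = glm_cv_post,
                 excluded_singletons = as.integer(singletons),
                 partition = p_fast),
            class = "dnm_report")
}

#' @export
print.dnm_report <- function(x, ...) {
  cat("dnm_report\n")
  cat(sprintf("  selected DNM module: %s%s\n",
              if (is.na(x$selected_module)) "none" else x$selected_module,
              if (x$flag != "none") sprintf(" [%s]", x$flag) else ""))
  cat(sprintf("  centrality ~ module:        F(%d,%d) = %.2f, p = %.3g\n",
              x$glm_centrality$df1, x$glm_centrality$df2,
              x$glm_centrality$F, x$glm_centrality$p))
  cat(sprintf("  delta centrality ~ module:  F(%d,%d) = %.2f, p = %.3g\n",
              x$glm_delta_centrality$df1, x$glm_delta_centrality$df2,
              x$glm_delta_centrality$F, x$glm_delta_centrality$p))
  cat(sprintf("  log fasted CV ~ module:     F(%d,%d) = %.2f, p = %.3g\n",
              x$glm_cv_fasted$df1, x$glm_cv_fasted$df2,
              x$glm_cv_fasted$F, x$glm_cv_fasted$p))
  cat(sprintf("  log baseline CV ~ module:   F(%d,%d) = %.2f, p = %.3g\n",
              x$glm_cv_post$df1, x$glm_cv_post$df2,
              x$glm_cv_post$F, x$glm_cv_post$p))
  if (!is.null(x$candidates) && nrow(x$candidates)) {
    cat("  top candidates:\n")
    print(utils::head(x$candidates[, c("module", "size", "mean_centrality",
                                       "mean_delta_centrality",
                                       "mean_cv_fasted", "q_contrib",
                                       "composite")], 5), row.names = FALSE)
  }
  invisible(x)
}
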
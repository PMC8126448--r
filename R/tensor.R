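#' Canonical condition labels
#'
#' The pipeline works on a paired two-condition design: a baseline
#' (post-absorptive) sample and a fasted sample from each individual.
#' All user-supplied condition labels are normalised to these two.
#'
#' @return Character vector `c("post_absorptive", "fasted")`.
#' @export
conditions <- function() c("post_absorptive", "fasted")

normalize_condition <- function(x) {
  key <- gsub("[ -]", "_", tolower(trimws(x)))
  post <- c("post_absorptive", "postabsorptive", "post", "baseline", "fed")
  fast <- c("fasted", "fasting", "fast")
  out <- ifelse(key %in% post, "post_absorptive",
                ifelse(key %in% fast, "fasted", NA_character_))
  if (anyNA(out))
    format_error(sprintf("unrecognised condition label(s): %s",
                         paste(unique(x[is.na(out)]), collapse = ", ")))
  out
}

#' Construct an intensity tensor
#'
#' Builds the 3-dimensional container used throughout the pipeline: a
#' metabolite x individual x condition array of natural-scale (strictly
#' non-negative) intensities, with an optional metabolite annotation table.
#' Intensities are stored on the natural scale; log2 is taken once, downstream.
#'
#' @param values Numeric array with `dim = c(n_metabolites, n_individuals, 2)`.
#' @param metabolite_ids Unique metabolite labels (rows of mode 1).
#' @param individual_ids Unique subject labels (mode 2).
#' @param annotations Optional `data.frame` with columns `metabolite_id`,
#'   `identified` (logical) and `super_pathway` (character).
#'
#' @return An object of class `intensity_tensor`.
#' @export
intensity_tensor <- function(values, metabolite_ids, individual_ids,
                             annotations = NULL) {
  values <- as.array(values)
  if (length(dim(values)) != 3L || dim(values)[3] != 2L)
    format_error("'values' must be a 3-d array with two condition slices")
  if (length(metabolite_ids) != dim(values)[1])
    format_error("metabolite_ids length does not match values")
  if (length(individual_ids) != dim(values)[2])
    format_error("individual_ids length does not match values")
  metabolite_ids <- as.character(metabolite_ids)
  individual_ids <- as.character(individual_ids)
  if (anyDuplicated(metabolite_ids))
    format_error("duplicate metabolite IDs")
  if (anyDuplicated(individual_ids))
    format_error("duplicate individual IDs")
  if (any(!is.finite(values)))
    value_error("intensities must be finite")
  if (any(values < 0))
    value_error("intensities must be non-negative")
  dimnames(values) <- list(metabolite = metabolite_ids,
                           individual = individual_ids,
                           condition = conditions())
  if (!is.null(annotations)) {
    annotations <- as.data.frame(annotations)
    need <- c("metabolite_id", "identified", "super_pathway")
    if (!all(need %in% names(annotations)))
      format_error("annotations must have columns metabolite_id, identified, super_pathway")
    annotations$metabolite_id <- as.character(annotations$metabolite_id)
  }
  structure(list(values = values,
                 metabolite_ids = metabolite_ids,
                 individual_ids = individual_ids,
                 conditions = conditions(),
                 annotations = annotations),
            class = "intensity_tensor")
}

#' @export
print.intensity_tensor <- function(x, ...) {
  cat(sprintf("intensity_tensor: %d metabolites x %d individuals x 2 conditions\n",
              length(x$metabolite_ids), length(x$individual_ids)))
  cat(sprintf("  conditions: %s\n", paste(x$conditions, collapse = ", ")))
  cat(sprintf("  annotations: %s\n",
              if (is.null(x$annotations)) "none" else
                sprintf("%d metabolites annotated", nrow(x$annotations))))
  invisible(x)
}

#' @export
dim.intensity_tensor <- function(x) dim(x$values)

#' Extract one condition slice as a metabolite x individual matrix
#'
#' @param tensor An `intensity_tensor`.
#' @param condition `"post_absorptive"` or `"fasted"` (any recognised alias).
#' @param log2 If `TRUE`, return log2 intensities (requires strictly
#'   positive values).
#' @return Numeric matrix, metabolites in rows.
#' @export
condition_slice <- function(tensor, condition, log2 = FALSE) {
  stopifnot(inherits(tensor, "intensity_tensor"))
  cond <- normalize_condition(condition)
  m <- tensor$values[, , cond, drop = FALSE]
  m <- array(m, dim = dim(m)[1:2],
             dimnames = dimnames(tensor$values)[1:2])
  if (log2) {
    if (any(m <= 0)) {
      bad <- which(m <= 0, arr.ind = TRUE)[1, ]
      value_error(sprintf(
        "zero/negative intensity for metabolite '%s', individual '%s': log2 undefined",
        rownames(m)[bad[1]], colnames(m)[bad[2]]))
    }
    m <- log2(m)
  }
  m
}

#' Log2 tensor as a 3-d array
#' @keywords internal
log2_tensor <- function(tensor) {
  if (any(tensor$values <= 0)) {
    bad <- which(tensor$values <= 0, arr.ind = TRUE)[1, ]
    value_error(sprintf(
      "zero intensity for metabolite '%s' (individual '%s', %s): log2 undefined",
      tensor$metabolite_ids[bad[1]], tensor$individual_ids[bad[2]],
      tensor$conditions[bad[3]]))
  }
  log2(tensor$values)
}

#' Count identified and unidentified metabolites
#'
#' Summarises the metabolite catalogue of a dataset: how many compounds are
#' present in total, how many carry a positive structural identification in the
#' annotation table, and how many remain of undetermined identity. Totals
#' always satisfy `total = identified + unidentified`.
#'
#' @param tensor An `intensity_tensor`.
#' @return A list with components `total`, `identified`, `unidentified`.
#' @export
summarize_catalogue <- function(tensor) {
  stopifnot(inherits(tensor, "intensity_tensor"))
  total <- length(tensor$metabolite_ids)
  ann <- tensor$annotations
  if (is.null(ann)) {
    warning("no annotations: counting all metabolites as unidentified")
    ident <- 0L
  } else {
    flags <- ann$identified[match(tensor$metabolite_ids, ann$metabolite_id)]
    flags[is.na(flags)] <- FALSE
    ident <- sum(flags)
  }
  list(total = total, identified = ident, unidentified = total - ident)
}
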
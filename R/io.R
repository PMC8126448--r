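#' Load a paired metabolomics dataset from delimited text
#'
#' Reads an intensity table (metabolites in rows, samples in columns, first
#' column the metabolite ID), a sample sheet mapping each sample to a subject
#' and a condition, and an optional metabolite annotation table, then
#' assembles the metabolite x individual x condition tensor. The design must
#' be complete and paired: every subject needs exactly one sample per
#' condition. Samples present in the intensity table but absent from the
#' sample sheet are rejected.
#'
#' @param intensity_path Path to a TSV/CSV intensity matrix.
#' @param sample_sheet_path Path to a TSV/CSV with columns `sample_id`,
#'   `subject_id`, `condition`.
#' @param annotation_path Optional TSV/CSV with columns `metabolite_id`,
#'   `identified`, `super_pathway`.
#' @param sep Field separator (default tab).
#' @return An [intensity_tensor()].
#' @export
load_dataset <- function(intensity_path, sample_sheet_path,
                         annotation_path = NULL, sep = "\t") {
  for (p in c(intensity_path, sample_sheet_path, annotation_path))
    if (!file.exists(p)) config_error(sprintf("file not found: %s", p))

  intens <- utils::read.table(intensity_path, header = TRUE, sep = sep,
                              check.names = FALSE, stringsAsFactors = FALSE,
                              quote = "")
  sheet <- utils::read.table(sample_sheet_path, header = TRUE, sep = sep,
                             stringsAsFactors = FALSE, quote = "")
  need <- c("sample_id", "subject_id", "condition")
  if (!all(need %in% names(sheet)))
    format_error("sample sheet must have columns sample_id, subject_id, condition")

  met_ids <- as.character(intens[[1]])
  if (anyDuplicated(met_ids))
    format_error(sprintf("duplicate metabolite ID: %s",
                         met_ids[duplicated(met_ids)][1]))
  mat <- as.matrix(intens[, -1, drop = FALSE])
  if (!is.numeric(mat)) value_error("non-numeric intensity values")
  if (any(!is.finite(mat))) value_error("non-finite intensity values")
  if (any(mat < 0)) value_error("negative intensity values")

  sheet$condition <- normalize_condition(sheet$condition)
  unknown <- setdiff(colnames(mat), sheet$sample_id)
  if (length(unknown))
    format_error(sprintf("samples not in sample sheet: %s",
                         paste(unknown, collapse = ", ")))
  sheet <- sheet[sheet$sample_id %in% colnames(mat), , drop = FALSE]

  subjects <- unique(sheet$subject_id)
  for (s in subjects) {
    conds <- sort(sheet$condition[sheet$subject_id == s])
    if (!identical(conds, sort(conditions())))
      design_error(sprintf(
        "subject '%s' is unpaired: needs exactly one sample per condition", s))
  }

  G <- length(met_ids); N <- length(subjects)
  values <- array(NA_real_, c(G, N, 2))
  for (ci in 1:2) {
    cond <- conditions()[ci]
    for (ni in seq_len(N)) {
      sid <- sheet$sample_id[sheet$subject_id == subjects[ni] &
                               sheet$condition == cond]
      values[, ni, ci] <- mat[, sid]
    }
  }

  ann <- NULL
  if (!is.null(annotation_path)) {
    ann <- utils::read.table(annotation_path, header = TRUE, sep = sep,
                             stringsAsFactors = FALSE, quote = "")
    ann$identified <- as.logical(ann$identified)
  }
  intensity_tensor(values, met_ids, subjects, annotations = ann)
}

#' Write a dataset (and optional truth/config) as delimited text
#'
#' Writes the intensity table (sample columns named `<subject>_<condition>`),
#' the sample sheet, the annotation table if present, and — when supplied —
#' the planted truth table and the generator configuration as JSON. The
#' written files round-trip losslessly through [load_dataset()].
#'
#' @param tensor An [intensity_tensor()].
#' @param dir Output directory (created if needed).
#' @param truth Optional `planted_truth` to serialise alongside.
#' @param config Optional `synth_config` to serialise as JSON.
#' @return Invisibly, a named character vector of written paths.
#' @export
write_dataset <- function(tensor, dir, truth = NULL, config = NULL) {
  stopifnot(inherits(tensor, "intensity_tensor"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  N <- length(tensor$individual_ids)

  sample_ids <- c(paste0(tensor$individual_ids, "_", conditions()[1]),
                  paste0(tensor$individual_ids, "_", conditions()[2]))
  mat <- cbind(tensor$values[, , 1], tensor$values[, , 2])
  # 17 significant digits: doubles survive the text round-trip bit-exactly
  mat <- apply(mat, 2, function(v) sprintf("%.17g", v))
  colnames(mat) <- sample_ids
  df <- data.frame(metabolite_id = tensor$metabolite_ids, mat,
                   check.names = FALSE, stringsAsFactors = FALSE)
  paths <- c(intensity = file.path(dir, "intensities.tsv"),
             sample_sheet = file.path(dir, "sample_sheet.tsv"))
  utils::write.table(df, paths["intensity"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  sheet <- data.frame(sample_id = sample_ids,
                      subject_id = rep(tensor$individual_ids, 2),
                      condition = rep(conditions(), each = N),
                      stringsAsFactors = FALSE)
  utils::write.table(sheet, paths["sample_sheet"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(tensor$annotations)) {
    paths["annotation"] <- file.path(dir, "annotations.tsv")
    utils::write.table(tensor$annotations, paths["annotation"], sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(truth)) {
    paths["truth"] <- file.path(dir, "truth.tsv")
    tr <- data.frame(metabolite_id = truth$metabolite_ids,
                     module = unname(truth$module_assignment),
                     de_class = unname(truth$de_class),
                     true_lfc = sprintf("%.17g", unname(truth$true_lfc)),
                     stringsAsFactors = FALSE)
    utils::write.table(tr, paths["truth"], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths["dnm_module"] <- file.path(dir, "dnm_module.json")
    jsonlite::write_json(list(dnm_module = truth$dnm_module),
                         paths["dnm_module"], auto_unbox = TRUE, null = "null")
  }
  if (!is.null(config)) {
    paths["config"] <- file.path(dir, "synth_config.json")
    jsonlite::write_json(unclass(config), paths["config"], auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(paths)
}

#' Read a planted-truth table written by [write_dataset()]
#' @param dir Directory holding `truth.tsv` (and `dnm_module.json`).
#' @return A `planted_truth` object.
#' @export
read_truth <- function(dir) {
  path <- file.path(dir, "truth.tsv")
  if (!file.exists(path)) config_error(sprintf("file not found: %s", path))
  tr <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  dnm <- NA_integer_
  jp <- file.path(dir, "dnm_module.json")
  if (file.exists(jp)) {
    val <- jsonlite::read_json(jp)$dnm_module
    dnm <- if (is.null(val)) NA_integer_ else as.integer(val)
  }
  structure(list(metabolite_ids = tr$metabolite_id,
                 module_assignment = setNames(tr$module, tr$metabolite_id),
                 dnm_module = dnm,
                 de_class = setNames(tr$de_class, tr$metabolite_id),
                 true_lfc = setNames(tr$true_lfc, tr$metabolite_id)),
            class = "planted_truth")
}
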
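# Plain-text input/output: feature x sample TSV matrices (first column
# the feature id), sample metadata CSV, id lists, and JSON ground-truth
# objects.  Everything round-trips byte-identically for auditability.

#' Write a features-by-samples matrix as TSV
#'
#' @param x Numeric matrix with row names, or an [expr_set] /
#'   [metab_set] (values are taken from it; `NA` marks missing).
#' @param path Output path.
#' @param id_column Name of the first (feature id) column.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(x, path, id_column = "feature_id") {
  mat <- if (inherits(x, "expr_set")) x$values
  else if (inherits(x, "metab_set")) x$intensities
  else x
  stopifnot(is.matrix(mat))
  df <- data.frame(id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df[[1]]
  mat
}

#' Write sample metadata as CSV
#'
#' @param samples Data frame of per-sample metadata.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_samples_csv <- function(samples, path) {
  utils::write.csv(samples, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an expression set from TSV + metadata CSV
#'
#' @param matrix_path Features x samples TSV (first column feature id).
#' @param samples_path Sample metadata CSV with `sample_id`,
#'   `timepoint`, `replicate`, `group`.
#' @param unit Unit tag for the values.
#' @return An [expr_set].
#' @export
read_expression <- function(matrix_path, samples_path, unit = "au") {
  mat <- read_matrix_tsv(matrix_path)
  samples <- utils::read.csv(samples_path, stringsAsFactors = FALSE)
  samples <- samples[match(colnames(mat), samples$sample_id), , drop = FALSE]
  if (anyNA(samples$sample_id)) {
    stop("sample metadata does not cover every expression column", call. = FALSE)
  }
  expr_set(mat, samples, unit = unit)
}

#' Read a metabolite set from TSV + metadata CSV
#'
#' @param matrix_path Metabolites x samples TSV; empty/NA cells are
#'   missing values.
#' @param samples_path Sample metadata CSV with `sample_id`, `group`,
#'   `is_qc` (and optionally `timepoint`, `replicate`).
#' @param classes_path Optional CSV with `metabolite_id`, `class`.
#' @return A [metab_set].
#' @export
read_metabolome <- function(matrix_path, samples_path, classes_path = NULL) {
  mat <- read_matrix_tsv(matrix_path)
  samples <- utils::read.csv(samples_path, stringsAsFactors = FALSE)
  samples <- samples[match(colnames(mat), samples$sample_id), , drop = FALSE]
  if (anyNA(samples$sample_id)) {
    stop("sample metadata does not cover every metabolome column", call. = FALSE)
  }
  samples$is_qc <- as.logical(samples$is_qc)
  if (is.null(samples$timepoint)) samples$timepoint <- NA_real_
  if (is.null(samples$replicate)) samples$replicate <- NA_integer_
  classes <- character()
  if (!is.null(classes_path)) {
    cdf <- utils::read.csv(classes_path, stringsAsFactors = FALSE)
    classes <- stats::setNames(cdf$class, cdf$metabolite_id)
  }
  metab_set(mat, samples, classes)
}

#' Read an id list (one id per line)
#'
#' @param path Text file path.
#' @return Character vector.
#' @export
read_id_list <- function(path) {
  ids <- readLines(path)
  ids[nzchar(trimws(ids))]
}

#' Write an id list (one id per line)
#'
#' @param ids Character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_id_list <- function(ids, path) {
  writeLines(ids, path)
  invisible(path)
}

#' Write a simulated dataset as plain-text fixtures
#'
#' Writes the abundance TSV, the sample metadata CSV, and the planted
#' ground truth as JSON (class matrices reduced to index lists).
#'
#' @param sim Result of [simulate_hierarchy_expression()] or
#'   [simulate_metabolome()].
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix.
#' @return Named vector of written paths, invisibly.
#' @export
write_simulation <- function(sim, dir, prefix = "sim") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(matrix = file.path(dir, paste0(prefix, "_matrix.tsv")),
             samples = file.path(dir, paste0(prefix, "_samples.csv")),
             truth = file.path(dir, paste0(prefix, "_truth.json")))
  if (!is.null(sim$expr)) {
    write_matrix_tsv(sim$expr, paths["matrix"])
    write_samples_csv(sim$expr$samples, paths["samples"])
  } else {
    write_matrix_tsv(sim$metab, paths["matrix"], id_column = "metabolite_id")
    write_samples_csv(sim$metab$samples, paths["samples"])
    paths["classes"] <- file.path(dir, paste0(prefix, "_classes.csv"))
    utils::write.csv(
      data.frame(metabolite_id = names(sim$metab$classes),
                 class = unname(sim$metab$classes)),
      paths["classes"], row.names = FALSE, quote = FALSE)
  }
  truth <- unclass(sim$truth)
  if (!is.null(truth$missing_mask)) {
    truth$missing_cells <- which(truth$missing_mask, arr.ind = TRUE)
    truth$missing_mask <- NULL
  }
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
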
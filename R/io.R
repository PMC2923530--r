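# Readers, writers and validation for the tabular interchange formats.
# All tables are tab-separated UTF-8 with a header row; numeric columns are
# serialized at 17 significant digits so round trips are lossless.

PARTITIONS <- c("development", "abiotic", "biotic", "hormone")

#' Read and validate a sample metadata table
#'
#' The metadata table assigns each array (sample) to a study, a biological
#' replicate group and one of the four compendium partitions
#' (`development`, `abiotic`, `biotic`, `hormone`). Columns:
#' `sample_id`, `study_id`, `replicate_group`, `partition`.
#'
#' @param path Path to a TSV file.
#' @return A `data.frame` with the four character columns, validated.
#' @seealso [validate_metadata()]
#' @export
read_sample_metadata <- function(path) {
  meta <- utils::read.delim(path, stringsAsFactors = FALSE,
                            colClasses = "character")
  validate_metadata(meta)
}

#' Validate a sample metadata data.frame
#'
#' Checks required columns, uniqueness of `sample_id` and that every
#' `partition` value is one of the four recognised categories.
#'
#' @param meta A data.frame with columns `sample_id`, `study_id`,
#'   `replicate_group`, `partition`.
#' @return `meta`, invisibly validated (returned unchanged).
#' @export
validate_metadata <- function(meta) {
  required <- c("sample_id", "study_id", "replicate_group", "partition")
  missing <- setdiff(required, names(meta))
  if (length(missing))
    stop_("metadata is missing column(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(meta$sample_id))
    stop_("duplicated sample_id in metadata: ",
          paste(unique(meta$sample_id[duplicated(meta$sample_id)]),
                collapse = ", "))
  bad <- setdiff(unique(meta$partition), PARTITIONS)
  if (length(bad))
    stop_("unknown partition value(s): ", paste(bad, collapse = ", "),
          " (expected one of ", paste(PARTITIONS, collapse = ", "), ")")
  meta
}

#' Write a sample metadata table
#' @param meta Metadata data.frame (see [read_sample_metadata()]).
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_sample_metadata <- function(meta, path) {
  validate_metadata(meta)
  utils::write.table(meta, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a normalized expression matrix
#'
#' Expects a TSV whose first column (`probeset_id`) holds gene/probeset
#' identifiers and whose remaining columns are samples, holding linear-scale
#' normalized intensities (no missing cells, all values >= 0).
#'
#' @param path Path to a TSV file.
#' @param metadata Optional metadata data.frame; when supplied, every sample
#'   column must have a metadata row (unknown columns are a hard error
#'   naming the offending column).
#' @return A numeric matrix, genes in rows, samples in columns; row and
#'   column order preserved from the file.
#' @export
read_expression_matrix <- function(path, metadata = NULL) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2L)
    stop_("expression table needs a probeset_id column plus >= 1 sample")
  genes <- as.character(tab[[1L]])
  mat <- as.matrix(tab[, -1L, drop = FALSE])
  if (!is.numeric(mat)) {
    bad <- which(is.na(suppressWarnings(array(as.numeric(mat), dim(mat)))) &
                   !is.na(mat), arr.ind = TRUE)
    coord <- if (nrow(bad)) paste0(" first at row ", bad[1, 1],
                                   ", column ", colnames(mat)[bad[1, 2]])
             else ""
    stop_("non-numeric expression value(s);", coord)
  }
  storage.mode(mat) <- "double"
  rownames(mat) <- genes
  validate_expression_matrix(mat, metadata)
}

#' Validate an expression matrix against metadata
#'
#' @param mat Numeric matrix (genes x samples) with dimnames.
#' @param metadata Optional metadata data.frame.
#' @return `mat`, validated.
#' @export
validate_expression_matrix <- function(mat, metadata = NULL) {
  if (anyNA(mat)) {
    bad <- which(is.na(mat), arr.ind = TRUE)
    stop_("missing expression value at row ", rownames(mat)[bad[1, 1]],
          ", column ", colnames(mat)[bad[1, 2]])
  }
  if (any(mat < 0)) {
    bad <- which(mat < 0, arr.ind = TRUE)
    stop_("negative expression value at row ", rownames(mat)[bad[1, 1]],
          ", column ", colnames(mat)[bad[1, 2]])
  }
  if (!is.null(metadata)) {
    metadata <- validate_metadata(metadata)
    unknown <- setdiff(colnames(mat), metadata$sample_id)
    if (length(unknown))
      stop_("sample column(s) absent from metadata: ",
            paste(unknown, collapse = ", "))
  }
  mat
}

#' Write an expression matrix to TSV
#' @param mat Numeric matrix with gene rownames and sample colnames.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_expression_matrix <- function(mat, path) {
  out <- data.frame(probeset_id = rownames(mat),
                    apply(mat, 2L, fmt_full),
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a probe-level PM/MM table
#'
#' Long-format TSV with columns `probeset_id`, `probe_index`, `pm`, `mm`,
#' `sample_id`; PM/MM are strictly positive linear intensities and every
#' (probeset, sample) cell should carry at least 3 probe pairs for the
#' signed-rank detection test to be informative.
#'
#' @param path Path to a TSV file.
#' @return A validated data.frame.
#' @export
read_probe_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_probe_table(tab)
}

#' Validate a probe-level table
#' @param tab data.frame with columns `probeset_id`, `probe_index`, `pm`,
#'   `mm`, `sample_id`.
#' @return `tab`, validated.
#' @export
validate_probe_table <- function(tab) {
  required <- c("probeset_id", "probe_index", "pm", "mm", "sample_id")
  missing <- setdiff(required, names(tab))
  if (length(missing))
    stop_("probe table is missing column(s): ",
          paste(missing, collapse = ", "))
  if (any(!is.finite(tab$pm)) || any(!is.finite(tab$mm)) ||
      any(tab$pm <= 0) || any(tab$mm <= 0))
    stop_("pm and mm intensities must be finite and strictly positive")
  tab
}

#' Write a probe-level table to TSV
#' @param tab Probe-level data.frame.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_probe_table <- function(tab, path) {
  tab$pm <- fmt_full(tab$pm)
  tab$mm <- fmt_full(tab$mm)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a qPCR Ct table
#'
#' Gene x sample matrix of cycle-threshold values; blank cells are read as
#' missing ("not measured") and propagated as `NA`.
#'
#' @param path Path to a TSV with first column `gene_id` and one column per
#'   sample.
#' @return A numeric matrix with possible `NA`s.
#' @export
read_ct_table <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  genes <- as.character(tab[[1L]])
  mat <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- genes
  if (any(mat[!is.na(mat)] <= 0))
    stop_("Ct values must be positive where measured")
  mat
}

#' Write a qPCR Ct table
#' @param ct Numeric matrix (genes x samples), `NA` = not measured.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_ct_table <- function(ct, path) {
  out <- data.frame(gene_id = rownames(ct),
                    apply(ct, 2L, fmt_full),
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Write a stability table
#'
#' Serializes per-gene, per-partition mean/SD/CV rows. The `cv` column is
#' written at full precision; a `cv_display` column carries the
#' conventional 2-decimal rendering used in published reference-gene
#' tables.
#'
#' @param tab A stability table as returned by [stability_table()] or
#'   [partition_stats()].
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_stability_table <- function(tab, path) {
  cols <- c("gene_id", "partition", "mean", "sd", "cv")
  missing <- setdiff(cols, names(tab))
  if (length(missing))
    stop_("stability table is missing column(s): ",
          paste(missing, collapse = ", "))
  out <- data.frame(gene_id = tab$gene_id,
                    partition = tab$partition,
                    mean = fmt_full(tab$mean),
                    sd = fmt_full(tab$sd),
                    cv = fmt_full(tab$cv),
                    cv_display = sprintf("%.2f", tab$cv),
                    stringsAsFactors = FALSE)
  out$cv_display[is.na(tab$cv)] <- NA_character_
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a stability table written by [write_stability_table()]
#' @param path Path to the TSV.
#' @return A data.frame with columns `gene_id`, `partition`, `mean`, `sd`,
#'   `cv`, `cv_display`.
#' @export
read_stability_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c(gene_id = "character",
                                          partition = "character",
                                          cv_display = "character"))
  class(tab) <- c("stability_table", "data.frame")
  tab
}

#' Write detection calls and p-values
#' @param calls A `call_set` from [detection_calls()].
#' @param calls_path TSV path for the P/M/A letters.
#' @param p_path TSV path for the detection p-values.
#' @return Invisibly, `NULL`.
#' @export
write_call_set <- function(calls, calls_path, p_path) {
  stopifnot(inherits(calls, "call_set"))
  cl <- data.frame(probeset_id = rownames(calls$calls), calls$calls,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(cl, calls_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  pv <- data.frame(probeset_id = rownames(calls$p_value),
                   apply(calls$p_value, 2L, fmt_full),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(pv, p_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(NULL)
}

#' Curated rice reference-gene panel
#'
#' A panel of 26 candidate rice reference genes (plus secondary probesets
#' targeting the same loci) with their compendium-wide mean, standard
#' deviation, coefficient of variation (CV) and a qPCR-derived stability
#' value, as tabulated for the 373-array rice Affymetrix compendium. The
#' `source` column distinguishes novel stably expressed genes from
#' commonly used, previously suggested and orthology-derived candidates.
#' Used in tests and in the acceptance script to confirm that CV = SD/mean
#' reproduces the tabulated 2-decimal CVs.
#'
#' @return A data.frame with columns `gene`, `probeset_id`, `tigr_id`,
#'   `description`, `mean`, `sd`, `cv`, `mv`, `source`.
#' @export
reference_panel <- function() {
  path <- system.file("extdata", "rice_reference_panel.tsv",
                      package = "refstab", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(gene = "character"))
}
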
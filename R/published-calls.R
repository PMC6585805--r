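# md5 of the shipped transcription; guards against silent fixture corruption.
.published_calls_md5 <- "925ab4b3cfaea20cbc97383f4b8bd1e7"

#' Load the published per-peptide call table
#'
#' Returns the transcription of the published comparative kinome-profiling
#' call table for mesenchymal stromal cells adhering to an osteoblast-derived
#' extracellular matrix (ECM) versus a titanium surface: for each of the 67
#' peptides called on at least one substrate, the kinetic class
#' (early/mid/late) on ECM and on titanium, `none` meaning not called on that
#' substrate.
#'
#' The packaged copy is checksum-verified on load.
#'
#' @param path alternative TSV with columns `peptide_id`, `ecm_class`,
#'   `ti_class`; the packaged fixture when `NULL`.
#' @return data frame with those three columns.
#' @export
load_published_calls <- function(path = NULL) {
  packaged <- is.null(path)
  if (packaged) {
    path <- system.file("extdata", "published_calls.tsv", package = "kinomekin")
    if (!nzchar(path) || !file.exists(path)) {
      kk_integrity_error("packaged published-calls fixture is missing")
    }
    md5 <- unname(tools::md5sum(path))
    if (!identical(md5, .published_calls_md5)) {
      kk_integrity_error("published-calls fixture failed its checksum")
    }
  } else if (!file.exists(path)) {
    kk_io_error(sprintf("file not found: %s", path))
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("peptide_id", "ecm_class", "ti_class")
  if (!all(required %in% names(df))) {
    kk_format_error("published call table needs columns peptide_id, ecm_class, ti_class")
  }
  if (nrow(df) == 0L) kk_integrity_error("published call table is empty")
  ok <- c(kinetic_class_levels, "none")
  if (!all(df$ecm_class %in% ok) || !all(df$ti_class %in% ok)) {
    kk_format_error("call classes must be one of early/mid/late/none")
  }
  if (anyDuplicated(df$peptide_id)) {
    kk_validation_error("duplicate peptide_id in published call table")
  }
  if (any(df$ecm_class == "none" & df$ti_class == "none")) {
    kk_validation_error("every row must be called on at least one substrate")
  }
  df[required]
}

#' Convert the published call table to per-condition call rows
#'
#' Expands the two-substrate call table into the long call-table layout used
#' by [class_counts()] and [venn_overlap()]: one row per (condition, peptide)
#' that was called, with its kinetic class.
#'
#' @param published data frame from [load_published_calls()].
#' @param conditions labels for the two substrates, in (ECM, titanium) order.
#' @return data frame with columns `condition`, `peptide_id`,
#'   `kinetic_class`, `markov_positive` (all `TRUE`).
#' @export
published_as_calls <- function(published, conditions = c("ECM", "Ti")) {
  stopifnot(length(conditions) == 2L)
  rows <- lapply(1:2, function(i) {
    cls <- published[[c("ecm_class", "ti_class")[i]]]
    keep <- cls != "none"
    data.frame(condition = conditions[i],
               peptide_id = published$peptide_id[keep],
               kinetic_class = cls[keep],
               markov_positive = TRUE,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[kk_order(out$condition, out$peptide_id), , drop = FALSE]
}
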
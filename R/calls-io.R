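#' Write a call table to TSV
#'
#' Deterministic output: rows ordered by (condition, peptide id), numerics
#' formatted to 12 significant digits, so identical inputs yield
#' byte-identical files.
#'
#' @param calls a [markov_calls()] call table (or any data frame with the
#'   written columns).
#' @param path output TSV.
#' @export
write_calls_table <- function(calls, path) {
  cols <- c("peptide_id", "condition", "vmax_mean", "vmax_sd",
            "kinetic_class", "background_value", "markov_positive")
  missing_cols <- setdiff(cols, names(calls))
  if (length(missing_cols)) {
    kk_format_error(sprintf("call table is missing column(s): %s",
                            paste(missing_cols, collapse = ", ")))
  }
  df <- as.data.frame(calls)[cols]
  df <- df[kk_order(df$condition, df$peptide_id), , drop = FALSE]
  for (num in c("vmax_mean", "vmax_sd", "background_value")) {
    df[[num]] <- kk_num(df[[num]])
  }
  df$markov_positive <- ifelse(df$markov_positive, "TRUE", "FALSE")
  tryCatch(
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE),
    error = function(e) kk_io_error(sprintf("cannot write '%s': %s",
                                            path, conditionMessage(e))),
    warning = function(w) kk_io_error(sprintf("cannot write '%s': %s",
                                              path, conditionMessage(w))))
  invisible(path)
}

#' Read a call table written by [write_calls_table()]
#'
#' @param path TSV file.
#' @return data frame with the written columns and proper types.
#' @export
read_calls_table <- function(path) {
  if (!file.exists(path)) kk_io_error(sprintf("file not found: %s", path))
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(peptide_id = "character",
                                         condition = "character",
                                         vmax_mean = "numeric",
                                         vmax_sd = "numeric",
                                         kinetic_class = "character",
                                         background_value = "numeric",
                                         markov_positive = "logical"))
  required <- c("peptide_id", "condition", "vmax_mean", "vmax_sd",
                "kinetic_class", "background_value", "markov_positive")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    kk_format_error(sprintf("call table file is missing column(s): %s",
                            paste(missing_cols, collapse = ", ")))
  }
  df
}
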
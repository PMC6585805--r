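#' Validate a long-format kinetic dataset
#'
#' A kinetic dataset is a long-format data frame with one fluorescence reading
#' per row and columns `condition`, `peptide_id`, `replicate`, `time_s` and
#' `intensity`. One curve is the intensity time series of a single peptide
#' spot (peptide x technical replicate) under one condition. Validation
#' enforces: finite intensities, strictly increasing times with at least two
#' readings per curve, positive integer replicate indices, and a common time
#' grid for all curves within a condition.
#'
#' @param x data frame with the five columns above.
#' @param validate skip checks when `FALSE` (internal fast path for data the
#'   simulator constructed in canonical form).
#' @return the validated data frame, row-ordered by (condition, peptide_id,
#'   replicate, time_s), with class `kinetic_dataset`.
#' @export
as_kinetic_dataset <- function(x, validate = TRUE) {
  if (inherits(x, "kinetic_dataset") && !validate) return(x)
  if (!is.data.frame(x)) kk_validation_error("kinetic dataset must be a data frame")
  required <- c("condition", "peptide_id", "replicate", "time_s", "intensity")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols)) {
    kk_format_error(sprintf("kinetic table is missing column(s): %s",
                            paste(missing_cols, collapse = ", ")))
  }
  x <- as.data.frame(x)[required]
  if (nrow(x) == 0L) kk_validation_error("kinetic table contains no data rows")
  x$condition <- as.character(x$condition)
  x$peptide_id <- as.character(x$peptide_id)
  x$replicate <- as.integer(x$replicate)
  x$time_s <- as.numeric(x$time_s)
  x$intensity <- as.numeric(x$intensity)
  if (!validate) {
    class(x) <- c("kinetic_dataset", "data.frame")
    return(x)
  }
  if (anyNA(x$replicate) || any(x$replicate < 1L)) {
    kk_validation_error("replicate indices must be positive integers")
  }
  if (!all(is.finite(x$intensity))) kk_validation_error("intensities must be finite")
  if (!all(is.finite(x$time_s)) || any(x$time_s < 0)) {
    kk_validation_error("times must be finite and >= 0 seconds")
  }
  x <- x[kk_order(x$condition, x$peptide_id, x$replicate, x$time_s), , drop = FALSE]
  rownames(x) <- NULL
  key <- paste(x$condition, x$peptide_id, x$replicate, sep = "\r")
  curve_start <- key != c("", key[-length(key)])
  dup <- !curve_start & diff(c(x$time_s[1] - 1, x$time_s)) <= 0
  if (any(dup)) {
    i <- which(dup)[1]
    kk_validation_error(sprintf(
      "non-increasing times within curve (condition=%s, peptide_id=%s, replicate=%d)",
      x$condition[i], x$peptide_id[i], x$replicate[i]))
  }
  lens <- rle(key)$lengths
  if (any(lens < 2L)) {
    i <- cumsum(lens)[which(lens < 2L)[1]]
    kk_validation_error(sprintf(
      "curve with fewer than 2 readings (condition=%s, peptide_id=%s, replicate=%d)",
      x$condition[i], x$peptide_id[i], x$replicate[i]))
  }
  for (cond in unique(x$condition)) {
    times <- x$time_s[x$condition == cond]
    grid <- times[seq_len(lens[match(TRUE, x$condition[cumsum(lens)] == cond)])]
    # all curves of a condition must repeat the first curve's grid
    ncurve <- length(times) / length(grid)
    if (ncurve != round(ncurve) ||
        !isTRUE(all.equal(times, rep(grid, ncurve), check.attributes = FALSE))) {
      kk_validation_error(sprintf(
        "curves within condition '%s' do not share a common time grid", cond))
    }
  }
  class(x) <- c("kinetic_dataset", "data.frame")
  x
}

#' Read a long-format kinetic intensity table
#'
#' @param path CSV or TSV file with header
#'   `condition,peptide_id,replicate,time_s,intensity`; `time_s` in seconds,
#'   `intensity` in arbitrary fluorescence units.
#' @param dialect `"auto"` picks the separator from the file extension
#'   (`.tsv`/`.tab` are tab-separated, anything else comma-separated).
#' @return a validated [as_kinetic_dataset()] data frame.
#' @export
read_kinetics_table <- function(path, dialect = c("auto", "csv", "tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) kk_io_error(sprintf("file not found: %s", path))
  if (dialect == "auto") {
    dialect <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "tsv" else "csv"
  }
  sep <- if (dialect == "tsv") "\t" else ","
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                      check.names = FALSE),
    error = function(e) kk_validation_error(sprintf("cannot parse '%s': %s",
                                                    path, conditionMessage(e))))
  as_kinetic_dataset(df)
}

#' Write a kinetic dataset back to CSV/TSV
#'
#' Inverse of [read_kinetics_table()]; round-trips a dataset up to floating
#' point formatting.
#'
#' @param data a kinetic dataset.
#' @param path output file; extension selects the separator as in
#'   [read_kinetics_table()].
#' @export
write_kinetics_table <- function(data, path) {
  data <- as_kinetic_dataset(data)
  sep <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  out <- tryCatch(
    utils::write.table(as.data.frame(data), path, sep = sep, quote = FALSE,
                       row.names = FALSE),
    error = function(e) kk_io_error(sprintf("cannot write '%s': %s",
                                            path, conditionMessage(e))))
  invisible(path)
}

#' @export
print.kinetic_dataset <- function(x, ...) {
  conds <- unique(x$condition)
  cat(sprintf("Kinetic dataset: %d conditions (%s), %d peptides, %d readings\n",
              length(conds), paste(conds, collapse = ", "),
              length(unique(x$peptide_id)), nrow(x)))
  invisible(x)
}
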
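#' @keywords internal
"_PACKAGE"

`%||%` <- function(x, y) if (is.null(x)) y else x

# Classed conditions so callers can distinguish malformed files (format),
# contract violations (validation), corrupted fixtures (integrity) and
# filesystem failures (io).
kk_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "kinomekin_error")))
}
kk_validation_error <- function(msg) kk_stop(msg, "kk_validation_error")
kk_format_error     <- function(msg) kk_stop(msg, "kk_format_error")
kk_integrity_error  <- function(msg) kk_stop(msg, "kk_integrity_error")
kk_io_error         <- function(msg) kk_stop(msg, "kk_io_error")

# Locale-independent ordering (C collation) used everywhere determinism of
# row order or tie-breaking matters.
kk_order <- function(...) order(..., method = "radix")
kk_sort <- function(x) sort(x, method = "radix")

# Fixed-precision numeric formatting (12 significant digits) so repeated
# writes of identical results are byte-identical.
kk_num <- function(x) {
  out <- formatC(x, digits = 12, format = "g")
  out[is.na(x)] <- "NA"
  trimws(out)
}

kinetic_class_levels <- c("early", "mid", "late")
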
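#' Kinetic analysis windows
#'
#' Three contiguous equal-width windows starting at the kinase reaction
#' start (640 s): early 640-1040 s, mid 1040-1440 s, late 1440-1840 s.
#' Windows are closed intervals, so a reading at exactly 1040 s belongs to
#' both the early and the mid window.
#'
#' @param reaction_start reaction start time, seconds.
#' @param width window width, seconds.
#' @return list with elements `early`, `mid`, `late` (each `c(lo, hi)`) and
#'   `reaction_start`; class `kinetic_windows`.
#' @export
kinetic_windows <- function(reaction_start = 640, width = 400) {
  if (width <= 0) kk_validation_error("window width must be > 0")
  b <- reaction_start + width * 0:3
  structure(list(early = c(b[1], b[2]), mid = c(b[2], b[3]),
                 late = c(b[3], b[4]), reaction_start = reaction_start),
            class = "kinetic_windows")
}

# Window slopes for a curve matrix (rows = curves sharing one time grid).
# >= 2 in-window readings: OLS slope of intensity on time over those
# readings; sparse fallback: difference quotient of the linearly
# interpolated curve between the window edges (clamped at the grid ends).
window_slopes_matrix <- function(Y, times, window) {
  lo <- window[1]; hi <- window[2]
  if (lo >= hi) kk_validation_error("window must satisfy t_lo < t_hi")
  if (hi < times[1] || lo > times[length(times)]) {
    kk_validation_error("window lies entirely outside the observed time range")
  }
  idx <- which(times >= lo & times <= hi)
  if (length(idx) >= 2L) {
    tt <- times[idx]
    ct <- tt - mean(tt)
    drop(Y[, idx, drop = FALSE] %*% (ct / sum(ct^2)))
  } else {
    (interp_columns(Y, times, hi) - interp_columns(Y, times, lo)) / (hi - lo)
  }
}

# Linear interpolation of each row of Y at time t, clamping outside the grid.
interp_columns <- function(Y, times, t) {
  n <- length(times)
  if (t <= times[1]) return(Y[, 1])
  if (t >= times[n]) return(Y[, n])
  j <- findInterval(t, times)
  w <- (t - times[j]) / (times[j + 1] - times[j])
  (1 - w) * Y[, j] + w * Y[, j + 1]
}

#' Tangent (slope) of a kinetic curve within a time window
#'
#' The apparent maximal velocity over a window is estimated as the ordinary
#' least-squares slope of intensity versus time over the readings falling in
#' the closed window. When the window holds fewer than two readings (sparse
#' grids) the slope falls back to the difference quotient of the linearly
#' interpolated curve between the window edges.
#'
#' @param times strictly increasing reading times, seconds.
#' @param intensities intensities at `times`, AU.
#' @param window `c(t_lo, t_hi)` in seconds.
#' @return slope in AU/s.
#' @export
window_slope <- function(times, intensities, window) {
  if (length(times) != length(intensities) || length(times) < 2L) {
    kk_validation_error("curve needs equal-length times/intensities with >= 2 readings")
  }
  if (is.unsorted(times, strictly = TRUE)) {
    kk_validation_error("times must be strictly increasing")
  }
  window_slopes_matrix(matrix(intensities, nrow = 1L), times, window)
}

#' Assign a kinetic class from the three window slopes
#'
#' The class is the window with the steepest replicate-averaged rise; exact
#' ties break toward the earlier window. This is the deterministic
#' replacement for classifying curve shapes by visual inspection.
#'
#' @param slopes numeric length-3 vector of (early, mid, late) slopes.
#' @return `"early"`, `"mid"` or `"late"`.
#' @export
classify_kinetics <- function(slopes) {
  if (length(slopes) != 3L || !all(is.finite(slopes))) {
    kk_validation_error("classification needs three finite window slopes")
  }
  kinetic_class_levels[which.max(slopes)]
}

#' Aggregate per-replicate Vmax with zero-clipping
#'
#' Replicate slopes below zero are artificially set to zero before
#' averaging; a peptide is `considered` for calling only when its clipped
#' replicate mean is above zero. SD is the sample SD (n - 1), zero for a
#' single replicate.
#'
#' @param slopes per-replicate class-window slopes, AU/s.
#' @return list with `vmax_mean`, `vmax_sd`, `considered`.
#' @export
aggregate_vmax <- function(slopes) {
  if (length(slopes) == 0L) kk_validation_error("need at least one replicate slope")
  v <- pmax(slopes, 0)
  m <- mean(v)
  s <- if (length(v) > 1L) stats::sd(v) else 0
  list(vmax_mean = m, vmax_sd = s, considered = m > 0)
}

#' Per-peptide windowed Vmax statistics
#'
#' For every (condition, analyte peptide): per-replicate slopes in the three
#' kinetic windows, a kinetic class from the replicate-mean slopes, and the
#' zero-clipped mean/SD of the class-window slope across replicates. The
#' internal positive control (ids matching `control_pattern`) is excluded
#' from all analysis.
#'
#' @param data a kinetic dataset.
#' @param windows a [kinetic_windows()].
#' @param control_pattern regular expression identifying the internal
#'   positive control peptide(s).
#' @return data frame (class `vmax_table`) with columns `condition`,
#'   `peptide_id`, `slope_early`, `slope_mid`, `slope_late` (replicate
#'   means), `kinetic_class`, `vmax_mean`, `vmax_sd`, `n_replicates`,
#'   `considered`.
#' @export
vmax_table <- function(data, windows = kinetic_windows(),
                       control_pattern = "^ART_003") {
  data <- as_kinetic_dataset(data)
  d <- data[!grepl(control_pattern, data$peptide_id), , drop = FALSE]
  if (nrow(d) == 0L) kk_validation_error("no analyte peptides in dataset")
  conds <- kk_sort(unique(d$condition))
  peps_all <- kk_sort(unique(d$peptide_id))
  missing <- lapply(conds, function(cc)
    setdiff(peps_all, unique(d$peptide_id[d$condition == cc])))
  if (any(lengths(missing) > 0L)) {
    bad <- unique(unlist(missing))
    kk_validation_error(sprintf("peptide(s) missing in some condition: %s",
                                paste(kk_sort(bad), collapse = ", ")))
  }
  out <- lapply(conds, function(cc) {
    dd <- d[d$condition == cc, , drop = FALSE]
    grid <- sort(unique(dd$time_s))
    nt <- length(grid)
    ord <- kk_order(dd$peptide_id, dd$replicate, dd$time_s)
    dd <- dd[ord, , drop = FALSE]
    key <- paste(dd$peptide_id, dd$replicate, sep = "\r")
    ukey <- unique(key)
    Y <- matrix(dd$intensity, nrow = length(ukey), ncol = nt, byrow = TRUE)
    pep_of_row <- dd$peptide_id[seq(1L, nrow(dd), by = nt)]
    S <- vapply(list(windows$early, windows$mid, windows$late),
                function(w) window_slopes_matrix(Y, grid, w),
                numeric(length(ukey)))
    reps <- as.vector(table(factor(pep_of_row, levels = unique(pep_of_row))))
    M <- rowsum(S, pep_of_row, reorder = TRUE) /
      reps[kk_order(unique(pep_of_row))]
    peps <- rownames(M)
    cls_idx <- max.col(M, ties.method = "first")
    vr <- pmax(S[cbind(seq_len(nrow(S)), cls_idx[match(pep_of_row, peps)])], 0)
    n <- as.vector(rowsum(rep(1, length(vr)), pep_of_row, reorder = TRUE))
    vm <- as.vector(rowsum(vr, pep_of_row, reorder = TRUE)) / n
    ss <- as.vector(rowsum(vr^2, pep_of_row, reorder = TRUE))
    vsd <- ifelse(n > 1L, sqrt(pmax(ss - n * vm^2, 0) / (n - 1L)), 0)
    data.frame(condition = cc, peptide_id = peps,
               slope_early = M[, 1], slope_mid = M[, 2], slope_late = M[, 3],
               kinetic_class = kinetic_class_levels[cls_idx],
               vmax_mean = vm, vmax_sd = vsd, n_replicates = n,
               considered = vm > 0,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  out <- do.call(rbind, out)
  class(out) <- c("vmax_table", "data.frame")
  out
}
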
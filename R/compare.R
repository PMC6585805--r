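#' Area under a kinetic curve
#'
#' Trapezoidal integral of intensity versus time from `from_time` (default
#' the 640 s reaction start) to the last reading. When `from_time` falls
#' between readings the curve is linearly interpolated there, which keeps
#' the integral additive over adjacent intervals.
#'
#' @param times strictly increasing reading times, seconds.
#' @param intensities intensities at `times`, AU (typically the
#'   replicate-mean curve).
#' @param from_time integration start, seconds.
#' @return area in AU*s.
#' @export
curve_auc <- function(times, intensities, from_time = 640) {
  if (length(times) != length(intensities)) {
    kk_validation_error("times and intensities must have equal length")
  }
  if (is.unsorted(times, strictly = TRUE)) {
    kk_validation_error("times must be strictly increasing")
  }
  if (sum(times >= from_time) < 2L) {
    kk_validation_error("need at least 2 readings at or after from_time")
  }
  if (from_time > times[1] && !any(times == from_time)) {
    keep <- times >= from_time
    y0 <- interp_columns(matrix(intensities, nrow = 1L), times, from_time)
    times <- c(from_time, times[keep])
    intensities <- c(y0, intensities[keep])
  } else {
    keep <- times >= from_time
    times <- times[keep]
    intensities <- intensities[keep]
  }
  dt <- diff(times)
  sum(dt * (intensities[-length(intensities)] + intensities[-1]) / 2)
}

#' Two-set overlap partition
#'
#' @param calls_a,calls_b character vectors of positive peptide ids.
#' @return list with `n_both`, `n_a_only`, `n_b_only` and the sorted member
#'   vectors `both`, `a_only`, `b_only`.
#' @export
venn_overlap <- function(calls_a, calls_b) {
  a <- unique(as.character(calls_a))
  b <- unique(as.character(calls_b))
  both <- kk_sort(intersect(a, b))
  a_only <- kk_sort(setdiff(a, b))
  b_only <- kk_sort(setdiff(b, a))
  list(n_both = length(both), n_a_only = length(a_only),
       n_b_only = length(b_only), both = both, a_only = a_only,
       b_only = b_only)
}

#' Count positive calls per kinetic class
#'
#' @param calls a call table (any data frame with `condition`,
#'   `kinetic_class` and `markov_positive` columns).
#' @return integer matrix, conditions x (early, mid, late), counting
#'   Markov-positive peptides; column sums over an empty table are zero.
#' @export
class_counts <- function(calls) {
  required <- c("condition", "kinetic_class", "markov_positive")
  if (!all(required %in% names(calls))) {
    kk_format_error("call table needs condition, kinetic_class, markov_positive")
  }
  pos <- calls[calls$markov_positive, , drop = FALSE]
  conds <- kk_sort(unique(pos$condition))
  m <- table(factor(pos$condition, levels = conds),
             factor(pos$kinetic_class, levels = kinetic_class_levels))
  matrix(as.integer(m), nrow = length(conds), ncol = 3L,
         dimnames = list(conds, kinetic_class_levels))
}

# Replicate-mean curves of one condition as a peptide x time matrix.
mean_curves <- function(data, condition) {
  dd <- data[data$condition == condition, , drop = FALSE]
  grid <- sort(unique(dd$time_s))
  agg <- rowsum(dd$intensity, paste(dd$peptide_id, dd$time_s, sep = "\r"))
  cnt <- rowsum(rep(1, nrow(dd)), paste(dd$peptide_id, dd$time_s, sep = "\r"))
  keys <- strsplit(rownames(agg), "\r", fixed = TRUE)
  pep <- vapply(keys, `[`, "", 1L)
  tt <- as.numeric(vapply(keys, `[`, "", 2L))
  peps <- kk_sort(unique(pep))
  Y <- matrix(NA_real_, length(peps), length(grid),
              dimnames = list(peps, NULL))
  Y[cbind(match(pep, peps), match(tt, grid))] <- agg / cnt
  list(peptides = peps, times = grid, Y = Y)
}

#' Compare kinase activity between two conditions
#'
#' Computes the per-peptide AUC of the replicate-mean kinetic curve from the
#' reaction start in each condition, pairs the AUCs over the peptides
#' selected by `pairing` (default: the intersection of the two
#' Markov-positive sets, the only choice under which both members of a pair
#' carry a call), applies the Wilcoxon matched-pairs signed-rank test, and
#' attaches the overlap partition and per-class call counts.
#'
#' @param x a kinetic dataset (then supply `calls_a` and `calls_b`) or a
#'   [kinome_profile()] (then name the two conditions).
#' @param ... passed between methods.
#' @return object of class `kinome_comparison`; see Details.
#' @details The result carries `auc_a`/`auc_b` (named vectors over the
#'   pairing set), their means and SDs, the `wilcoxon` test object, the
#'   `venn` partition of the positive sets, and the `class_counts` matrix.
#' @export
compare_conditions <- function(x, ...) UseMethod("compare_conditions")

#' @param calls_a,calls_b call tables for the two conditions (rows of a
#'   [markov_calls()] result).
#' @param pairing `"intersection"`, `"union"` or `"all"` — which peptides
#'   enter the paired AUC comparison.
#' @param from_time integration start, seconds; defaults to the 640 s
#'   reaction start.
#' @rdname compare_conditions
#' @export
compare_conditions.kinetic_dataset <- function(x, calls_a, calls_b,
                                               pairing = c("intersection", "union", "all"),
                                               from_time = 640, ...) {
  pairing <- match.arg(pairing)
  cond_a <- unique(calls_a$condition)
  cond_b <- unique(calls_b$condition)
  if (length(cond_a) != 1L || length(cond_b) != 1L || cond_a == cond_b) {
    kk_validation_error("calls_a and calls_b must each cover one distinct condition")
  }
  pos_a <- calls_a$peptide_id[calls_a$markov_positive]
  pos_b <- calls_b$peptide_id[calls_b$markov_positive]
  pair_set <- switch(pairing,
                     intersection = intersect(pos_a, pos_b),
                     union = union(pos_a, pos_b),
                     all = union(calls_a$peptide_id, calls_b$peptide_id))
  pair_set <- kk_sort(pair_set)
  if (length(pair_set) == 0L) {
    kk_validation_error("pairing set is empty; no peptides to compare")
  }
  mc_a <- mean_curves(x, cond_a)
  mc_b <- mean_curves(x, cond_b)
  if (!all(pair_set %in% mc_a$peptides) || !all(pair_set %in% mc_b$peptides)) {
    kk_validation_error("paired peptides missing from the dataset")
  }
  auc_of <- function(mc) {
    vapply(pair_set, function(p)
      curve_auc(mc$times, mc$Y[p, ], from_time), numeric(1))
  }
  auc_a <- auc_of(mc_a)
  auc_b <- auc_of(mc_b)
  wil <- paired_signed_rank(auc_a, auc_b)
  calls_both <- rbind(as.data.frame(calls_a), as.data.frame(calls_b))
  res <- list(condition_a = cond_a, condition_b = cond_b, pairing = pairing,
              peptides = pair_set, auc_a = auc_a, auc_b = auc_b,
              mean_auc_a = mean(auc_a), mean_auc_b = mean(auc_b),
              sd_auc_a = stats::sd(auc_a), sd_auc_b = stats::sd(auc_b),
              wilcoxon_statistic = unname(wil$statistic),
              p_value = wil$p.value, wilcoxon = wil,
              venn = venn_overlap(pos_a, pos_b),
              class_counts = class_counts(calls_both),
              from_time = from_time)
  class(res) <- "kinome_comparison"
  res
}

#' @param condition_a,condition_b condition labels to compare (A vs B);
#'   default the first two conditions of the profile.
#' @rdname compare_conditions
#' @export
compare_conditions.kinome_profile <- function(x, condition_a = NULL,
                                              condition_b = NULL,
                                              pairing = c("intersection", "union", "all"),
                                              from_time = NULL, ...) {
  conds <- kk_sort(unique(x$calls$condition))
  condition_a <- condition_a %||% conds[1]
  condition_b <- condition_b %||% conds[2]
  if (!all(c(condition_a, condition_b) %in% conds)) {
    kk_validation_error("requested conditions are not present in the profile")
  }
  compare_conditions.kinetic_dataset(
    x$data,
    calls_a = x$calls[x$calls$condition == condition_a, , drop = FALSE],
    calls_b = x$calls[x$calls$condition == condition_b, , drop = FALSE],
    pairing = pairing,
    from_time = from_time %||% x$windows$reaction_start)
}

#' @export
print.kinome_comparison <- function(x, digits = 4, ...) {
  cat(sprintf("Kinome comparison: %s vs %s (pairing: %s, %d peptides)\n",
              x$condition_a, x$condition_b, x$pairing, length(x$peptides)))
  cat(sprintf("  AUC %s: %.*g +/- %.*g   AUC %s: %.*g +/- %.*g\n",
              x$condition_a, digits, x$mean_auc_a, digits, x$sd_auc_a,
              x$condition_b, digits, x$mean_auc_b, digits, x$sd_auc_b))
  cat(sprintf("  Wilcoxon signed-rank V = %g, p = %.3g\n",
              x$wilcoxon_statistic, x$p_value))
  cat(sprintf("  Calls: %d both, %d %s-only, %d %s-only\n",
              x$venn$n_both, x$venn$n_a_only, x$condition_a,
              x$venn$n_b_only, x$condition_b))
  invisible(x)
}
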
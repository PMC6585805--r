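#' Rank-background linear trend
#'
#' Peptides are ranked ascending by mean Vmax (ties broken alphabetically by
#' peptide id so the ranking is deterministic) and an ordinary least-squares
#' line of Vmax versus rank is fitted over the lowest `n_background`
#' peptides, which are treated as unphosphorylated background. The returned
#' line can be evaluated at any rank via [predict.background_trend()].
#'
#' @param vmax_mean per-peptide mean Vmax values, AU/s.
#' @param peptide_id ids used for deterministic tie-breaking.
#' @param n_background number of lowest-ranked peptides defining background.
#' @return list with `intercept`, `slope` (per rank), `n_background`;
#'   class `background_trend`.
#' @export
background_trend <- function(vmax_mean, peptide_id = NULL, n_background = 60) {
  n <- length(vmax_mean)
  if (is.null(peptide_id)) peptide_id <- sprintf("%06d", seq_len(n))
  if (n_background < 1L || n_background > n) {
    kk_validation_error(sprintf(
      "n_background (%d) must be between 1 and the number of peptides (%d)",
      n_background, n))
  }
  ord <- kk_order(vmax_mean, peptide_id)
  y <- vmax_mean[ord][seq_len(n_background)]
  x <- seq_len(n_background)
  cx <- x - mean(x)
  slope <- if (n_background > 1L) sum(cx * (y - mean(y))) / sum(cx^2) else 0
  structure(list(intercept = mean(y) - slope * mean(x), slope = slope,
                 n_background = as.integer(n_background)),
            class = "background_trend")
}

#' Evaluate a background trend at given ranks
#'
#' @param object a [background_trend()].
#' @param rank rank position(s) to evaluate at.
#' @param ... unused.
#' @return background Vmax value(s), AU/s.
#' @export
predict.background_trend <- function(object, rank, ...) {
  object$intercept + object$slope * rank
}

#' @export
print.background_trend <- function(x, ...) {
  cat(sprintf("Background trend over lowest %d ranks: intercept %.4g, slope %.4g per rank\n",
              x$n_background, x$intercept, x$slope))
  invisible(x)
}

#' Markov-positive on/off calls from Vmax statistics
#'
#' The calling rule of the array analysis: per condition, peptides are
#' ranked ascending by mean Vmax and a linear background trend is fitted to
#' the lowest `n_background` peptides. A peptide is a Markov-positive "on"
#' call when it is considered (mean Vmax above zero) and its mean Vmax minus
#' `sd_multiplier` times its replicate SD exceeds the background signal. By
#' default the background signal is the trend evaluated at the peptide's own
#' rank; `background_eval = "fixed_rank"` instead uses the trend value at
#' rank `n_background` for every peptide.
#'
#' @param stats a [vmax_table()] (one or more conditions).
#' @param n_background lowest-ranked peptides used as background.
#' @param sd_multiplier SD multiplier of the rule (>= 0).
#' @param background_eval `"at_rank"` (default) or `"fixed_rank"`.
#' @return data frame (class `call_table`) with columns `condition`,
#'   `peptide_id`, `vmax_mean`, `vmax_sd`, `kinetic_class`, `rank`,
#'   `background_value`, `considered`, `markov_positive`; per-condition
#'   trends in the `"trend"` attribute.
#' @export
markov_calls <- function(stats, n_background = 60, sd_multiplier = 1.95,
                         background_eval = c("at_rank", "fixed_rank")) {
  background_eval <- match.arg(background_eval)
  if (sd_multiplier < 0) kk_validation_error("sd_multiplier must be >= 0")
  required <- c("condition", "peptide_id", "vmax_mean", "vmax_sd",
                "kinetic_class", "considered")
  missing_cols <- setdiff(required, names(stats))
  if (length(missing_cols)) {
    kk_format_error(sprintf("Vmax table is missing column(s): %s",
                            paste(missing_cols, collapse = ", ")))
  }
  conds <- kk_sort(unique(stats$condition))
  trends <- list()
  out <- lapply(conds, function(cc) {
    s <- stats[stats$condition == cc, , drop = FALSE]
    if (anyDuplicated(s$peptide_id)) {
      kk_validation_error(sprintf("duplicate peptide in condition '%s'", cc))
    }
    if (n_background >= nrow(s)) {
      kk_validation_error("n_background must be smaller than the number of peptides")
    }
    ord <- kk_order(s$vmax_mean, s$peptide_id)
    rank <- integer(nrow(s))
    rank[ord] <- seq_len(nrow(s))
    trend <- background_trend(s$vmax_mean, s$peptide_id, n_background)
    trends[[cc]] <<- trend
    bg <- switch(background_eval,
                 at_rank = predict(trend, rank),
                 fixed_rank = rep(predict(trend, n_background), nrow(s)))
    pos <- s$considered & (s$vmax_mean - sd_multiplier * s$vmax_sd) > bg
    res <- data.frame(condition = s$condition, peptide_id = s$peptide_id,
                      vmax_mean = s$vmax_mean, vmax_sd = s$vmax_sd,
                      kinetic_class = s$kinetic_class, rank = rank,
                      background_value = bg, considered = s$considered,
                      markov_positive = pos, stringsAsFactors = FALSE)
    res[kk_order(res$peptide_id), , drop = FALSE]
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  attr(out, "trend") <- trends
  attr(out, "params") <- list(n_background = n_background,
                              sd_multiplier = sd_multiplier,
                              background_eval = background_eval)
  class(out) <- c("call_table", "data.frame")
  out
}
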
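#' Fit a kinome activity profile from kinetic array data
#'
#' The central fitting routine: from a long-format kinetic dataset it
#' estimates per-peptide windowed Vmax values ([vmax_table()]) and applies
#' the rank-background calling rule ([markov_calls()]) independently per
#' condition, returning a fitted profile object with print, summary, coef
#' and plot methods.
#'
#' @param data a kinetic dataset (or data frame coercible via
#'   [as_kinetic_dataset()]).
#' @param windows a [kinetic_windows()].
#' @param n_background,sd_multiplier,background_eval calling-rule settings,
#'   see [markov_calls()].
#' @param control_pattern regex for the excluded internal positive control.
#' @return object of class `kinome_profile` with components `calls` (the
#'   call table), `vmax` (the Vmax table), `trend` (per-condition background
#'   trends), `windows`, `params` and the `data` used.
#' @examples
#' sim <- simulate_dataset(sim_config(seed = 1))
#' fit <- kinome_profile(sim$dataset)
#' summary(fit)
#' @export
kinome_profile <- function(data, windows = kinetic_windows(),
                           n_background = 60, sd_multiplier = 1.95,
                           background_eval = c("at_rank", "fixed_rank"),
                           control_pattern = "^ART_003") {
  background_eval <- match.arg(background_eval)
  data <- as_kinetic_dataset(data)
  vm <- vmax_table(data, windows, control_pattern)
  calls <- markov_calls(vm, n_background = n_background,
                        sd_multiplier = sd_multiplier,
                        background_eval = background_eval)
  structure(list(calls = calls, vmax = vm, trend = attr(calls, "trend"),
                 windows = windows,
                 params = list(n_background = n_background,
                               sd_multiplier = sd_multiplier,
                               background_eval = background_eval,
                               control_pattern = control_pattern),
                 data = data, call = match.call()),
            class = "kinome_profile")
}

#' @export
print.kinome_profile <- function(x, ...) {
  conds <- kk_sort(unique(x$calls$condition))
  cat("Kinome activity profile\n")
  for (cc in conds) {
    cl <- x$calls[x$calls$condition == cc, ]
    cat(sprintf("  %s: %d/%d peptides Markov-positive\n",
                cc, sum(cl$markov_positive), nrow(cl)))
  }
  cat(sprintf("  calling rule: mean Vmax - %.4g x SD > background trend (lowest %d ranks)\n",
              x$params$sd_multiplier, x$params$n_background))
  invisible(x)
}

#' @export
summary.kinome_profile <- function(object, ...) {
  cc <- class_counts(object$calls)
  conds <- rownames(cc)
  pos <- vapply(conds, function(c1)
    sum(object$calls$markov_positive[object$calls$condition == c1]), 0L)
  out <- list(class_counts = cc, n_positive = pos,
              n_peptides = length(unique(object$calls$peptide_id)),
              params = object$params)
  if (length(conds) >= 2L) {
    c1 <- object$calls[object$calls$condition == conds[1], ]
    c2 <- object$calls[object$calls$condition == conds[2], ]
    out$venn <- venn_overlap(c1$peptide_id[c1$markov_positive],
                             c2$peptide_id[c2$markov_positive])
    out$conditions <- conds[1:2]
  }
  class(out) <- "summary.kinome_profile"
  out
}

#' @export
print.summary.kinome_profile <- function(x, ...) {
  cat(sprintf("Kinome profile of %d analyte peptides\n", x$n_peptides))
  cat("Markov-positive calls per kinetic class:\n")
  print(cbind(x$class_counts, total = x$n_positive))
  if (!is.null(x$venn)) {
    cat(sprintf("Overlap (%s vs %s): %d both, %d %s-only, %d %s-only\n",
                x$conditions[1], x$conditions[2], x$venn$n_both,
                x$venn$n_a_only, x$conditions[1],
                x$venn$n_b_only, x$conditions[2]))
  }
  invisible(x)
}

#' Mean Vmax matrix of a fitted profile
#'
#' @param object a [kinome_profile()].
#' @param ... unused.
#' @return numeric matrix, peptides x conditions, of zero-clipped mean Vmax
#'   (AU/s).
#' @export
coef.kinome_profile <- function(object, ...) {
  calls <- object$calls
  peps <- kk_sort(unique(calls$peptide_id))
  conds <- kk_sort(unique(calls$condition))
  m <- matrix(NA_real_, length(peps), length(conds),
              dimnames = list(peps, conds))
  m[cbind(match(calls$peptide_id, peps), match(calls$condition, conds))] <-
    calls$vmax_mean
  m
}

#' Rank-vs-Vmax diagnostic plot
#'
#' One panel per condition: peptides ordered by ascending mean Vmax, the
#' fitted background trend as a line, positive calls highlighted. This is
#' the standard diagnostic for the rank-background calling rule.
#'
#' @param x a [kinome_profile()].
#' @param conditions subset of conditions to draw; all by default.
#' @param ... passed to [graphics::plot()].
#' @export
plot.kinome_profile <- function(x, conditions = NULL, ...) {
  conds <- conditions %||% kk_sort(unique(x$calls$condition))
  old <- graphics::par(mfrow = c(1, length(conds)))
  on.exit(graphics::par(old))
  for (cc in conds) {
    cl <- x$calls[x$calls$condition == cc, ]
    ord <- order(cl$rank)
    cl <- cl[ord, ]
    graphics::plot(cl$rank, cl$vmax_mean, pch = 16, cex = 0.6,
                   col = ifelse(cl$markov_positive, "firebrick", "grey40"),
                   xlab = "Vmax rank", ylab = "mean Vmax (AU/s)",
                   main = cc, ...)
    tr <- x$trend[[cc]]
    graphics::abline(tr$intercept, tr$slope, col = "steelblue", lwd = 2)
    graphics::legend("topleft", bty = "n",
                     legend = c("Markov-positive", "negative", "background trend"),
                     col = c("firebrick", "grey40", "steelblue"),
                     pch = c(16, 16, NA), lty = c(NA, NA, 1))
  }
  invisible(x)
}
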
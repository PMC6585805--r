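#' Wilcoxon matched-pairs signed-rank test
#'
#' Paired two-sided signed-rank test with the conventions needed for kinetic
#' AUC comparisons: zero differences are discarded, tied absolute
#' differences receive mid-ranks, the exact null distribution is used for up
#' to 25 effective pairs (computed by convolution of the rank generating
#' function, which is exact also under ties), and a tie-corrected normal
#' approximation with continuity correction is used beyond. The two-sided p
#' is the null probability of a statistic at least as far from its mean
#' (n(n+1)/4) as observed — the distribution is symmetric, also with
#' mid-ranks.
#'
#' @param x,y paired measurements of equal length.
#' @param exact_max largest effective n for which the exact null is used.
#' @return object of classes `kinome_signed_rank` and `htest` with
#'   `statistic` (V, the positive-rank sum), `p.value`, `parameter` (the
#'   effective n), and `degenerate` (`TRUE` when all differences are zero,
#'   in which case p = 1).
#' @export
paired_signed_rank <- function(x, y, exact_max = 25L) {
  if (length(x) != length(y)) kk_validation_error("x and y must have equal length")
  if (length(x) < 1L) kk_validation_error("need at least one pair")
  d <- x - y
  if (anyNA(d) || !all(is.finite(d))) kk_validation_error("differences must be finite")
  d <- d[d != 0]
  n <- length(d)
  data_name <- paste(deparse1(substitute(x)), "vs", deparse1(substitute(y)))
  if (n == 0L) {
    res <- list(statistic = c(V = 0), parameter = c(n = 0L), p.value = 1,
                method = "Wilcoxon matched-pairs signed-rank test (degenerate)",
                data.name = data_name, degenerate = TRUE)
    class(res) <- c("kinome_signed_rank", "htest")
    return(res)
  }
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  if (n <= exact_max) {
    p <- signed_rank_exact_p(r, w)
    method <- "Wilcoxon matched-pairs signed-rank test (exact)"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    method <- "Wilcoxon matched-pairs signed-rank test (normal approximation)"
  }
  res <- list(statistic = c(V = w), parameter = c(n = n), p.value = p,
              method = method, data.name = data_name, degenerate = FALSE)
  class(res) <- c("kinome_signed_rank", "htest")
  res
}

# Exact two-sided p via the generating function of the positive-rank sum.
# Ranks are doubled so mid-ranks become integers; the convolution builds the
# full null distribution over the 2^n equiprobable sign assignments.
signed_rank_exact_p <- function(r, w) {
  r2 <- as.integer(round(2 * r))
  tot <- sum(r2)
  f <- numeric(tot + 1L)
  f[1L] <- 1
  for (rr in r2) {
    f <- f + c(numeric(rr), f[seq_len(length(f) - rr)])
  }
  probs <- f / 2^length(r2)
  support <- 0:tot
  mu2 <- tot / 2
  sum(probs[abs(support - mu2) >= abs(2 * w - mu2) - 1e-9])
}
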
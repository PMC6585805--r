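# Independent oracles used to cross-check the package's own numerics.

# OLS slope via stats::lm (independent of the package's closed-form path).
oracle_ols_slope <- function(t, y) {
  unname(stats::coef(stats::lm(y ~ t))[2])
}

# Two-sided signed-rank p by full enumeration of all 2^n sign patterns.
oracle_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1)
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  ws <- as.vector(signs %*% r)
  mean(abs(ws - mu) >= abs(w - mu) - 1e-9)
}

# Right-tail hypergeometric p by direct combinatorial summation.
oracle_hyper_p <- function(k, K, n, N) {
  lo <- max(k, 0, n + K - N)
  hi <- min(K, n)
  if (lo > hi) return(0)
  sum(choose(K, lo:hi) * choose(N - K, n - lo:hi)) / choose(N, n)
}

# Tiny long-format kinetic table from a list of curves:
# curves[[i]] = list(condition, peptide_id, replicate, times, intensities)
make_kinetics_df <- function(curves) {
  do.call(rbind, lapply(curves, function(cv) {
    data.frame(condition = cv$condition, peptide_id = cv$peptide_id,
               replicate = cv$replicate, time_s = cv$times,
               intensity = cv$intensities, stringsAsFactors = FALSE)
  }))
}

# Vmax-stats frame for direct tests of the calling rule.
make_stats <- function(vmax_mean, vmax_sd = rep(0, length(vmax_mean)),
                       peptide_id = sprintf("P%03d", seq_along(vmax_mean)),
                       condition = "A", kinetic_class = "early") {
  data.frame(condition = condition, peptide_id = peptide_id,
             vmax_mean = vmax_mean, vmax_sd = vmax_sd,
             kinetic_class = kinetic_class, considered = vmax_mean > 0,
             stringsAsFactors = FALSE)
}

# Per-condition sensitivity / false-positive counts of a fitted profile
# against simulation ground truth (control excluded).
call_performance <- function(fit, truth, conditions = c("ECM", "Ti")) {
  tr <- truth[!grepl("^ART_003", truth$peptide_id), ]
  out <- list(tp = 0, fp = 0, n_active = 0, n_inactive = 0, class_ok = 0)
  for (i in 1:2) {
    active <- if (i == 1) tr$active_in_a else tr$active_in_b
    cl <- fit$calls[fit$calls$condition == conditions[i], ]
    m <- match(tr$peptide_id, cl$peptide_id)
    out$tp <- out$tp + sum(cl$markov_positive[m][active])
    out$fp <- out$fp + sum(cl$markov_positive[m][!active])
    out$n_active <- out$n_active + sum(active)
    out$n_inactive <- out$n_inactive + sum(!active)
    out$class_ok <- out$class_ok +
      sum(cl$kinetic_class[m][active] == tr$true_class[active])
  }
  out
}
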
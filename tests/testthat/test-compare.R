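test_that("kinetic AUC matches closed forms and refined quadrature", {
  times <- seq(0, 1900, by = 100)
  expect_equal(curve_auc(times, rep(2, length(times)), from_time = 640),
               2 * (1900 - 640))
  t2 <- seq(0, 1000, by = 100)
  expect_equal(curve_auc(t2, t2, from_time = 0), 5e5)
  # logistic on the default grid vs a 1 s trapezoid oracle
  y <- curve_model("mid", 100, times, background_level = 20)
  fine_t <- seq(640, 1900, by = 1)
  fine_y <- curve_model("mid", 100, fine_t, background_level = 20)
  oracle <- if (requireNamespace("pracma", quietly = TRUE)) {
    pracma::trapz(fine_t, fine_y)
  } else {
    sum(diff(fine_t) * (fine_y[-1] + fine_y[-length(fine_y)]) / 2)
  }
  expect_equal(curve_auc(times, y, from_time = 640), oracle, tolerance = 0.01)
  # additivity over a shared sample point
  set.seed(31)
  yy <- rnorm(length(times))
  full <- curve_auc(times, yy, from_time = 0)
  expect_equal(curve_auc(times, yy, from_time = 0) ,
               sum(diff(times) * (yy[-1] + yy[-length(yy)]) / 2))
  expect_equal(full,
               curve_auc(times[times <= 1000], yy[times <= 1000], from_time = 0) +
                 curve_auc(times, yy, from_time = 1000), tolerance = 1e-10)
  expect_error(curve_auc(times, yy, from_time = 1900),
               class = "kk_validation_error")
})

test_that("the signed-rank test is exact, symmetric and tie-safe", {
  # n = 5, all positive, distinct magnitudes: p = 2/32
  res <- paired_signed_rank(c(2, 4, 6, 8, 10), c(1, 2, 3, 4, 5))
  expect_equal(res$p.value, 0.0625)
  expect_equal(unname(res$statistic), 15)
  # identical vectors: degenerate with p = 1
  res0 <- paired_signed_rank(1:4, 1:4)
  expect_true(res0$degenerate)
  expect_equal(res0$p.value, 1)
  # swapping the pair reflects the statistic and keeps p
  x <- c(3.2, 1.1, 5.6, 2.2, 9, 4)
  y <- c(1.0, 2.0, 5.0, 2.0, 7, 6)
  a <- paired_signed_rank(x, y)
  b <- paired_signed_rank(y, x)
  expect_equal(a$p.value, b$p.value)
  n_eff <- unname(a$parameter)
  expect_equal(unname(a$statistic) + unname(b$statistic),
               n_eff * (n_eff + 1) / 2)
  # exact p agrees with full sign-pattern enumeration, with and without ties
  set.seed(41)
  for (i in 1:20) {
    n <- sample(2:9, 1)
    d <- sample(c(-3, -2, -1, 1, 2, 2, 3), n, replace = TRUE)
    expect_equal(paired_signed_rank(d, rep(0, n))$p.value,
                 oracle_signed_rank_p(d), tolerance = 1e-12)
  }
  # no-ties case cross-checked against stats::wilcox.test (exact)
  set.seed(42)
  x <- rnorm(12); y <- rnorm(12)
  expect_equal(paired_signed_rank(x, y)$p.value,
               wilcox.test(x, y, paired = TRUE, exact = TRUE)$p.value,
               tolerance = 1e-12)
  # large-n normal approximation tracks wilcox.test's continuity-corrected p
  x <- rnorm(40); y <- rnorm(40, 0.3)
  expect_equal(paired_signed_rank(x, y)$p.value,
               wilcox.test(x, y, paired = TRUE, exact = FALSE,
                           correct = TRUE)$p.value,
               tolerance = 1e-8)
  expect_error(paired_signed_rank(1:3, 1:4), class = "kk_validation_error")
})

test_that("overlap partitions and class counts reproduce set arithmetic", {
  expect_equal(venn_overlap(letters[1:5], letters[1:5])[1:3],
               list(n_both = 5L, n_a_only = 0L, n_b_only = 0L))
  expect_equal(venn_overlap(c("a", "b", "c"), c("d", "e"))[1:3],
               list(n_both = 0L, n_a_only = 3L, n_b_only = 2L))
  v <- venn_overlap(c("a", "b", "c"), c("b", "c", "d"))
  expect_equal(v$both, c("b", "c"))
  # |A| + |B| - n_both partitions the union
  expect_equal(3 + 3 - v$n_both, v$n_both + v$n_a_only + v$n_b_only)

  calls <- published_as_calls(load_published_calls())
  cc <- class_counts(calls)
  expect_equal(cc["ECM", ], c(early = 43L, mid = 16L, late = 4L))
  expect_equal(cc["Ti", ], c(early = 37L, mid = 10L, late = 12L))
  empty <- calls[0, ]
  expect_equal(unname(colSums(class_counts(empty))), c(0, 0, 0))
})

test_that("condition comparison pairs AUCs under the chosen policy", {
  cfg <- sim_config(seed = 13, effect_ratio = 1, noise_sd = 0)
  sim <- simulate_dataset(cfg)
  fit <- kinome_profile(sim$dataset)
  cmp <- compare_conditions(fit)
  # no effect, no noise: the paired AUCs are identical
  expect_equal(cmp$mean_auc_a, cmp$mean_auc_b, tolerance = 1e-12)
  expect_true(cmp$wilcoxon$degenerate)
  expect_equal(cmp$p_value, 1)
  # venn invariants against the call totals
  calls <- fit$calls
  n_a <- sum(calls$markov_positive[calls$condition == "ECM"])
  n_b <- sum(calls$markov_positive[calls$condition == "Ti"])
  expect_equal(cmp$venn$n_both + cmp$venn$n_a_only, n_a)
  expect_equal(cmp$venn$n_both + cmp$venn$n_b_only, n_b)
  # pairing over everything covers all 143 analytes
  cmp_all <- compare_conditions(fit, pairing = "all")
  expect_equal(length(cmp_all$peptides), 143L)
  # nothing positive anywhere: the default pairing set is empty
  flat <- simulate_dataset(sim_config(seed = 2, n_active_shared = 0,
                                      n_active_a_only = 0,
                                      n_active_b_only = 0, noise_sd = 0))
  fit_flat <- kinome_profile(flat$dataset)
  expect_error(compare_conditions(fit_flat), class = "kk_validation_error")
})
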
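test_that("curve templates have the intended kinetic shapes", {
  times <- seq(0, 1900, by = 100)
  # reaction start: early curve is exactly at baseline at t = 640
  expect_equal(curve_model("early", 100, 640, background_level = 20), 20)
  expect_equal(curve_model("early", 100, c(0, 300, 600), background_level = 20),
               rep(20, 3))
  # early curve reaches 90% of its plateau by 1440 s
  expect_equal(curve_model("early", 100, 1440), 90)
  # saturating: steeper in the early window than in the late window
  y <- curve_model("early", 100, times)
  s_early <- window_slope(times, y, c(640, 1040))
  s_late <- window_slope(times, y, c(1440, 1840))
  expect_gt(s_early, s_late)
  # mid logistic: central finite-difference slope at the 1240 s inflection
  # equals the analytic derivative A/(4 tau) within 1%
  tau <- 100
  fd <- (curve_model("mid", 100, 1241, tau = tau) -
           curve_model("mid", 100, 1239, tau = tau)) / 2
  expect_equal(fd, 100 / (4 * tau), tolerance = 0.01)
  expect_error(curve_model("sigmoidal", 1, times),
               class = "kk_validation_error")
})

test_that("simulation is deterministic and honours its config", {
  cfg <- sim_config(seed = 42, n_peptides = 20, n_active_shared = 5,
                    n_active_a_only = 2, n_active_b_only = 1)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a$dataset$intensity, b$dataset$intensity)
  expect_identical(a$truth, b$truth)

  # no actives: every analyte curve is flat up to noise (exactly flat when
  # noiseless)
  flat <- simulate_dataset(sim_config(seed = 1, n_peptides = 10,
                                      n_active_shared = 0, n_active_a_only = 0,
                                      n_active_b_only = 0, noise_sd = 0))
  analyte <- !grepl("^ART_003", flat$dataset$peptide_id)
  expect_true(all(flat$dataset$intensity[analyte] == 20))

  # ground-truth invariant: background peptides inactive in both conditions
  bg <- a$truth$true_class == "background"
  expect_false(any(a$truth$active_in_a[bg] | a$truth$active_in_b[bg]))
})

test_that("doubling the effect ratio doubles supra-background AUC exactly when noiseless", {
  cfg <- sim_config(seed = 5, n_peptides = 12, n_active_shared = 4,
                    n_active_a_only = 0, n_active_b_only = 0,
                    effect_ratio = 2, noise_sd = 0)
  sim <- simulate_dataset(cfg)
  shared <- sim$truth$peptide_id[sim$truth$active_in_a & sim$truth$active_in_b &
                                   !grepl("^ART_003", sim$truth$peptide_id)]
  d <- sim$dataset
  for (p in shared) {
    sub_a <- d[d$condition == "ECM" & d$peptide_id == p & d$replicate == 1, ]
    sub_b <- d[d$condition == "Ti" & d$peptide_id == p & d$replicate == 1, ]
    base_area <- 20 * (1900 - 640)
    supra_a <- curve_auc(sub_a$time_s, sub_a$intensity) - base_area
    supra_b <- curve_auc(sub_b$time_s, sub_b$intensity) - base_area
    expect_equal(supra_a, 2 * supra_b, tolerance = 1e-12)
  }
})

test_that("degenerate configurations are rejected", {
  expect_error(sim_config(n_peptides = 5, n_active_shared = 5),
               class = "kk_validation_error")
  expect_error(sim_config(class_mix = c(early = 0.5, mid = 0.5, late = 0.5)),
               class = "kk_validation_error")
  expect_error(sim_config(effect_ratio = 0), class = "kk_validation_error")
  expect_error(sim_config(time_grid = seq(0, 1500, 100)),
               class = "kk_validation_error")
})
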
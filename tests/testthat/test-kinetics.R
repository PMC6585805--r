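test_that("window slopes match OLS on dense grids and interpolation on sparse ones", {
  times <- seq(0, 1900, by = 100)
  # exact linear curve
  expect_equal(window_slope(times, 2 * times, c(640, 1040)), 2)
  expect_equal(window_slope(times, rep(7, length(times)), c(1040, 1440)), 0)
  # logistic curve: equals an independent lm() fit over the in-window points
  y <- curve_model("mid", 100, times)
  idx <- times >= 1040 & times <= 1440
  expect_equal(window_slope(times, y, c(1040, 1440)),
               oracle_ols_slope(times[idx], y[idx]), tolerance = 1e-12)
  # random curves against the lm oracle
  set.seed(101)
  for (i in 1:50) {
    yy <- rnorm(length(times))
    w <- sort(sample(times, 2))
    if (w[1] == w[2]) next
    idx <- times >= w[1] & times <= w[2]
    if (sum(idx) >= 2) {
      expect_equal(window_slope(times, yy, w),
                   oracle_ols_slope(times[idx], yy[idx]), tolerance = 1e-9)
    }
  }
  # sparse 300 s grid: the early window holds one reading, so the slope is
  # the difference quotient of the interpolated curve between the edges
  t300 <- seq(0, 1800, by = 300)
  y300 <- curve_model("early", 100, t300)
  interp <- function(t) approx(t300, y300, t, rule = 2)$y
  expect_equal(window_slope(t300, y300, c(640, 1040)),
               (interp(1040) - interp(640)) / 400, tolerance = 1e-12)
  expect_error(window_slope(times, 2 * times, c(5000, 5400)),
               class = "kk_validation_error")
})

test_that("kinetic classes follow the steepest window with early tie-break", {
  expect_equal(classify_kinetics(c(0.9, 0.4, 0.1)), "early")
  expect_equal(classify_kinetics(c(0.2, 0.2, 0.1)), "early")
  expect_equal(classify_kinetics(c(0.1, 0.3, 0.3)), "mid")
  expect_error(classify_kinetics(c(0.1, NA, 0.2)),
               class = "kk_validation_error")
  # simulated noiseless late curve classifies late through the full path
  times <- seq(0, 1900, by = 100)
  y <- curve_model("late", 80, times, background_level = 20)
  slopes <- vapply(list(c(640, 1040), c(1040, 1440), c(1440, 1840)),
                   function(w) window_slope(times, y, w), numeric(1))
  expect_equal(classify_kinetics(slopes), "late")
})

test_that("replicate aggregation clips at zero before averaging", {
  a <- aggregate_vmax(c(-0.5, 1.0, 1.1))
  expect_equal(a$vmax_mean, mean(c(0, 1.0, 1.1)))
  expect_equal(a$vmax_sd, sd(c(0, 1.0, 1.1)))
  expect_true(a$considered)
  b <- aggregate_vmax(c(-1, -2, -3))
  expect_equal(b$vmax_mean, 0)
  expect_false(b$considered)
  c1 <- aggregate_vmax(2.0)
  expect_equal(c1$vmax_mean, 2.0)
  expect_equal(c1$vmax_sd, 0)
  expect_error(aggregate_vmax(numeric()), class = "kk_validation_error")
})

test_that("the Vmax table excludes the control and covers every analyte", {
  sim <- simulate_dataset(sim_config(seed = 2))
  expect_true(any(grepl("^ART_003", sim$dataset$peptide_id)))
  vm <- vmax_table(sim$dataset)
  expect_false(any(grepl("^ART_003", vm$peptide_id)))
  expect_equal(sum(vm$condition == "ECM"), 143L)
  expect_equal(sum(vm$condition == "Ti"), 143L)
  expect_true(all(vm$vmax_mean >= 0))
  expect_true(all(vm$vmax_sd >= 0))
  expect_equal(vm$considered, vm$vmax_mean > 0)

  # a peptide missing from one condition is reported
  d <- as.data.frame(sim$dataset)
  d <- d[!(d$condition == "Ti" & d$peptide_id == "PEP_005"), ]
  err <- tryCatch(vmax_table(as_kinetic_dataset(d)), error = identity)
  expect_s3_class(err, "kk_validation_error")
  expect_match(conditionMessage(err), "PEP_005")
})

test_that("slopes and Vmax are scale-equivariant and shift-invariant", {
  sim <- simulate_dataset(sim_config(seed = 8, n_peptides = 16,
                                     n_active_shared = 5, n_active_a_only = 1,
                                     n_active_b_only = 1))
  vm1 <- vmax_table(sim$dataset)
  scaled <- as.data.frame(sim$dataset)
  scaled$intensity <- scaled$intensity * 3.7
  vm2 <- vmax_table(as_kinetic_dataset(scaled))
  expect_equal(vm2$vmax_mean, 3.7 * vm1$vmax_mean, tolerance = 1e-12)
  expect_equal(vm2$vmax_sd, 3.7 * vm1$vmax_sd, tolerance = 1e-12)
  expect_identical(vm2$kinetic_class, vm1$kinetic_class)

  # common time shift of samples and window leaves the OLS slope unchanged
  times <- seq(0, 1900, by = 100)
  set.seed(9)
  y <- rnorm(length(times))
  expect_equal(window_slope(times + 500, y, c(1140, 1540)),
               window_slope(times, y, c(640, 1040)), tolerance = 1e-12)
})
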
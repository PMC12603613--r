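test_that("error metrics match independent implementations", {
  expect_equal(mae(c(45, 55), c(40, 60)), 5)
  expect_equal(mae(1:10, 1:10), 0)
  set.seed(3)
  a <- runif(1000, 0, 100); b <- runif(1000, 0, 100)
  expect_equal(mae(a, b), sum(abs(a - b)) / 1000)         # brute-force loop
  expect_equal(pearson_r(a, b),
               sum((a - mean(a)) * (b - mean(b))) /
                 sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2)))
  expect_equal(pearson_r(2 * a + 3, a), 1)
  expect_equal(pearson_r(-a + 7, a), -1)
  expect_error(pearson_r(c(1, 1, 1), c(1, 2, 3)), "variance")
  expect_error(mae(numeric(0), numeric(0)), "pairs")
})

test_that("cleaning removes rails, outliers and suppresses spikes", {
  t <- seq(0, 990, by = 10)
  x <- rep(80, 100)
  cfg <- cleaning_config(window_length = 120, smooth = FALSE)
  # rail removal: [80, 99, 81] -> middle becomes missing
  y <- clean_spo2_trace(c(0, 10, 20), c(80, 99, 81), cfg)
  expect_true(is.na(y$spo2[2]) && y$spo2[1] == 80 && y$spo2[3] == 81)
  # constant trace is a fixed point of all stages
  z <- clean_spo2_trace(t, x, cleaning_config(window_length = 120))
  expect_equal(z$spo2, x)
  # a single 5-SD spike on a jittered flat trace is removed by Hampel and
  # its residual after smoothing is < 10% of the spike
  set.seed(9)
  xs <- 60 + rnorm(100, 0, 1)
  xs[50] <- 60 + 5 * 1 * 5
  sm <- clean_spo2_trace(t, xs, cleaning_config(window_length = 120))
  expect_lt(abs(sm$spo2[50] - 60), 0.1 * 25)
})

test_that("rail removal is a projection and Hampel is nearly one", {
  set.seed(12)
  t <- seq(0, 990, by = 10)
  x <- 70 + rnorm(100, 0, 3)
  x[c(10, 40)] <- 99.5
  x[70] <- 30
  cfg <- cleaning_config(window_length = 120, smooth = FALSE)
  once <- clean_spo2_trace(t, x, cfg)$spo2
  expect_true(all(is.na(once[c(10, 40)])))      # rails removed
  expect_lt(abs(once[70] - 70), 10)             # spike replaced
  # a second pass introduces no new rails and alters only a small fraction
  # of points (median replacement shifts window statistics slightly)
  twice <- clean_spo2_trace(t, once, cfg)$spo2
  expect_identical(is.na(twice), is.na(once))
  expect_lte(mean(twice != once, na.rm = TRUE), 0.1)
})

test_that("perturbation study reproduces directional biases on a small cohort", {
  cfg <- tiny_cohort(n = 8, depth = 35, seed = 21)
  co <- run_virtual_cohort(cfg, "diffusion", sd_distances = 60)
  res <- perturbation_study(co, 60,
                            conditions = data.frame(
                              target = c("ideal", "mu_a", "mu_a"),
                              factor = c(1, 0.8, 1.2)))
  agg <- res$aggregate
  ideal <- agg[agg$condition == "ideal", ]
  expect_lte(ideal$mae, 0.5)                       # inverse crime
  lo <- agg[agg$condition == "mu_a x0.8", ]
  hi <- agg[agg$condition == "mu_a x1.2", ]
  expect_gt(lo$median_signed_error, 0)
  expect_lt(hi$median_signed_error, 0)
  expect_gte(lo$frac_positive_error, 0.8)
})

test_that("single- and multi-layer algorithms agree on a degenerate one-layer stack", {
  # one-layer stack: the "fetal" layer is the whole medium, so both models
  # describe the same pulsating tissue
  st <- tissue_stack(list(optical_layer(Inf, 50, 0.5, 1.0, 1.0)))
  m <- analytical_dod_single(0.5, 1.0, 1.0, 60, assumed_hbt = 50)
  ctx_s <- fit_context("single_layer", assumed_hbt = 50,
                       scat_amplitude = 1.0, scat_power = 1.0)
  expect_equal(estimate_spo2(m, ctx_s)$spo2, 50)
  # multi-layer estimator on the same data: agreement limited only by the
  # closed-form vs log-derivative pathlength difference
  ctx_m <- fit_context("multi_layer", stack = st)
  expect_lte(abs(estimate_spo2(m, ctx_m)$spo2 - 50), 3)
})

test_that("baseline calibration recovers properties inside the grid", {
  wl <- c(756, 785, 812, 825, 846, 855)
  true_st <- tissue_stack(list(optical_layer(15, 55, 0.98, 1.1, 1),
                               optical_layer(Inf, 95, 0.55, 0.4, 1)),
                          wavelengths = wl)
  base_dod <- t(vapply(1:3, function(i)
    analytical_dod_fetal(0.55, true_st, 55)$dod, numeric(6)))
  baseline <- structure(list(time = c(0, 10, 20), dod = base_dod,
                             wavelengths = wl, sd_distance = 55),
                        class = "fetal_od_series")
  cal <- calibrate_baseline_properties(
    baseline, reference_sao2 = 55,
    hbt_m = c(40, 55), hbt_f = c(80, 95), a_m = c(0.75, 1.1),
    a_f = c(0.4, 0.75))
  expect_true(all(cal$table$a_m >= cal$table$a_f))  # constraint everywhere
  expect_lte(cal$objective, 1)
  expect_equal(cal$best$hbt_m, 55)
  expect_equal(cal$best$a_m, 1.1)
  # degenerate single-candidate grid returns that candidate
  one <- calibrate_baseline_properties(baseline, 55, hbt_m = 55, hbt_f = 95,
                                       a_m = 1.1, a_f = 0.4)
  expect_equal(unlist(one$best), c(hbt_m = 55, hbt_f = 95, a_m = 1.1, a_f = 0.4))
})

test_that("single vs multi-layer comparison is paired by subject", {
  cfg <- tiny_cohort(n = 5, depth = 35, seed = 2)
  co <- run_virtual_cohort(cfg, "diffusion", sd_distances = 90)
  cmp <- compare_single_vs_multilayer(co, 90)
  expect_equal(cmp$per_subject$subject, 1:5)
  expect_equal(cmp$per_subject$truth,
               vapply(co$subjects, `[[`, 0, "fetal_sao2"))
  expect_lt(cmp$metrics$mae[1], cmp$metrics$mae[2])
})
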
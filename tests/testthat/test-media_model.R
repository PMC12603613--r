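test_that("extinction table is valid and interpolates linearly", {
  expect_true(all(diff(hb_tab$wavelength_nm) > 0))
  expect_true(all(hb_tab$eps_hbo > 0) && all(hb_tab$eps_hb > 0))
  # linear interpolation between grid points
  l1 <- hb_tab$wavelength_nm[10]; l2 <- hb_tab$wavelength_nm[11]
  mid <- extinction_at(hb_tab, (l1 + l2) / 2)
  expect_equal(mid$eps_hbo, (hb_tab$eps_hbo[10] + hb_tab$eps_hbo[11]) / 2)
  expect_error(extinction_at(hb_tab, 650), "range")
  expect_error(extinction_at(hb_tab, 950), "range")
})

test_that("absorption matches the published order of magnitude at 800 nm", {
  l <- optical_layer(Inf, 40, 0.95, 1.1)
  expect_equal(absorption_spectrum(l, 800), 0.0075, tolerance = 0.1)
  l2 <- optical_layer(Inf, 100, 0.50, 1.1)
  expect_equal(absorption_spectrum(l2, 800), 0.02, tolerance = 0.12)
  # zero concentration and pure oxyhemoglobin limits
  l0 <- optical_layer(Inf, 0, 0.5, 1.1)
  expect_equal(absorption_spectrum(l0, c(700, 800, 860)), c(0, 0, 0))
  lox <- optical_layer(Inf, 60, 1, 1.1)
  eps <- extinction_at(hb_tab, c(700, 800, 860))
  expect_equal(absorption_spectrum(lox, c(700, 800, 860)), eps$eps_hbo * 60)
})

test_that("absorption is linear in HbT and affine in SaO2", {
  wl <- c(700, 760, 800, 860)
  mu1 <- absorption_spectrum(optical_layer(Inf, 30, 0.4, 1), wl)
  mu2 <- absorption_spectrum(optical_layer(Inf, 60, 0.4, 1), wl)
  expect_equal(mu2, 2 * mu1)
  # affine: mu(s) = mu(0) + s*(mu(1)-mu(0))
  s <- 0.37
  mu_s <- absorption_spectrum(optical_layer(Inf, 50, s, 1), wl)
  mu_0 <- absorption_spectrum(optical_layer(Inf, 50, 0, 1), wl)
  mu_1 <- absorption_spectrum(optical_layer(Inf, 50, 1, 1), wl)
  expect_equal(mu_s, mu_0 + s * (mu_1 - mu_0))
})

test_that("pulsatile absorption is exactly pulse_fraction times baseline", {
  wl <- c(700, 730, 760, 800, 830, 860)
  l <- optical_layer(Inf, 100, 0.5, 1)
  for (f in c(0.02, 0.05, 0.10))
    expect_identical(pulsatile_absorption(l, wl, f),
                     f * absorption_spectrum(l, wl))
  expect_equal(pulsatile_absorption(l, wl, 0), rep(0, 6))
  # 5% of the ~0.02 mm^-1 example
  expect_equal(pulsatile_absorption(l, 800, 0.05), 0.001, tolerance = 0.12)
})

test_that("mu_a is independent of SaO2 at the table's isosbestic point", {
  dif <- hb_tab$eps_hbo - hb_tab$eps_hb
  i <- which(diff(sign(dif)) != 0)[1]
  lam <- stats::approx(dif[i:(i + 1)], hb_tab$wavelength_nm[i:(i + 1)], 0)$y
  mus <- vapply(seq(0, 1, 0.25), function(s)
    absorption_spectrum(optical_layer(Inf, 50, s, 1), lam), 0)
  expect_lt(diff(range(mus)) / mean(mus), 1e-9)
})

test_that("reduced scattering follows the power law", {
  expect_equal(reduced_scattering(1.1, 1.0, 800), 1.1)
  expect_equal(reduced_scattering(0.77, 1.33, 800), 0.77)
  expect_equal(reduced_scattering(1.1, 1.0, 700), 1.1 * (700 / 800)^-1,
               tolerance = 1e-12)
  expect_equal(reduced_scattering(1.1, 1.0, 700), 1.2571, tolerance = 1e-4)
  expect_error(reduced_scattering(-1, 1, 800), "positive")
  expect_error(reduced_scattering(1, 1, -800), "positive")
})

test_that("virtual subjects respect depth presets and sampling bounds", {
  cfg20 <- tiny_cohort(depth = 20)
  st <- sample_virtual_subject(cfg20, 1)
  expect_equal(vapply(st$layers, `[[`, 0, "thickness"), c(5, 15, Inf))
  expect_equal(fetal_depth(st), 20)
  cfg35 <- tiny_cohort(depth = 35)
  expect_equal(fetal_depth(sample_virtual_subject(cfg35, 1)), 35)
  expect_error(cohort_config(fetal_depth = 27), "preset")
})

test_that("cohort sampling respects every configured bound (1000 draws)", {
  cfg <- cohort_config(n_subjects = 1000, fetal_depth = 35, seed = 9)
  ok <- vapply(seq_len(1000), function(i) {
    st <- sample_virtual_subject(cfg, i)
    l <- st$layers
    tr <- attr(st, "truth")
    all(
      tr$fetal_sao2 >= 0.30, tr$fetal_sao2 <= 0.70,
      tr$maternal_sao2 >= 0.90, tr$maternal_sao2 <= 1.00,
      l[[1]]$sao2 == l[[2]]$sao2,                 # shared maternal SaO2
      l[[1]]$hbt >= 20, l[[1]]$hbt <= 60,
      l[[2]]$hbt >= 40, l[[2]]$hbt <= 80,
      l[[3]]$hbt >= 60, l[[3]]$hbt <= 100,
      vapply(l, `[[`, 0, "scat_amplitude") >= 0.35,
      vapply(l, `[[`, 0, "scat_amplitude") <= 1.5,
      l[[1]]$scat_amplitude >= l[[3]]$scat_amplitude,
      l[[2]]$scat_amplitude >= l[[3]]$scat_amplitude,
      vapply(l, `[[`, 0, "scat_power") >= 0.7,
      vapply(l, `[[`, 0, "scat_power") <= 1.4
    )
  }, TRUE)
  expect_true(all(ok))
})

test_that("sampling is reproducible given (seed, draw_index)", {
  cfg <- tiny_cohort(seed = 123)
  a <- sample_virtual_subject(cfg, 7)
  b <- sample_virtual_subject(cfg, 7)
  expect_identical(a, b)
  c <- sample_virtual_subject(cfg, 8)
  expect_false(identical(a$layers[[3]]$sao2, c$layers[[3]]$sao2))
})

test_that("stack constructor enforces the semi-infinite terminal layer", {
  expect_error(tissue_stack(list(optical_layer(5, 40, 0.9, 1))), "semi-infinite")
  expect_error(tissue_stack(list(optical_layer(Inf, 40, 0.9, 1),
                                 optical_layer(Inf, 40, 0.9, 1))), "last layer")
})
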
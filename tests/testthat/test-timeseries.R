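fs <- 50

test_that("intensity to delta-OD conversion inverts an exponential exactly", {
  t <- seq(0, 59.98, by = 1 / fs)
  x <- 0.02 * sin(2 * pi * 1.3 * t)
  I <- cbind(100 * exp(-x), 7 * exp(-x))
  tr <- intensity_trace(t, I, fs, c(800, 830), 55)
  dod <- intensity_to_dod(tr)
  # -ln(I/I0) = x - ln(mean exp(-x)) ~ x up to a tiny DC offset
  expect_equal(dod[, 1] - mean(dod[, 1]), x - mean(x), tolerance = 1e-10)
  # constant trace -> zero
  trc <- intensity_trace(t, cbind(rep(5, length(t)), rep(2, length(t))),
                         fs, c(800, 830), 55)
  expect_equal(max(abs(intensity_to_dod(trc))), 0)
  # small-signal: 1% modulation gives ~0.01 amplitude
  I1 <- cbind(100 * (1 + 0.01 * sin(2 * pi * 2 * t)), rep(1, length(t)))
  d1 <- intensity_to_dod(intensity_trace(t, I1, fs, c(800, 830), 55))
  expect_equal(max(abs(d1[, 1])), 0.01, tolerance = 0.02)
})

test_that("high-pass reference filter has the designed response", {
  t <- seq(0, 120 - 1 / fs, by = 1 / fs)
  # DC passes to ~zero
  expect_lt(max(abs(bandpass_reference(rep(3, length(t)), fs))), 1e-3)
  # 2.5 Hz passes with gain ~1
  x <- sin(2 * pi * 2.5 * t)
  y <- bandpass_reference(x, fs)
  mid <- seq(1000, length(t) - 1000)
  expect_equal(sd(y[mid]) / sd(x[mid]), 1, tolerance = 0.01)
  # 0.1 Hz drift attenuated > 20 dB
  d <- sin(2 * pi * 0.1 * t)
  yd <- bandpass_reference(d, fs)
  expect_lt(sd(yd[mid]) / sd(d[mid]), 0.1)
})

test_that("ridge tracker locks to the fetal tone", {
  t <- seq(0, 300 - 1 / fs, by = 1 / fs)
  set.seed(4)
  noise <- rnorm(length(t), 0, 0.3)
  # single tone
  x1 <- sin(2 * pi * 2.4 * t) + noise
  hr1 <- track_fetal_hr(x1, fs)
  expect_true(all(abs(hr1$hr - 2.4) < 0.05))
  # two tones: large maternal tone outside the band is ignored
  x2 <- 10 * sin(2 * pi * 1.2 * t) + sin(2 * pi * 2.4 * t) + noise
  hr2 <- track_fetal_hr(x2, fs, band = c(1.6, 4))
  expect_true(all(abs(hr2$hr - 2.4) < 0.05))
})

test_that("ridge tracker follows a chirp within one bin per frame", {
  dur <- 600
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  f_inst <- 2.0 + 1.0 * t / dur            # 2.0 -> 3.0 Hz
  phase <- 2 * pi * cumsum(f_inst) / fs
  set.seed(8)
  x <- sin(phase) + rnorm(length(t), 0, 0.3)
  hr <- track_fetal_hr(x, fs)
  truth <- 2.0 + 1.0 * hr$time / dur
  bin <- fs / (4 * 20 * fs)                # spectrogram bin width, Hz
  expect_true(all(abs(hr$hr - truth) < 0.05 + bin))
})

test_that("fetal spectrum extraction is linear and leakage-immune", {
  t <- seq(0, 300 - 1 / fs, by = 1 / fs)
  amp <- c(1, 0.8, 1.3) * 1e-3
  mk <- function(f_amp, maternal = 0) {
    od <- vapply(amp * f_amp, function(a)
      a * sin(2 * pi * 2.4 * t) + maternal * 1e-2 * sin(2 * pi * 1.2 * t),
      numeric(length(t)))
    od
  }
  hrt <- track_fetal_hr(mk(1)[, 1], fs)
  ex1 <- extract_fetal_dod(mk(1), hrt, fs, c(760, 800, 860), 55)
  # recovered ratios match the programmed wavelength ratios within 2%
  ratio <- ex1$dod[3, ] / ex1$dod[3, 1]
  expect_equal(ratio, amp / amp[1], tolerance = 0.02)
  # 10x maternal tone changes the fetal-bin magnitudes by < 2%
  ex_m <- extract_fetal_dod(mk(1, maternal = 10), hrt, fs, c(760, 800, 860), 55)
  expect_equal(ex_m$dod[3, ], ex1$dod[3, ], tolerance = 0.02)
  # doubling the fetal amplitude doubles the recovered magnitudes within 5%
  ex2 <- extract_fetal_dod(mk(2), hrt, fs, c(760, 800, 860), 55)
  expect_equal(ex2$dod[3, ] / ex1$dod[3, ], rep(2, 3), tolerance = 0.05)
})

test_that("frame times follow the window/overlap convention exactly", {
  x <- rnorm(20 * fs * 6)
  sg <- fetox:::.stft(x, fs, window_s = 20, overlap = 0.5)
  expect_equal(sg$time, 10 + 10 * (seq_along(sg$time) - 1))
})

test_that("synthesized traces honour their ground-truth ledger", {
  st <- stack3(0.6)
  tr <- synthesize_abdominal_traces(st, duration = 120, sd_distance = 55,
                                    fetal_sao2 = 0.6, seed = 2)
  expect_s3_class(tr, "intensity_trace")
  truth <- attr(tr, "truth")
  expect_equal(unique(truth$fetal_sao2), 0.6)
  # zero pulsations: constant intensity up to the noise floor
  tr0 <- synthesize_abdominal_traces(st, duration = 60, sd_distance = 55,
                                     pulse_fraction = 1e-12, noise_sd = 1e-6,
                                     seed = 2)
  cv <- apply(tr0$intensity, 2, function(v) sd(v) / mean(v))
  expect_true(all(cv < 1e-5))
  # reproducibility
  tr2 <- synthesize_abdominal_traces(st, duration = 120, sd_distance = 55,
                                     fetal_sao2 = 0.6, seed = 2)
  expect_identical(tr$intensity, tr2$intensity)
  # artifact bursts act only inside their window (paired seeds)
  tra <- synthesize_abdominal_traces(st, duration = 120, sd_distance = 55,
                                     fetal_sao2 = 0.6, seed = 2,
                                     artifact_windows = list(c(40, 60, 0.05)))
  dlog <- log(tra$intensity[, 1]) - log(tr$intensity[, 1])
  inside <- tra$time >= 40 & tra$time <= 60
  expect_equal(max(abs(dlog[!inside])), 0)
  expect_gt(sd(dlog[inside]), 0.01)
})
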
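#' Multi-wavelength intensity time series
#'
#' @param time seconds, uniformly sampled.
#' @param intensity matrix (n_samples x n_wavelengths), positive, arbitrary
#'   units; columns named \code{I_<wavelength>nm} or given via
#'   \code{wavelengths}.
#' @param sampling_rate Hz (default 50).
#' @param wavelengths nm, one per intensity column.
#' @param sd_distance mm.
#' @return object of class \code{intensity_trace}.
#' @export
intensity_trace <- function(time, intensity, sampling_rate = 50,
                            wavelengths, sd_distance) {
  intensity <- as.matrix(intensity)
  stopifnot(nrow(intensity) == length(time), all(intensity > 0),
            length(wavelengths) == ncol(intensity))
  dt <- diff(time)
  if (max(abs(dt - 1 / sampling_rate)) > 1e-6)
    stop("time vector must be uniformly sampled at sampling_rate", call. = FALSE)
  colnames(intensity) <- paste0("I_", wavelengths, "nm")
  structure(list(time = time, intensity = intensity,
                 sampling_rate = sampling_rate, wavelengths = wavelengths,
                 sd_distance = sd_distance),
            class = "intensity_trace")
}

#' Convert intensities to optical-density changes
#'
#' \code{delta OD(t) = -ln(I(t)/I0)} per wavelength, with \code{I0} the mean
#' of \code{I(t)}.
#'
#' @param trace an [intensity_trace()].
#' @return matrix (n_samples x n_wavelengths) of delta-OD values.
#' @export
intensity_to_dod <- function(trace) {
  stopifnot(inherits(trace, "intensity_trace"))
  I0 <- colMeans(trace$intensity)
  -log(sweep(trace$intensity, 2, I0, "/"))
}

#' High-pass filter a cardiac reference signal
#'
#' Zero-phase (forward-backward) 3rd-order Butterworth high-pass, removing
#' baseline drift below the cardiac band before spectrogram analysis.
#'
#' @param x numeric signal.
#' @param fs sampling rate, Hz.
#' @param cutoff high-pass corner, Hz (default 1).
#' @return filtered signal.
#' @export
bandpass_reference <- function(x, fs, cutoff = 1) {
  stopifnot(fs > 2 * cutoff)
  if (length(x) < 12 * fs / cutoff)
    stop("signal too short for stable zero-phase filtering", call. = FALSE)
  bf <- signal::butter(3, cutoff / (fs / 2), type = "high")
  # reflection padding suppresses the forward-backward edge transient
  np <- min(length(x) - 1, round(3 * fs / cutoff))
  xp <- c(2 * x[1] - x[(np + 1):2], x, 2 * x[length(x)] - x[(length(x) - 1):(length(x) - np)])
  y <- signal::filtfilt(bf, xp)
  as.numeric(y[(np + 1):(np + length(x))])
}

# Short-time Fourier transform: Hann window, zero-padded 4x, frame-centred
# timestamps. Returns magnitude matrix (n_freq x n_frames).
.stft <- function(x, fs, window_s = 20, overlap = 0.5, pad = 4) {
  n_win <- round(window_s * fs)
  hop <- round(n_win * (1 - overlap))
  n_frames <- floor((length(x) - n_win) / hop) + 1
  if (n_frames < 1) stop("signal shorter than one analysis window", call. = FALSE)
  nfft <- pad * n_win
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(n_win) / (n_win + 1))  # Hann
  n_keep <- nfft %/% 2 + 1
  mag <- matrix(0, n_keep, n_frames)
  for (f in seq_len(n_frames)) {
    seg <- x[((f - 1) * hop + 1):((f - 1) * hop + n_win)] * w
    sp <- stats::fft(c(seg, numeric(nfft - n_win)))
    mag[, f] <- Mod(sp[seq_len(n_keep)])
  }
  list(mag = mag,
       freq = (seq_len(n_keep) - 1) * fs / nfft,
       time = (seq_len(n_frames) - 1) * hop / fs + window_s / 2,
       window_s = window_s, overlap = overlap, fs = fs)
}

#' Track the fetal heart rate with a time-frequency ridge
#'
#' Computes a spectrogram (Hann window, default 20 s, 50% overlap, 4x
#' zero-padding) and extracts the maximum-energy path through the fetal band
#' by dynamic programming with a quadratic inter-frame jump penalty.
#'
#' @param x reference signal (high-pass filtered cardiac signal or a
#'   delta-OD channel).
#' @param fs sampling rate, Hz.
#' @param band fetal heart-rate search band, Hz (default c(1.6, 4)).
#' @param window_s spectrogram window, s (default 20).
#' @param overlap fractional window overlap (default 0.5).
#' @param jump_penalty penalty weight per squared bin jump between frames
#'   (default 1).
#' @return object of class \code{hr_track}: frame \code{time} (s), \code{hr}
#'   (Hz), \code{confidence} (ridge power / band power per frame), and the
#'   spectrogram parameters.
#' @export
track_fetal_hr <- function(x, fs, band = c(1.6, 4), window_s = 20,
                           overlap = 0.5, jump_penalty = 1) {
  stopifnot(band[1] > 0, band[2] > band[1], band[2] < fs / 2)
  sg <- .stft(x, fs, window_s, overlap)
  sel <- which(sg$freq >= band[1] & sg$freq <= band[2])
  if (length(sel) < 3) stop("band too narrow for the frequency grid", call. = FALSE)
  P <- sg$mag[sel, , drop = FALSE]^2
  nb <- nrow(P); nf <- ncol(P)
  # dynamic-programming ridge: maximize sum of per-frame normalized power
  # minus jump_penalty * (delta bin)^2
  Pn <- sweep(P, 2, apply(P, 2, max) + .Machine$double.xmin, "/")
  score <- Pn[, 1]
  back <- matrix(0L, nb, nf)
  db2 <- outer(seq_len(nb), seq_len(nb), function(i, j) (i - j)^2)
  pen <- jump_penalty * db2 / nb^2 * 100   # scaled so one full-band jump ~ 100
  for (f in 2:nf) {
    tot <- score - t(pen)                  # tot[j_prev, j_new]
    best <- max.col(t(tot))
    back[, f] <- best
    score <- Pn[, f] + tot[cbind(best, seq_len(nb))]
  }
  ridge <- integer(nf)
  ridge[nf] <- which.max(score)
  if (nf > 1) for (f in (nf - 1):1) ridge[f] <- back[ridge[f + 1], f + 1]
  conf <- P[cbind(ridge, seq_len(nf))] / colSums(P)
  structure(list(time = sg$time, hr = sg$freq[sel][ridge],
                 ridge_bin = sel[ridge], confidence = conf, band = band,
                 window_s = window_s, overlap = overlap, fs = fs),
            class = "hr_track")
}

#' Extract the fetal pulsatile spectrum from delta-OD traces
#'
#' For every analysis frame and wavelength, the fetal pulsatile component is
#' the spectrogram magnitude at the tracked fetal heart-rate bin (same
#' window and overlap as the tracker).
#'
#' @param dod matrix (n_samples x n_wavelengths) from [intensity_to_dod()].
#' @param hr_track an [track_fetal_hr()] result for the same recording.
#' @param fs sampling rate, Hz.
#' @param wavelengths nm, one per column.
#' @param sd_distance mm.
#' @return object of class \code{fetal_od_series}: \code{time} (frame
#'   centres), \code{dod} (n_frames x n_wavelengths magnitudes),
#'   \code{wavelengths}, \code{sd_distance}.
#' @export
extract_fetal_dod <- function(dod, hr_track, fs, wavelengths, sd_distance) {
  stopifnot(inherits(hr_track, "hr_track"), ncol(dod) == length(wavelengths))
  out <- matrix(NA_real_, length(hr_track$time), length(wavelengths))
  for (j in seq_len(ncol(dod))) {
    sg <- .stft(dod[, j], fs, hr_track$window_s, hr_track$overlap)
    nf <- min(ncol(sg$mag), length(hr_track$ridge_bin))
    out[seq_len(nf), j] <- sg$mag[cbind(hr_track$ridge_bin[seq_len(nf)],
                                        seq_len(nf))]
  }
  structure(list(time = hr_track$time, dod = out, wavelengths = wavelengths,
                 sd_distance = sd_distance, hr = hr_track$hr,
                 confidence = hr_track$confidence),
            class = "fetal_od_series")
}

#' Synthesize transabdominal intensity traces with mixed pulsations
#'
#' Emulates a transabdominal NIRS recording: a layered-tissue baseline
#' intensity modulated by a maternal pulsation (maternal-layer absorption at
#' the maternal heart rate) and a fetal pulsation (fetal-layer absorption at
#' the fetal heart rate), with the fetal saturation following a programmed
#' trajectory, plus multiplicative log-normal measurement noise. The
#' attached \code{"truth"} attribute carries everything needed for
#' end-to-end testing.
#'
#' @param stack a [tissue_stack()]; the fetal layer's saturation is overridden
#'   by \code{fetal_sao2} frame by frame.
#' @param duration s.
#' @param fs sampling rate, Hz (default 50).
#' @param sd_distance mm.
#' @param maternal_hr,fetal_hr Hz; scalar or function of time.
#' @param fetal_sao2 fraction; scalar or function of time (e.g. a programmed
#'   desaturation 0.80 -> 0.25 -> 0.75).
#' @param pulse_fraction fractional systolic mu_a modulation (both
#'   compartments; default 0.05).
#' @param noise_sd log-normal multiplicative noise sigma (default 1e-4).
#' @param artifact_windows optional list of \code{c(start_s, end_s, sigma)}
#'   triples adding broadband noise bursts (emulating transient
#'   interference across all wavelengths).
#' @param seed integer.
#' @param table extinction table.
#' @return an [intensity_trace()] with attribute \code{"truth"}.
#' @export
synthesize_abdominal_traces <- function(stack, duration, fs = 50,
                                        sd_distance = 55,
                                        maternal_hr = 1.2, fetal_hr = 2.4,
                                        fetal_sao2 = 0.5,
                                        pulse_fraction = 0.05,
                                        noise_sd = 1e-4,
                                        artifact_windows = NULL, seed = 1,
                                        table = hb_extinction()) {
  stopifnot(inherits(stack, "tissue_stack"), duration > 0)
  as_fun <- function(v) if (is.function(v)) v else function(t) rep(v, length(t))
  f_mhr <- as_fun(maternal_hr); f_fhr <- as_fun(fetal_hr)
  f_sat <- as_fun(fetal_sao2)
  t <- seq(0, duration - 1 / fs, by = 1 / fs)
  wl <- stack$wavelengths
  nL <- length(stack$layers)
  fl <- stack$fetal_layer
  fetal_hbt <- stack$layers[[fl]]$hbt

  # maternal pulsatile amplitude: sum of maternal partial pathlengths times
  # the maternal pulsatile absorption (same 5% model as the fetal layer)
  L_mat <- vapply(seq_len(nL - 1), function(i)
    partial_pathlength(stack, sd_distance, i, wl, table),
    numeric(length(wl)))
  dmua_m <- vapply(seq_len(nL - 1), function(i)
    pulsatile_absorption(stack$layers[[i]], wl, pulse_fraction, table),
    numeric(length(wl)))
  A_m <- rowSums(L_mat * dmua_m)                     # per wavelength

  # fetal amplitude follows the saturation trajectory; evaluated on a coarse
  # grid (10 s) and interpolated, since the trajectory is slow
  tg <- unique(c(seq(0, duration, by = 10), duration))
  sat_g <- pmin(1, pmax(0, f_sat(tg)))
  A_f_g <- analytical_dod_fetal(sat_g, stack, sd_distance,
                                fetal_hbt, pulse_fraction, wl, table)
  if (is.null(dim(A_f_g))) A_f_g <- matrix(A_f_g$dod, 1)
  A_f <- vapply(seq_along(wl), function(j)
    stats::approx(tg, A_f_g[, j], t)$y, numeric(length(t)))

  phase_m <- 2 * pi * cumsum(f_mhr(t)) / fs
  phase_f <- 2 * pi * cumsum(f_fhr(t)) / fs
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sig <- rep(noise_sd, length(t))
  for (aw in artifact_windows)
    sig[t >= aw[1] & t <= aw[2]] <- sig[t >= aw[1] & t <= aw[2]] + aw[3]
  I <- matrix(NA_real_, length(t), length(wl))
  base <- layered_reflectance(stack, sd_distance, wl, table)
  for (j in seq_along(wl)) {
    od <- A_m[j] * sin(phase_m) + A_f[, j] * sin(phase_f)
    I[, j] <- base[j] * exp(-od) *
      exp(stats::rnorm(length(t), 0, sig))
  }
  tr <- intensity_trace(t, I, fs, wl, sd_distance)
  attr(tr, "truth") <- list(time = t, fetal_sao2 = pmin(1, pmax(0, f_sat(t))),
                            fetal_hr = f_fhr(t), maternal_hr = f_mhr(t),
                            A_f = A_f, A_m = A_m,
                            pulse_fraction = pulse_fraction)
  tr
}
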
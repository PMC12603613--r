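#' Pulsatile optical-density spectrum
#'
#' Container for a delta-OD value per wavelength at one source-detector
#' distance (natural-log convention, \code{ln(I_diastole/I_systole)}).
#'
#' @param wavelengths nm (>= 3 values; the fit needs spectral shape).
#' @param dod delta-OD per wavelength (unitless).
#' @param sd_distance mm.
#' @param time_stamp optional frame time, s.
#' @return object of class \code{od_spectrum}.
#' @export
od_spectrum <- function(wavelengths, dod, sd_distance, time_stamp = NULL) {
  stopifnot(length(wavelengths) == length(dod), length(wavelengths) >= 3,
            all(is.finite(dod)), sd_distance > 0)
  structure(list(wavelengths = wavelengths, dod = dod,
                 sd_distance = sd_distance, time_stamp = time_stamp),
            class = "od_spectrum")
}

#' Fitting context for the self-calibrated estimators
#'
#' @param mode \code{"multi_layer"} (layered partial-pathlength model) or
#'   \code{"single_layer"} (homogeneous semi-infinite mean pathlength).
#' @param stack [tissue_stack()] (required for multi-layer mode; maternal
#'   layers keep their configured saturations, the fetal layer's saturation is
#'   swept over the grid).
#' @param assumed_hbt homogeneous-tissue HbT assumption for single-layer
#'   mode, uM (default 50).
#' @param scat_amplitude,scat_power single-layer scattering power-law
#'   parameters (mu_s' at 800 nm and exponent).
#' @param fetal_hbt fetal-layer HbT used by the multi-layer model; defaults
#'   to the stack's fetal layer value.
#' @param pulse_fraction fractional systolic HbT pulsation (default 0.05).
#' @param grid SpO2 candidate grid, fractions (default 0 to 1 step 0.01).
#' @param reference_index index of the normalization reference wavelength
#'   (default 1, the first/lowest wavelength).
#' @param rail_threshold estimates above this percent are flagged as railed in
#'   downstream cleaning (default 95).
#' @return object of class \code{fit_context}.
#' @export
fit_context <- function(mode = c("multi_layer", "single_layer"),
                        stack = NULL, assumed_hbt = 50,
                        scat_amplitude = 1.0, scat_power = 1.0,
                        fetal_hbt = NULL, pulse_fraction = 0.05,
                        grid = seq(0, 1, by = 0.01),
                        reference_index = 1L, rail_threshold = 95) {
  mode <- match.arg(mode)
  stopifnot(all(diff(grid) > 0), all(grid >= 0), all(grid <= 1),
            assumed_hbt > 0, pulse_fraction > 0, pulse_fraction < 1)
  if (mode == "multi_layer") {
    if (!inherits(stack, "tissue_stack"))
      stop("multi-layer mode requires a tissue_stack", call. = FALSE)
    if (is.null(fetal_hbt)) fetal_hbt <- stack$layers[[stack$fetal_layer]]$hbt
  }
  structure(list(mode = mode, stack = stack, assumed_hbt = assumed_hbt,
                 scat_amplitude = scat_amplitude, scat_power = scat_power,
                 fetal_hbt = fetal_hbt, pulse_fraction = pulse_fraction,
                 grid = grid, reference_index = as.integer(reference_index),
                 rail_threshold = rail_threshold),
            class = "fit_context")
}

# extinction-weighted arterial spectrum: eps_HbO*S + eps_Hb*(1-S)
# S may be a vector -> returns length(S) x length(lambda) matrix
.eps_mix <- function(spo2, wavelengths, table) {
  eps <- extinction_at(table, wavelengths)
  outer(spo2, eps$eps_hbo) + outer(1 - spo2, eps$eps_hb)
}

#' Analytical pulsatile spectrum of a homogeneous medium
#'
#' Single-layer model: \code{delta OD = <L>(lambda; S) * delta mu_a(lambda; S)}
#' with the semi-infinite mean pathlength and the hemoglobin
#' absorption model at an assumed total hemoglobin concentration.
#'
#' @param spo2_candidate saturation candidate, fraction in \[0, 1\].
#' @param scat_amplitude,scat_power scattering power law (mu_s' at 800 nm).
#' @param r source-detector distance, mm.
#' @param assumed_hbt uM.
#' @param pulse_fraction fractional systolic HbT change.
#' @param wavelengths nm.
#' @param table extinction table.
#' @return an [od_spectrum()].
#' @export
analytical_dod_single <- function(spo2_candidate, scat_amplitude, scat_power,
                                  r, assumed_hbt = 50, pulse_fraction = 0.05,
                                  wavelengths = c(700, 730, 760, 800, 830, 860),
                                  table = hb_extinction()) {
  stopifnot(spo2_candidate >= 0, spo2_candidate <= 1)
  eps <- .eps_mix(spo2_candidate, wavelengths, table)[1, ]
  mua <- eps * assumed_hbt
  musp <- reduced_scattering(scat_amplitude, scat_power, wavelengths)
  L <- mean_pathlength_semi_infinite(mua, musp, r)
  od_spectrum(wavelengths, L * eps * pulse_fraction * assumed_hbt, r)
}

#' Analytical fetal pulsatile spectrum of a layered medium
#'
#' Multi-layer model: the candidate saturation drives both the fetal
#' pulsatile absorption change and, through the fetal baseline mu_a, the
#' fetal partial pathlength:
#' \code{delta OD_fetus = <L_fetus>(lambda; S) * delta mu_a,fetus(lambda; S)}.
#' Maternal layers keep the stack's configured properties.
#'
#' @param spo2_candidate fetal saturation candidate, fraction (vectorised).
#' @param stack a [tissue_stack()].
#' @param r source-detector distance, mm.
#' @param fetal_hbt fetal HbT, uM (default: stack value).
#' @param pulse_fraction fractional systolic change of fetal mu_a.
#' @param wavelengths nm.
#' @param table extinction table.
#' @return an [od_spectrum()] for scalar input; a matrix
#'   (candidates x wavelengths) of delta-OD values for vector input.
#' @export
analytical_dod_fetal <- function(spo2_candidate, stack, r, fetal_hbt = NULL,
                                 pulse_fraction = 0.05,
                                 wavelengths = stack$wavelengths,
                                 table = hb_extinction()) {
  stopifnot(inherits(stack, "tissue_stack"),
            all(spo2_candidate >= 0), all(spo2_candidate <= 1))
  fl <- stack$fetal_layer
  if (fl != length(stack$layers))
    stop("multi-layer model expects the fetal layer to be the terminal layer",
         call. = FALSE)
  if (is.null(fetal_hbt)) fetal_hbt <- stack$layers[[fl]]$hbt
  Lf <- .fetal_pathlength_grid(spo2_candidate, stack, r, fetal_hbt,
                               wavelengths, table)
  eps <- .eps_mix(spo2_candidate, wavelengths, table)
  dod <- Lf * eps * pulse_fraction * fetal_hbt
  if (length(spo2_candidate) == 1L)
    return(od_spectrum(wavelengths, dod[1, ], r))
  dod
}

# Fetal partial pathlength <L_fetus>(lambda; S) for a grid of candidate
# saturations, evaluated in one batched solver call (candidates x wavelengths
# x central-difference sides share one Hankel grid).
.fetal_pathlength_grid <- function(spo2, stack, r, fetal_hbt, wavelengths,
                                   table, thickness_scale = 1) {
  nL <- length(stack$layers)
  n_c <- length(spo2); n_w <- length(wavelengths)
  d <- .stack_thk(stack)
  d[-nL] <- d[-nL] * thickness_scale
  mua_st <- .stack_mua(stack, wavelengths, table)    # nL x n_w
  musp_st <- .stack_musp(stack, wavelengths)
  mua_f <- .eps_mix(spo2, wavelengths, table) * fetal_hbt  # n_c x n_w
  h <- .fd_step(mua_f)
  # case layout: (candidate, side) fastest, then wavelength
  C <- n_c * 2 * n_w
  idx_w <- rep(seq_len(n_w), each = 2 * n_c)
  mua <- mua_st[, idx_w, drop = FALSE]
  fet <- rbind(mua_f + h, mua_f - h)                 # 2n_c x n_w
  mua[nL, ] <- as.numeric(fet)
  musp <- musp_st[, idx_w, drop = FALSE]
  lnR <- log(.layered_Rr(r, mua, musp, d,
                         stack$layers[[1]]$refractive_index))
  dim(lnR) <- c(n_c, 2, n_w)
  Lf <- -(lnR[, 1, ] - lnR[, 2, ]) / (2 * h)         # n_c x n_w
  matrix(Lf, n_c, n_w)
}

#' Normalize a pulsatile spectrum at a reference wavelength
#'
#' Divides every delta-OD by the reference-wavelength value, removing
#' wavelength-independent gains (pulse amplitude, detector gain, spectrogram
#' scale). The reference entry becomes exactly 1.
#'
#' @param spectrum an [od_spectrum()] or numeric vector.
#' @param reference_index index of the reference wavelength (default 1).
#' @param eps_tol degenerate-spectrum guard: error if the reference magnitude
#'   is below this (default 1e-12).
#' @return same type as input, normalized.
#' @export
normalize_spectrum <- function(spectrum, reference_index = 1L,
                               eps_tol = 1e-12) {
  v <- if (inherits(spectrum, "od_spectrum")) spectrum$dod else spectrum
  ref <- v[reference_index]
  if (!is.finite(ref) || abs(ref) < eps_tol)
    stop("degenerate spectrum: reference delta-OD magnitude below tolerance",
         call. = FALSE)
  if (inherits(spectrum, "od_spectrum")) {
    spectrum$dod <- v / ref
    spectrum
  } else v / ref
}

#' Estimate SpO2 by normalized-spectrum grid search
#'
#' Sweeps the candidate grid, computes the analytical normalized spectrum for
#' each candidate (single- or multi-layer model per the context), and returns
#' the candidate minimizing the residual sum of squares against the
#' normalized measured spectrum. Ties break toward the lower saturation;
#' a minimum at either grid boundary sets the \code{railed} flag.
#'
#' @param measured an [od_spectrum()].
#' @param context a [fit_context()].
#' @param thickness_scale internal multiplier applied to the estimator's
#'   maternal thickness inputs (used by perturbation studies; default 1).
#' @param table extinction table.
#' @return object of class \code{spo2_estimate}: \code{spo2} (percent),
#'   \code{rss_curve}, \code{grid}, \code{railed}, \code{n_wavelengths_used}.
#' @export
estimate_spo2 <- function(measured, context, thickness_scale = 1,
                          table = hb_extinction()) {
  stopifnot(inherits(measured, "od_spectrum"), inherits(context, "fit_context"))
  wl <- measured$wavelengths
  r <- measured$sd_distance
  grid <- context$grid
  meas_n <- normalize_spectrum(measured$dod, context$reference_index)
  if (context$mode == "multi_layer") {
    Lf <- .fetal_pathlength_grid(grid, context$stack, r, context$fetal_hbt,
                                 wl, table, thickness_scale)
    eps <- .eps_mix(grid, wl, table)
    dod <- Lf * eps                      # pulse fraction cancels in the ratio
  } else {
    eps <- .eps_mix(grid, wl, table)
    mua <- eps * context$assumed_hbt
    musp <- reduced_scattering(context$scat_amplitude, context$scat_power, wl)
    L <- (1.5 * rep(musp, each = length(grid)) * r^2) /
      (r * sqrt(3 * mua * rep(musp, each = length(grid))) + 1)
    dod <- L * eps
  }
  ref <- dod[, context$reference_index]
  if (any(abs(ref) < 1e-300))
    stop("degenerate analytical spectrum on the candidate grid", call. = FALSE)
  dod_n <- dod / ref
  rss <- rowSums((dod_n - rep(meas_n, each = length(grid)))^2)
  i <- which.min(rss)                    # ties resolve to the lower candidate
  structure(list(spo2 = 100 * grid[i], rss_curve = rss, grid = grid,
                 railed = i == 1L || i == length(grid),
                 n_wavelengths_used = length(wl)),
            class = "spo2_estimate")
}

#' @export
print.spo2_estimate <- function(x, ...) {
  cat(sprintf("SpO2 estimate: %.0f%%%s (RSS %.3g, %d wavelengths)\n",
              x$spo2, if (x$railed) " [railed]" else "",
              min(x$rss_curve), x$n_wavelengths_used))
  invisible(x)
}
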
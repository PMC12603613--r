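#' Cleaning configuration for SpO2 traces
#'
#' @param rail_threshold percent; estimates above this are treated as
#'   algorithm failures (capped values near 100) and set to missing
#'   (default 95).
#' @param hampel_sigma outlier threshold in robust standard deviations
#'   (default 2).
#' @param window_length s; Hampel and smoothing window (default 360,
#'   i.e. ~6 min).
#' @param smooth apply the Gaussian smoothing stage (default TRUE). The
#'   smoothing kernel sigma is \code{window_length/6}.
#' @return object of class \code{cleaning_config}.
#' @export
cleaning_config <- function(rail_threshold = 95, hampel_sigma = 2,
                            window_length = 360, smooth = TRUE) {
  stopifnot(rail_threshold > 0, rail_threshold <= 100, window_length > 0,
            hampel_sigma > 0)
  structure(list(rail_threshold = rail_threshold,
                 hampel_sigma = hampel_sigma,
                 window_length = window_length, smooth = smooth),
            class = "cleaning_config")
}

# missing-aware Hampel filter: replace points deviating from the running
# median by more than sigma_mult robust SDs (1.4826*MAD) with that median
.hampel_na <- function(x, half_width, sigma_mult) {
  n <- length(x)
  out <- x
  for (i in seq_len(n)) {
    if (is.na(x[i])) next
    w <- x[max(1, i - half_width):min(n, i + half_width)]
    w <- w[!is.na(w)]
    if (length(w) < 3) next
    med <- stats::median(w)
    s <- 1.4826 * stats::median(abs(w - med))
    if (s > 0 && abs(x[i] - med) > sigma_mult * s) out[i] <- med
  }
  out
}

# missing-aware Gaussian smoothing (normalized convolution)
.gauss_smooth_na <- function(x, t, sigma) {
  out <- rep(NA_real_, length(x))
  ok <- !is.na(x)
  if (!any(ok)) return(out)
  for (i in seq_along(x)) {
    w <- exp(-0.5 * ((t - t[i]) / sigma)^2)
    w[!ok] <- 0
    if (sum(w) > 0) out[i] <- sum(w * x, na.rm = TRUE) / sum(w)
  }
  out
}

#' Clean and smooth a raw SpO2 estimate trace
#'
#' Three stages: (1) estimates above the rail threshold become missing
#' (boundary-railed fit failures cap near 100); (2) Hampel outlier
#' replacement over the configured window; (3) missing-aware Gaussian
#' smoothing with the same window. Stages 1-2 are idempotent; smoothing is
#' a genuine filter and is not.
#'
#' @param time frame times, s (uniform spacing; gaps allowed as NA values).
#' @param spo2 raw estimates, percent.
#' @param config a [cleaning_config()].
#' @return data.frame with columns \code{time}, \code{spo2} (cleaned,
#'   possibly smoothed) and \code{raw}.
#' @export
clean_spo2_trace <- function(time, spo2, config = cleaning_config()) {
  stopifnot(length(time) == length(spo2))
  if (all(is.na(spo2))) stop("all estimates missing", call. = FALSE)
  x <- spo2
  x[x > config$rail_threshold] <- NA_real_
  if (all(is.na(x))) stop("no estimates survive rail removal", call. = FALSE)
  dt <- stats::median(diff(time))
  hw <- max(1L, round(config$window_length / (2 * dt)))
  x <- .hampel_na(x, hw, config$hampel_sigma)
  if (config$smooth) x <- .gauss_smooth_na(x, time, config$window_length / 6)
  data.frame(time = time, spo2 = x, raw = spo2)
}

#' Mean absolute error on the percent scale
#'
#' @param estimates,truths percent; pairs with missing values are dropped.
#' @return MAE, percent.
#' @export
mae <- function(estimates, truths) {
  stopifnot(length(estimates) == length(truths))
  ok <- !is.na(estimates) & !is.na(truths)
  if (!any(ok)) stop("no complete pairs", call. = FALSE)
  mean(abs(estimates[ok] - truths[ok]))
}

#' Pearson correlation between estimates and reference values
#'
#' @param estimates,truths numeric; >= 3 complete pairs with nonzero
#'   variance required.
#' @return correlation coefficient.
#' @export
pearson_r <- function(estimates, truths) {
  ok <- !is.na(estimates) & !is.na(truths)
  if (sum(ok) < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(estimates[ok]) == 0 || stats::sd(truths[ok]) == 0)
    stop("zero variance: correlation undefined", call. = FALSE)
  stats::cor(estimates[ok], truths[ok])
}

# run the multi-layer estimator over one cohort at one SD distance with the
# estimator's inputs optionally perturbed; forward data stay untouched
.fit_cohort <- function(cohort, sd_distance, mua_scale = 1, musp_scale = 1,
                        thickness_scale = 1, table = hb_extinction()) {
  si <- match(paste0("sd", sd_distance), rownames(cohort$subjects[[1]]$dod))
  if (is.na(si)) stop("sd_distance not present in cohort", call. = FALSE)
  wl <- cohort$config$wavelengths
  res <- lapply(cohort$subjects, function(su) {
    st <- su$stack
    # perturb the estimator's assumed properties, not the data
    if (mua_scale != 1 || musp_scale != 1) {
      st$layers <- lapply(st$layers, function(l) {
        l$hbt <- l$hbt * mua_scale          # mu_a scales linearly with HbT
        l$scat_amplitude <- l$scat_amplitude * musp_scale
        l
      })
    }
    ctx <- fit_context("multi_layer", stack = st,
                       pulse_fraction = cohort$config$pulse_fraction)
    m <- od_spectrum(wl, su$dod[si, ], sd_distance)
    est <- estimate_spo2(m, ctx, thickness_scale = thickness_scale,
                         table = table)
    c(truth = su$fetal_sao2, spo2 = est$spo2, railed = est$railed)
  })
  as.data.frame(do.call(rbind, res))
}

#' Parameter-perturbation robustness study
#'
#' Re-runs the multi-layer estimator over a cohort with its input parameters
#' (absorption, scattering, or maternal thicknesses) uniformly scaled, while
#' the forward spectra stay at the true values. Railed estimates are kept at
#' their capped value so failures enter the error metrics.
#'
#' @param cohort a [run_virtual_cohort()] result.
#' @param sd_distance mm (one of the cohort's distances).
#' @param conditions data.frame with columns \code{target}
#'   (\code{"ideal"}, \code{"mu_a"}, \code{"mu_s_prime"}, \code{"thickness"})
#'   and \code{factor}; default: the ideal case plus the six +/-20%
#'   perturbations.
#' @param table extinction table.
#' @return object of class \code{cohort_result}: per-subject rows
#'   (condition, truth, estimate, railed) plus an aggregate table with MAE,
#'   Pearson R and median signed error per condition.
#' @export
perturbation_study <- function(cohort, sd_distance,
                               conditions = default_perturbations(),
                               table = hb_extinction()) {
  rows <- lapply(seq_len(nrow(conditions)), function(i) {
    tg <- conditions$target[i]; fc <- conditions$factor[i]
    df <- .fit_cohort(cohort, sd_distance,
                      mua_scale = if (tg == "mu_a") fc else 1,
                      musp_scale = if (tg == "mu_s_prime") fc else 1,
                      thickness_scale = if (tg == "thickness") fc else 1,
                      table = table)
    df$condition <- if (tg == "ideal") "ideal" else sprintf("%s x%.1f", tg, fc)
    df$subject <- seq_len(nrow(df))
    df
  })
  rows <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(split(rows, rows$condition), function(d)
    data.frame(condition = d$condition[1],
               mae = mae(d$spo2, d$truth),
               r = tryCatch(pearson_r(d$spo2, d$truth), error = function(e) NA),
               median_signed_error = stats::median(d$spo2 - d$truth),
               err_q25 = stats::quantile(d$spo2 - d$truth, 0.25, names = FALSE),
               err_q75 = stats::quantile(d$spo2 - d$truth, 0.75, names = FALSE),
               frac_positive_error = mean(d$spo2 > d$truth),
               frac_railed = mean(d$railed))))
  rownames(agg) <- NULL
  structure(list(per_subject = rows, aggregate = agg,
                 sd_distance = sd_distance,
                 depth = cohort$config$fetal_depth),
            class = "cohort_result")
}

#' @export
print.cohort_result <- function(x, ...) {
  cat("perturbation study, depth", x$depth, "mm, SD", x$sd_distance, "mm\n")
  print(x$aggregate, digits = 3)
  invisible(x)
}

#' Default perturbation conditions (+/-20% in mu_a, mu_s', thickness)
#' @return data.frame of conditions including the ideal case.
#' @export
default_perturbations <- function() {
  data.frame(
    target = c("ideal", "mu_a", "mu_a", "mu_s_prime", "mu_s_prime",
               "thickness", "thickness"),
    factor = c(1, 0.8, 1.2, 0.8, 1.2, 0.8, 1.2)
  )
}

#' Compare single-layer and multi-layer estimators on one cohort
#'
#' Runs both algorithms on identical fetal pulsatile spectra. The
#' single-layer context uses each subject's layer-averaged optical
#' properties (plain average of HbT and of the scattering law parameters
#' across layers), since the homogeneous model has no layer structure.
#'
#' @param cohort a [run_virtual_cohort()] result.
#' @param sd_distance mm.
#' @param table extinction table.
#' @return list with per-subject data.frame (truth, multi, single, paired by
#'   subject id) and metrics (MAE and R per algorithm).
#' @export
compare_single_vs_multilayer <- function(cohort, sd_distance,
                                         table = hb_extinction()) {
  si <- match(paste0("sd", sd_distance), rownames(cohort$subjects[[1]]$dod))
  if (is.na(si)) stop("sd_distance not present in cohort", call. = FALSE)
  wl <- cohort$config$wavelengths
  rows <- lapply(seq_along(cohort$subjects), function(i) {
    su <- cohort$subjects[[i]]
    m <- od_spectrum(wl, su$dod[si, ], sd_distance)
    ctx_m <- fit_context("multi_layer", stack = su$stack,
                         pulse_fraction = cohort$config$pulse_fraction)
    hbt_bar <- mean(vapply(su$stack$layers, `[[`, 0, "hbt"))
    a_bar <- mean(vapply(su$stack$layers, `[[`, 0, "scat_amplitude"))
    b_bar <- mean(vapply(su$stack$layers, `[[`, 0, "scat_power"))
    ctx_s <- fit_context("single_layer", assumed_hbt = hbt_bar,
                         scat_amplitude = a_bar, scat_power = b_bar,
                         pulse_fraction = cohort$config$pulse_fraction)
    data.frame(subject = i, truth = su$fetal_sao2,
               multi = estimate_spo2(m, ctx_m, table = table)$spo2,
               single = estimate_spo2(m, ctx_s, table = table)$spo2)
  })
  rows <- do.call(rbind, rows)
  list(per_subject = rows,
       metrics = data.frame(
         algorithm = c("multi_layer", "single_layer"),
         mae = c(mae(rows$multi, rows$truth), mae(rows$single, rows$truth)),
         r = c(pearson_r(rows$multi, rows$truth),
               pearson_r(rows$single, rows$truth))))
}

#' Calibrate baseline layer properties by grid search
#'
#' Emulates the baseline-window calibration used with in-vivo recordings:
#' over a grid of physiologically plausible layer properties (maternal HbT
#' 40-70 uM, fetal HbT from the maternal value to 100 uM, scattering
#' amplitude 0.35-1.5 mm^-1 with maternal >= fetal, scattering power fixed
#' at 1), pick the parameter set whose estimated SpO2 over the baseline
#' frames is closest on average to the reference saturation. The winning set
#' is then held fixed for the rest of the recording.
#'
#' @param baseline a \code{fetal_od_series} restricted to the baseline
#'   window (see [extract_fetal_dod()]).
#' @param reference_sao2 reference fetal saturation during baseline, percent.
#' @param maternal_sao2 maternal saturation (fraction) assumed for the
#'   maternal layer during baseline.
#' @param maternal_thickness mm.
#' @param hbt_m,hbt_f,a_m,a_f candidate grids (uM, uM, mm^-1, mm^-1).
#' @param scat_power fixed b (default 1).
#' @param table extinction table.
#' @return list: \code{best} (named parameter set), \code{objective} (mean
#'   absolute baseline error, percent), \code{ties} (parameter sets within
#'   1e-9 of the optimum), and the full search \code{table}.
#' @export
calibrate_baseline_properties <- function(baseline, reference_sao2,
                                          maternal_sao2 = 0.98,
                                          maternal_thickness = 15,
                                          hbt_m = c(40, 55, 70),
                                          hbt_f = c(70, 85, 100),
                                          a_m = c(0.75, 1.1, 1.5),
                                          a_f = c(0.35, 0.75, 1.1),
                                          scat_power = 1,
                                          table = hb_extinction()) {
  if (length(baseline$time) == 0 || all(is.na(baseline$dod)))
    stop("empty baseline window", call. = FALSE)
  grid <- expand.grid(hbt_m = hbt_m, hbt_f = hbt_f, a_m = a_m, a_f = a_f)
  grid <- grid[grid$hbt_f >= grid$hbt_m | grid$hbt_f >= max(hbt_m), ]
  grid <- grid[grid$a_m >= grid$a_f, ]           # higher maternal scattering
  wl <- baseline$wavelengths
  frames <- which(rowSums(is.na(baseline$dod)) == 0)
  obj <- vapply(seq_len(nrow(grid)), function(g) {
    st <- tissue_stack(list(
      optical_layer(maternal_thickness, grid$hbt_m[g], maternal_sao2,
                    grid$a_m[g], scat_power),
      optical_layer(Inf, grid$hbt_f[g], 0.5, grid$a_f[g], scat_power)),
      wavelengths = wl)
    ctx <- fit_context("multi_layer", stack = st)
    ests <- vapply(frames, function(f)
      estimate_spo2(od_spectrum(wl, baseline$dod[f, ],
                                baseline$sd_distance), ctx,
                    table = table)$spo2, 0)
    mean(abs(ests - reference_sao2))
  }, 0)
  best <- which.min(obj)
  ties <- which(obj <= obj[best] + 1e-9)
  list(best = as.list(grid[best, ]), objective = obj[best],
       ties = grid[ties, ], table = cbind(grid, objective = obj))
}
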
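#' Detector specification for Monte-Carlo intensity tallies
#'
#' Square detector of given side centred at the source-detector distance,
#' mapped to the radially symmetric slab geometry by arc-weighted
#' integration: a photon exiting at radius \code{rho} contributes with the
#' fraction of the circle of radius \code{rho} that intersects the square
#' footprint. The arc fraction is tabulated on a radial grid of the given
#' pitch and interpolated.
#'
#' @param sd_distance centre distance from the source, mm.
#' @param side square side, mm (default 10).
#' @param pitch radial averaging-grid pitch, mm (default 0.1).
#' @return object of class \code{detector_spec}.
#' @export
detector_spec <- function(sd_distance, side = 10, pitch = 0.1) {
  stopifnot(sd_distance > 0, side > 0, pitch > 0, pitch < side)
  structure(list(sd_distance = sd_distance, side = side, pitch = pitch),
            class = "detector_spec")
}

# fraction of the circle of radius rho intersecting the square
# [sd-side/2, sd+side/2] x [-side/2, side/2]; exact interval arithmetic,
# valid for sd > side/2 (detector does not contain the source)
.arc_fraction <- function(rho, sd, side) {
  h <- side / 2
  x1 <- sd - h; x2 <- sd + h
  clamp <- function(v) pmin(1, pmax(-1, v))
  th_lo <- acos(clamp(x2 / rho))               # cos(theta) <= x2/rho
  th_hi <- acos(clamp(x1 / rho))               # cos(theta) >= x1/rho
  th_y  <- asin(clamp(h / rho))                # |sin(theta)| <= h/rho
  lo <- pmax(th_lo, 0)
  hi <- pmin(th_hi, th_y)
  frac <- pmax(0, hi - lo) / pi                # +/- theta symmetry
  frac[rho <= 0] <- 0
  frac
}

# interpolated arc-fraction lookup at the detector's grid pitch
.arc_lookup <- function(detector) {
  h <- detector$side / 2
  r0 <- max(0, detector$sd_distance - h - detector$pitch)
  r1 <- sqrt((detector$sd_distance + h)^2 + h^2) + detector$pitch
  grid <- seq(r0, r1 + detector$pitch, by = detector$pitch)
  vals <- .arc_fraction(grid, detector$sd_distance, detector$side)
  function(rho) {
    out <- numeric(length(rho))
    inside <- rho >= grid[1] & rho <= grid[length(grid)]
    out[inside] <- stats::approx(grid, vals, rho[inside])$y
    out
  }
}

#' Run the layered-slab photon Monte Carlo
#'
#' White Monte Carlo: photons random-walk with isotropic scattering at rate
#' \code{mu_s = mu_s'} and no absorption; per-layer pathlengths of every
#' photon escaping the top surface are recorded so that absorption for any
#' \code{mu_a} vector can be applied afterwards by exponential rescaling.
#' Fresnel reflection at the top boundary (tissue index / exterior 1.0) is
#' sampled probabilistically; photons deeper than \code{z_cutoff} are
#' terminated. Reproducible given \code{seed}.
#'
#' @param thickness per-layer thickness, mm (last layer semi-infinite).
#' @param mus per-layer scattering coefficient, mm^-1.
#' @param n_photons number launched (>= 1e5 for meaningful tallies).
#' @param seed integer RNG seed.
#' @param n_rel tissue refractive index relative to exterior (default 1.4).
#' @param z_cutoff deep-termination depth, mm (default 150).
#' @return object of class \code{photon_records}: \code{records} matrix with
#'   columns \code{radius, L_1..L_n}, unit \code{weights}, \code{launched},
#'   \code{n_deep}, and the run configuration.
#' @export
run_slab_mc <- function(thickness, mus, n_photons, seed, n_rel = 1.4,
                        z_cutoff = 150) {
  stopifnot(length(thickness) == length(mus), all(mus > 0),
            n_photons >= 1e5)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  res <- mc_walk_slab(as.numeric(thickness), as.numeric(mus), n_rel,
                      as.integer(n_photons), z_cutoff)
  if (nrow(res$records) == 0)
    warning("no photons detected; increase n_photons")
  structure(list(records = res$records, weights = rep(1, nrow(res$records)),
                 launched = res$launched, n_deep = res$n_deep, seed = seed,
                 thickness = thickness, mus = mus, n_rel = n_rel,
                 z_cutoff = z_cutoff),
            class = "photon_records")
}

#' Detected intensity from recorded photons under given absorption
#'
#' Pathlength rescaling: \code{I = sum_j w_j f(rho_j) exp(-sum_i mu_a,i L_ij)}
#' over recorded photons, with \code{f} the detector arc fraction.
#' Deterministic given the record set; exactly monotone decreasing in every
#' layer absorption.
#'
#' @param records a [run_slab_mc()] result.
#' @param mua per-layer absorption coefficients, mm^-1.
#' @param detector a [detector_spec()].
#' @return intensity in arbitrary units.
#' @export
detected_intensity <- function(records, mua, detector) {
  stopifnot(inherits(records, "photon_records"),
            inherits(detector, "detector_spec"))
  L <- length(records$mus)
  if (length(mua) != L)
    stop("mua length does not match the record set's layer count",
         call. = FALSE)
  rec <- records$records
  f <- .arc_lookup(detector)(rec[, 1])
  keep <- f > 0
  if (!any(keep)) return(0)
  expo <- rec[keep, -1, drop = FALSE] %*% (-as.numeric(mua))
  sum(records$weights[keep] * f[keep] * exp(expo))
}

# radially binned diffuse reflectance (per unit area per launched photon)
# with absorption applied by rescaling; used to validate against diffusion
.mc_radial_reflectance <- function(records, mua, breaks) {
  rec <- records$records
  w <- records$weights * exp(rec[, -1, drop = FALSE] %*% (-as.numeric(mua)))
  idx <- findInterval(rec[, 1], breaks)
  ok <- idx >= 1 & idx < length(breaks)
  tot <- vapply(seq_len(length(breaks) - 1),
                function(i) sum(w[ok & idx == i]), 0)
  area <- pi * diff(breaks^2)
  tot / area / records$launched
}

# absorption-weighted per-layer mean pathlengths of photons detected in a
# radial annulus; MC estimate of the diffusion partial pathlengths
.mc_partial_pathlengths <- function(records, mua, r_lo, r_hi) {
  rec <- records$records
  sel <- rec[, 1] >= r_lo & rec[, 1] < r_hi
  if (!any(sel)) return(rep(NA_real_, length(mua)))
  Lm <- rec[sel, -1, drop = FALSE]
  w <- records$weights[sel] * exp(Lm %*% (-as.numeric(mua)))
  as.numeric(crossprod(Lm, w) / sum(w))
}

#' Simulated fetal pulsatile spectra from the Monte-Carlo engine
#'
#' For each wavelength one record set is produced at that wavelength's
#' scattering; diastolic absorption comes from the stack's hemoglobin model
#' and the systolic state scales the fetal-layer mu_a by
#' \code{(1 + pulse_fraction)}. The fetal pulsatile signal is
#' \code{delta OD_fetus = ln(I_diastole / I_systole)} at each source-detector
#' distance.
#'
#' @param stack a [tissue_stack()].
#' @param wavelengths nm.
#' @param sd_distances mm (detector centres).
#' @param pulse_fraction systolic fractional fetal mu_a increase.
#' @param n_photons photons launched per wavelength.
#' @param seed integer; a distinct stream is derived per wavelength.
#' @param table extinction table.
#' @return matrix of delta-OD values, \code{length(sd_distances)} x
#'   \code{length(wavelengths)}, with dimnames.
#' @export
simulate_dod_fetus <- function(stack, wavelengths = stack$wavelengths,
                               sd_distances = c(30, 60, 90),
                               pulse_fraction = 0.05, n_photons = 1e6,
                               seed = 1, table = hb_extinction()) {
  stopifnot(inherits(stack, "tissue_stack"))
  fl <- stack$fetal_layer
  thk <- .stack_thk(stack)
  mua <- .stack_mua(stack, wavelengths, table)
  musp <- .stack_musp(stack, wavelengths)
  out <- matrix(NA_real_, length(sd_distances), length(wavelengths),
                dimnames = list(paste0("sd", sd_distances),
                                paste0("wl", wavelengths)))
  dets <- lapply(sd_distances, detector_spec)
  for (j in seq_along(wavelengths)) {
    recs <- run_slab_mc(thk, musp[, j], n_photons,
                        seed = .draw_seed(seed, j),
                        n_rel = stack$layers[[1]]$refractive_index)
    mua_d <- mua[, j]
    mua_s <- mua_d
    mua_s[fl] <- mua_s[fl] * (1 + pulse_fraction)
    for (i in seq_along(dets)) {
      I_d <- detected_intensity(recs, mua_d, dets[[i]])
      I_s <- detected_intensity(recs, mua_s, dets[[i]])
      out[i, j] <- if (I_d > 0 && I_s > 0) log(I_d / I_s) else NA_real_
    }
  }
  out
}

#' Simulate a virtual cohort of maternal-fetal tissue stacks
#'
#' Samples \code{config$n_subjects} stacks and produces each subject's fetal
#' pulsatile spectra at the requested source-detector distances, using either
#' the analytical layered-diffusion forward model (fast; exact inverse-crime
#' tier) or the slab Monte Carlo.
#'
#' @param config a [cohort_config()].
#' @param engine \code{"diffusion"} or \code{"mc"}.
#' @param sd_distances mm.
#' @param n_photons per wavelength, MC engine only.
#' @param table extinction table.
#' @return object of class \code{cohort}: list with \code{config},
#'   \code{sd_distances}, \code{engine} and per-subject entries
#'   (\code{stack}, \code{fetal_sao2} truth in percent, \code{dod} matrix).
#' @export
run_virtual_cohort <- function(config, engine = c("diffusion", "mc"),
                               sd_distances = c(60, 90), n_photons = 1e6,
                               table = hb_extinction()) {
  engine <- match.arg(engine)
  subjects <- vector("list", config$n_subjects)
  for (i in seq_len(config$n_subjects)) {
    st <- sample_virtual_subject(config, i)
    truth <- attr(st, "truth")$fetal_sao2
    if (engine == "diffusion") {
      dod <- t(vapply(sd_distances, function(r)
        analytical_dod_fetal(truth, st, r,
                             pulse_fraction = config$pulse_fraction,
                             wavelengths = config$wavelengths,
                             table = table)$dod,
        numeric(length(config$wavelengths))))
      dimnames(dod) <- list(paste0("sd", sd_distances),
                            paste0("wl", config$wavelengths))
    } else {
      dod <- simulate_dod_fetus(st, config$wavelengths, sd_distances,
                                config$pulse_fraction, n_photons,
                                seed = .draw_seed(config$seed, 10000 + i),
                                table = table)
    }
    subjects[[i]] <- list(stack = st, fetal_sao2 = 100 * truth, dod = dod)
  }
  structure(list(config = config, sd_distances = sd_distances,
                 engine = engine, subjects = subjects),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat("virtual cohort:", length(x$subjects), "subjects, fetal depth",
      x$config$fetal_depth, "mm,", x$engine, "engine, SD",
      paste(x$sd_distances, collapse = "/"), "mm\n")
  invisible(x)
}
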
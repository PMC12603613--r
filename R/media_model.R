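#' Bundled hemoglobin extinction coefficient table
#'
#' Loads the packaged oxy-/deoxy-hemoglobin molar extinction table
#' (700--900 nm, 2 nm grid). Values are in natural-log convention,
#' mm^-1 per uM, so that \code{mu_a = (eps_hbo*SaO2 + eps_hb*(1-SaO2)) * HbT}
#' gives mm^-1 directly for HbT in uM.
#'
#' @return A data.frame of class \code{hb_extinction} with columns
#'   \code{wavelength_nm}, \code{eps_hbo}, \code{eps_hb}.
#' @export
hb_extinction <- function() {
  path <- system.file("extdata", "hb_extinction.csv", package = "fetox",
                      mustWork = TRUE)
  tab <- utils::read.csv(path, comment.char = "#")
  stopifnot(all(diff(tab$wavelength_nm) > 0),
            all(tab$eps_hbo > 0), all(tab$eps_hb > 0))
  class(tab) <- c("hb_extinction", "data.frame")
  tab
}

#' Interpolate extinction coefficients at given wavelengths
#'
#' Linear interpolation within the table range; querying outside the tabulated
#' range is an error (extinction spectra cannot be safely extrapolated).
#'
#' @param table extinction table from [hb_extinction()].
#' @param wavelengths numeric vector, nm.
#' @return list with numeric vectors \code{eps_hbo} and \code{eps_hb}.
#' @export
extinction_at <- function(table, wavelengths) {
  rng <- range(table$wavelength_nm)
  if (any(wavelengths < rng[1] | wavelengths > rng[2]))
    stop("wavelength outside extinction table range [", rng[1], ", ", rng[2],
         "] nm", call. = FALSE)
  list(
    eps_hbo = stats::approx(table$wavelength_nm, table$eps_hbo, wavelengths)$y,
    eps_hb  = stats::approx(table$wavelength_nm, table$eps_hb,  wavelengths)$y
  )
}

#' Construct one optical tissue layer
#'
#' @param thickness mm; \code{Inf} for the terminal (semi-infinite) layer.
#' @param hbt total hemoglobin concentration, uM.
#' @param sao2 arterial oxygen saturation, fraction in \[0, 1\].
#' @param scat_amplitude reduced scattering at the reference wavelength, mm^-1.
#' @param scat_power scattering power-law exponent (unitless).
#' @param refractive_index tissue refractive index (default 1.4).
#' @return object of class \code{optical_layer}.
#' @export
optical_layer <- function(thickness, hbt, sao2, scat_amplitude,
                          scat_power = 1.0, refractive_index = 1.4) {
  stopifnot(is.numeric(thickness), length(thickness) == 1, thickness > 0,
            hbt >= 0, sao2 >= 0, sao2 <= 1, scat_amplitude > 0)
  structure(list(thickness = thickness, hbt = hbt, sao2 = sao2,
                 scat_amplitude = scat_amplitude, scat_power = scat_power,
                 refractive_index = refractive_index),
            class = "optical_layer")
}

#' Construct a layered tissue stack
#'
#' Ordered layers, surface first; exactly the last layer must be
#' semi-infinite. The fetal layer is by convention the last (deepest) layer.
#'
#' @param layers list of [optical_layer()] objects.
#' @param fetal_layer index of the fetal layer (default: last).
#' @param wavelengths nm, the wavelength set used for this stack.
#' @return object of class \code{tissue_stack}.
#' @export
tissue_stack <- function(layers, fetal_layer = length(layers),
                         wavelengths = c(700, 730, 760, 800, 830, 860)) {
  stopifnot(length(layers) >= 1,
            all(vapply(layers, inherits, TRUE, "optical_layer")))
  thk <- vapply(layers, `[[`, 0, "thickness")
  if (!is.infinite(thk[length(thk)]))
    stop("last layer must be semi-infinite (thickness = Inf)", call. = FALSE)
  if (any(is.infinite(thk[-length(thk)])))
    stop("only the last layer may be semi-infinite", call. = FALSE)
  if (fetal_layer < 1 || fetal_layer > length(layers))
    stop("fetal_layer index out of range", call. = FALSE)
  structure(list(layers = layers, fetal_layer = fetal_layer,
                 wavelengths = wavelengths),
            class = "tissue_stack")
}

#' @export
print.tissue_stack <- function(x, ...) {
  cat("tissue_stack:", length(x$layers), "layers, fetal layer",
      x$fetal_layer, "\n")
  for (i in seq_along(x$layers)) {
    l <- x$layers[[i]]
    cat(sprintf("  [%d] thk %s mm, HbT %.1f uM, SaO2 %.2f, a %.2f mm-1, b %.2f\n",
                i, format(l$thickness), l$hbt, l$sao2,
                l$scat_amplitude, l$scat_power))
  }
  cat("  fetal depth:", fetal_depth(x), "mm;  wavelengths:",
      paste(x$wavelengths, collapse = ", "), "nm\n")
  invisible(x)
}

#' Fetal depth of a stack (sum of thicknesses above the fetal layer)
#' @param stack a [tissue_stack()].
#' @return depth in mm.
#' @export
fetal_depth <- function(stack) {
  idx <- stack$fetal_layer
  if (idx == 1) return(0)
  sum(vapply(stack$layers[seq_len(idx - 1)], `[[`, 0, "thickness"))
}

# internal accessors used throughout; always n_layers x n_wavelengths
.stack_thk  <- function(stack) vapply(stack$layers, `[[`, 0, "thickness")
.stack_mua  <- function(stack, wavelengths, table) {
  m <- vapply(stack$layers, absorption_spectrum,
              numeric(length(wavelengths)),
              wavelengths = wavelengths, table = table)
  t(matrix(m, nrow = length(wavelengths)))
}
.stack_musp <- function(stack, wavelengths) {
  m <- vapply(stack$layers, function(l)
    reduced_scattering(l$scat_amplitude, l$scat_power, wavelengths),
    numeric(length(wavelengths)))
  t(matrix(m, nrow = length(wavelengths)))
}

#' Absorption spectrum of a layer from its hemoglobin content
#'
#' \code{mu_a(lambda) = (eps_HbO(lambda)*SaO2 + eps_Hb(lambda)*(1-SaO2)) * HbT},
#' arterial blood assumed the only absorber.
#'
#' @param layer an [optical_layer()].
#' @param wavelengths nm, within the table range.
#' @param table extinction table, default [hb_extinction()].
#' @return mu_a per wavelength, mm^-1.
#' @export
absorption_spectrum <- function(layer, wavelengths, table = hb_extinction()) {
  eps <- extinction_at(table, wavelengths)
  (eps$eps_hbo * layer$sao2 + eps$eps_hb * (1 - layer$sao2)) * layer$hbt
}

#' Pulsatile absorption change of a layer
#'
#' Systolic arterial inflow is modelled as a small fractional increase of HbT,
#' so \code{delta mu_a = pulse_fraction * mu_a} elementwise.
#'
#' @inheritParams absorption_spectrum
#' @param pulse_fraction fractional systolic HbT increase (default 0.05).
#' @return delta mu_a per wavelength, mm^-1.
#' @export
pulsatile_absorption <- function(layer, wavelengths, pulse_fraction = 0.05,
                                 table = hb_extinction()) {
  stopifnot(pulse_fraction >= 0, pulse_fraction < 1)
  pulse_fraction * absorption_spectrum(layer, wavelengths, table)
}

#' Reduced scattering from the power-law model
#'
#' \code{mu_s' = a * (lambda/lambda0)^(-b)}.
#'
#' @param a scattering amplitude (mu_s' at lambda0), mm^-1.
#' @param b scattering power, unitless.
#' @param wavelength nm.
#' @param lambda0 reference wavelength, nm (default 800).
#' @return mu_s' per wavelength, mm^-1.
#' @export
reduced_scattering <- function(a, b, wavelength, lambda0 = 800) {
  if (any(a <= 0) || any(wavelength <= 0) || lambda0 <= 0)
    stop("scattering amplitude and wavelengths must be positive", call. = FALSE)
  a * (wavelength / lambda0)^(-b)
}

#' Virtual-cohort sampling configuration
#'
#' Defaults emulate the simulation cohorts: fixed layer thicknesses per depth
#' preset (20 mm: 5+15 mm maternal; 35 mm: 20+15 mm), maternal SaO2 shared by
#' both maternal layers and drawn from U(0.90, 1.00), fetal SaO2 from
#' U(0.30, 0.70), per-layer HbT / scattering amplitude / power from
#' physiologic ranges, and a 5% systolic fetal pulse.
#'
#' @param n_subjects number of virtual subjects (default 50).
#' @param fetal_depth mm; preset 20 or 35.
#' @param hbt_range 2 x n_layers matrix-like list of per-layer HbT ranges (uM).
#' @param a_range range of scattering amplitude (mm^-1); maternal layers are
#'   forced to scatter at least as strongly as the fetal layer.
#' @param b_range range of scattering power.
#' @param maternal_sao2_range,fetal_sao2_range saturation ranges (fractions).
#' @param pulse_fraction systolic fractional mu_a increase in the fetal layer.
#' @param wavelengths nm.
#' @param seed integer RNG seed for the cohort.
#' @return object of class \code{cohort_config}.
#' @export
cohort_config <- function(n_subjects = 50, fetal_depth = 20,
                          hbt_range = list(c(20, 60), c(40, 80), c(60, 100)),
                          a_range = c(0.35, 1.5),
                          b_range = c(0.7, 1.4),
                          maternal_sao2_range = c(0.90, 1.00),
                          fetal_sao2_range = c(0.30, 0.70),
                          pulse_fraction = 0.05,
                          wavelengths = c(700, 730, 760, 800, 830, 860),
                          seed = 1L) {
  if (!fetal_depth %in% c(20, 35))
    stop("unknown fetal depth preset (expected 20 or 35 mm)", call. = FALSE)
  stopifnot(n_subjects >= 1, pulse_fraction > 0, pulse_fraction < 1)
  structure(list(n_subjects = as.integer(n_subjects),
                 fetal_depth = fetal_depth, hbt_range = hbt_range,
                 a_range = a_range, b_range = b_range,
                 maternal_sao2_range = maternal_sao2_range,
                 fetal_sao2_range = fetal_sao2_range,
                 pulse_fraction = pulse_fraction,
                 wavelengths = wavelengths, seed = as.integer(seed)),
            class = "cohort_config")
}

# deterministic sub-stream for one draw; kept below 2^31
.draw_seed <- function(seed, draw_index)
  as.integer((as.numeric(seed) * 7919 + draw_index * 104729) %% 2147483647)

#' Sample one virtual subject from a cohort configuration
#'
#' Deterministic given \code{(config$seed, draw_index)}. Thicknesses follow the
#' depth preset (5/15/Inf mm or 20/15/Inf mm); both maternal layers share one
#' sampled SaO2; maternal scattering amplitude is forced >= fetal.
#'
#' @param config a [cohort_config()].
#' @param draw_index subject index (1-based).
#' @return a [tissue_stack()] with attribute \code{"truth"} holding the
#'   sampled fetal SaO2.
#' @export
sample_virtual_subject <- function(config, draw_index) {
  stopifnot(inherits(config, "cohort_config"), draw_index >= 1)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(.draw_seed(config$seed, draw_index))
  thk <- if (config$fetal_depth == 20) c(5, 15, Inf) else c(20, 15, Inf)
  sao2_m <- stats::runif(1, config$maternal_sao2_range[1], config$maternal_sao2_range[2])
  sao2_f <- stats::runif(1, config$fetal_sao2_range[1], config$fetal_sao2_range[2])
  hbt <- vapply(config$hbt_range, function(r) stats::runif(1, r[1], r[2]), 0)
  a_f <- stats::runif(1, config$a_range[1], config$a_range[2])
  a_m <- stats::runif(2, a_f, config$a_range[2])  # maternal scattering >= fetal
  b   <- stats::runif(3, config$b_range[1], config$b_range[2])
  layers <- list(
    optical_layer(thk[1], hbt[1], sao2_m, a_m[1], b[1]),
    optical_layer(thk[2], hbt[2], sao2_m, a_m[2], b[2]),
    optical_layer(thk[3], hbt[3], sao2_f, a_f,   b[3])
  )
  st <- tissue_stack(layers, wavelengths = config$wavelengths)
  attr(st, "truth") <- list(fetal_sao2 = sao2_f, maternal_sao2 = sao2_m)
  st
}
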
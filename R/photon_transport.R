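#' Mean photon pathlength in a semi-infinite medium
#'
#' Closed-form diffusion result for reflectance geometry:
#' \deqn{<L> = \frac{\sqrt{3\mu_s'}}{2\sqrt{\mu_a}}
#'        \frac{r^2\sqrt{3\mu_a\mu_s'}}{r\sqrt{3\mu_a\mu_s'}+1}
#'      = \frac{3\mu_s' r^2/2}{r\sqrt{3\mu_a\mu_s'}+1}.}
#' Used by the single-layer self-calibrated estimator.
#'
#' @param mua absorption coefficient, mm^-1 (vectorised).
#' @param musp reduced scattering coefficient, mm^-1 (vectorised).
#' @param r source-detector distance, mm.
#' @return mean pathlength, mm.
#' @export
mean_pathlength_semi_infinite <- function(mua, musp, r) {
  if (any(mua <= 0) || any(musp <= 0) || any(r <= 0))
    stop("mua, musp and r must be positive", call. = FALSE)
  (1.5 * musp * r^2) / (r * sqrt(3 * mua * musp) + 1)
}

# ---------------------------------------------------------------------------
# N-layer CW diffusion Green's function in Hankel space.
#
# Each layer i: D_i phi'' - (mu_a_i + D_i s^2) phi = -delta(z - z0), with
# D_i = 1/(3 mu_s'_i), alpha_i = sqrt(s^2 + 3 mu_a_i mu_s'_i). The stack below
# layer 1 is folded into a surface admittance by the stable tanh recursion
#   beta_i = (beta_{i+1} - D_i alpha_i t_i) / (1 - beta_{i+1} t_i/(D_i alpha_i)),
# t_i = tanh(alpha_i d_i), beta_N = -D_N alpha_N. With the extrapolated
# boundary at z = -zb and isotropic source at z0 = 1/mu_s'_1, the surface
# fluence and flux reduce to (k = beta/(D1 alpha1), u = alpha1 (l1 - z0),
# w = alpha1 (l1 + zb), hatc_x = (1+exp(-2x))/2, hats_x = (1-exp(-2x))/2):
#   phi(0)    = F * (1 - exp(-2 alpha1 zb)) / 2
#   D phi'(0) = F * D1 alpha1 (1 + exp(-2 alpha1 zb)) / 2
#   F = exp(-alpha1 z0) (hatc_u - k hats_u) / (D1 alpha1 (hatc_w - k hats_w))
# For a single semi-infinite layer the hatc/hats ratios equal 1 (u, w -> Inf).
# Reflectance uses the n = 1.4 partial-current fractions 0.118/0.306.
# ---------------------------------------------------------------------------

.reff_groenhuis <- function(n_rel) {
  -1.440 / n_rel^2 + 0.710 / n_rel + 0.668 + 0.0636 * n_rel
}

# Exact real-space reflectance of the semi-infinite medium with layer-1
# properties (image-source solution of the extrapolated-boundary problem);
# vectorised over cases. This is the analytic inverse Hankel transform of the
# one-layer kernel, so the layered solver only needs quadrature for the
# (fast-decaying) multi-layer correction.
.dipole_R <- function(r, mua1, musp1, n_rel = 1.4) {
  D <- 1 / (3 * musp1)
  mueff <- sqrt(3 * mua1 * musp1)
  reff <- .reff_groenhuis(n_rel)
  zb <- 2 * D * (1 + reff) / (1 - reff)
  z0 <- 1 / musp1
  r1 <- sqrt(r^2 + z0^2)
  r2 <- sqrt(r^2 + (z0 + 2 * zb)^2)
  phi <- (exp(-mueff * r1) / r1 - exp(-mueff * r2) / r2) / (4 * pi * D)
  jz  <- (z0 * (mueff + 1 / r1) * exp(-mueff * r1) / r1^2 +
          (z0 + 2 * zb) * (mueff + 1 / r2) * exp(-mueff * r2) / r2^2) / (4 * pi)
  0.118 * phi + 0.306 * jz
}

# Hankel-space correction kernel R_N(s) - R_1(s) for an N>=2 layer stack,
# vectorised over spatial frequency s (rows) and property "cases" (columns).
# With k = beta/(D1 a1) the correction is proportional to (1+k) (zero for a
# homogeneous stack) and to exp(-2 a1 (l1 - z0)), so it decays on the scale
# of the first-layer thickness and needs only a short quadrature.
.diff_Rs <- function(s, mua, musp, d, n_rel = 1.4) {
  L <- nrow(mua); ns <- length(s)
  s2 <- s^2
  aL <- sqrt(outer(s2, 3 * mua[L, ] * musp[L, ], "+"))
  beta <- -rep(1 / (3 * musp[L, ]), each = ns) * aL
  if (L > 2) for (i in (L - 1):2) {
    ai <- sqrt(outer(s2, 3 * mua[i, ] * musp[i, ], "+"))
    Da <- rep(1 / (3 * musp[i, ]), each = ns) * ai
    ti <- tanh(ai * d[i])
    beta <- (beta - Da * ti) / (1 - beta * ti / Da)
  }
  a1 <- sqrt(outer(s2, 3 * mua[1, ] * musp[1, ], "+"))
  D1 <- 1 / (3 * musp[1, ])
  D1a <- rep(D1, each = ns) * a1
  k <- beta / D1a
  reff <- .reff_groenhuis(n_rel)
  zb <- 2 * D1 * (1 + reff) / (1 - reff)
  z0 <- 1 / musp[1, ]
  if (any(z0 >= d[1]))
    stop("source depth 1/musp exceeds first-layer thickness; ",
         "diffusion solution not valid for this stack", call. = FALSE)
  eu <- exp(-2 * a1 * (d[1] - rep(z0, each = ns)))
  ew <- exp(-2 * a1 * (d[1] + rep(zb, each = ns)))
  dratio <- (1 + k) * (eu - ew) / ((1 + ew) - k * (1 - ew))
  ezb <- exp(-2 * a1 * rep(zb, each = ns))
  pre <- exp(-a1 * rep(z0, each = ns)) *
    (0.118 * (1 - ezb) / (2 * D1a) + 0.306 * (1 + ezb) / 2)
  pre * dratio
}

# Gauss-Legendre nodes/weights on [-1, 1] (Golub-Welsch)
.gauss_legendre <- function(n) {
  i <- seq_len(n - 1)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- b; J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  list(x = e$values, w = 2 * e$vectors[1, ]^2)
}

# Composite-GL inverse Hankel grid for radius r: panels of width pi/r
# (aligned to J0 half-oscillations), 8 nodes each, up to s_max.
# Returns s nodes and weights that already fold in s*J0(s r)/(2 pi).
.hankel_grid <- function(r, s_max, n_gl = 8) {
  gl <- .gauss_legendre(n_gl)
  width <- pi / r
  n_panel <- max(8L, ceiling(s_max / width))
  edges <- seq(0, by = width, length.out = n_panel + 1)
  mid <- rep((edges[-1] + edges[-length(edges)]) / 2, each = n_gl)
  half <- width / 2
  s <- mid + half * rep(gl$x, n_panel)
  w <- half * rep(gl$w, n_panel)
  list(s = s, w = w * s * besselJ(s * r, 0) / (2 * pi))
}

# tail cutoff for the correction kernel: decays ~ exp(-s (2 l1 - z0)) with
# z0 <= ~3 mm for physiologic scattering; 27.6 e-folds puts the tail < 1e-12
# of the integrand peak.
.s_max_for <- function(d1, musp1) {
  z0 <- 1 / min(musp1)
  max(4, 27.6 / max(2 * d1 - z0, 1))
}

# Core evaluator: reflectance at radius r for a batch of property "cases".
# mua, musp: n_layers x n_cases matrices; d: thicknesses (last Inf).
.layered_Rr <- function(r, mua, musp, d, n_rel = 1.4, grid = NULL) {
  L <- length(d)
  if (is.null(dim(mua)))  mua  <- matrix(mua,  nrow = L)
  if (is.null(dim(musp))) musp <- matrix(musp, nrow = L)
  C <- max(ncol(mua), ncol(musp))
  if (ncol(mua)  == 1 && C > 1) mua  <- mua[,  rep(1, C), drop = FALSE]
  if (ncol(musp) == 1 && C > 1) musp <- musp[, rep(1, C), drop = FALSE]
  if (any(mua <= 0) || any(musp <= 0))
    stop("optical properties must be positive", call. = FALSE)
  if (!is.infinite(d[L]))
    stop("terminal layer must be semi-infinite", call. = FALSE)
  base <- .dipole_R(r, mua[1, ], musp[1, ], n_rel)
  if (L == 1) return(base)
  if (is.null(grid)) grid <- .hankel_grid(r, .s_max_for(d[1], musp[1, ]))
  base + as.numeric(crossprod(grid$w, .diff_Rs(grid$s, mua, musp, d, n_rel)))
}

#' Steady-state diffuse reflectance of a layered slab
#'
#' CW reflectance at radial distance \code{r} from a point source on an
#' N-layer laterally infinite slab (terminal layer semi-infinite), computed
#' from the layered diffusion Green's function by inverse Hankel transform
#' with an extrapolated boundary (refractive index 1.4 tissue / 1.0 exterior
#' by default). Units are per mm^2 up to a fixed normalization.
#'
#' @param stack a [tissue_stack()].
#' @param r source-detector distance, mm.
#' @param wavelength nm (scalar or vector).
#' @param table extinction table.
#' @return reflectance per wavelength.
#' @export
layered_reflectance <- function(stack, r, wavelength = stack$wavelengths,
                                table = hb_extinction()) {
  stopifnot(inherits(stack, "tissue_stack"), r > 0)
  d <- .stack_thk(stack)
  mua <- .stack_mua(stack, wavelength, table)    # L x n_lambda
  musp <- .stack_musp(stack, wavelength)
  n_rel <- stack$layers[[1]]$refractive_index
  out <- .layered_Rr(r, mua, musp, d, n_rel)
  if (any(!is.finite(out) | out <= 0))
    stop("layered reflectance quadrature failed (non-finite or non-positive); ",
         "check optical properties", call. = FALSE)
  out
}

# finite-difference step for d ln R / d mu_a
.fd_step <- function(mua) pmax(1e-4, 0.01 * mua)

# partial pathlengths for a batch: mua L x C, returns n_layer_idx x C.
# layer_index may be a vector; "total" (all layers jointly) via layer_index = 0.
.partial_L_batch <- function(r, mua, musp, d, layer_index, n_rel = 1.4,
                             grid = NULL) {
  if (is.null(dim(mua)))  mua  <- matrix(mua,  nrow = length(d))
  if (is.null(dim(musp))) musp <- matrix(musp, nrow = length(d))
  if (is.null(grid) && length(d) > 1)
    grid <- .hankel_grid(r, .s_max_for(d[1], musp[1, ]))
  C <- ncol(mua)
  out <- matrix(NA_real_, length(layer_index), C)
  for (j in seq_along(layer_index)) {
    li <- layer_index[j]
    if (li == 0) {                    # all layers jointly -> total pathlength
      h <- pmax(1e-4, 0.01 * apply(mua, 2, min))
      up <- mua + rep(h, each = nrow(mua))
      dn <- mua - rep(h, each = nrow(mua))
    } else {
      h <- .fd_step(mua[li, ])
      up <- mua; up[li, ] <- up[li, ] + h
      dn <- mua; dn[li, ] <- dn[li, ] - h
    }
    Ru <- .layered_Rr(r, up, musp, d, n_rel, grid)
    Rd <- .layered_Rr(r, dn, musp, d, n_rel, grid)
    out[j, ] <- -(log(Ru) - log(Rd)) / (2 * h)
  }
  out
}

#' Partial pathlength of photons in one layer
#'
#' Logarithmic derivative of the layered diffuse reflectance with respect to
#' that layer's absorption coefficient,
#' \code{<L_i>(r) = -(1/R) dR/dmu_a,i}, evaluated by a central finite
#' difference with step \code{max(1e-4, 0.01*mu_a,i)} mm^-1.
#'
#' @inheritParams layered_reflectance
#' @param layer_index which layer (1 = surface); 0 perturbs all layers jointly
#'   and returns the total mean pathlength.
#' @return partial pathlength(s) in mm, one per wavelength.
#' @export
partial_pathlength <- function(stack, r, layer_index,
                               wavelength = stack$wavelengths,
                               table = hb_extinction()) {
  stopifnot(inherits(stack, "tissue_stack"), r > 0,
            layer_index >= 0, layer_index <= length(stack$layers))
  d <- .stack_thk(stack)
  mua <- .stack_mua(stack, wavelength, table)
  musp <- .stack_musp(stack, wavelength)
  out <- .partial_L_batch(r, mua, musp, d, layer_index,
                          stack$layers[[1]]$refractive_index)[1, ]
  if (any(out < 0))
    stop("negative partial pathlength from finite difference; ",
         "retry with a smaller step", call. = FALSE)
  out
}

#' Partial-pathlength spectrum across wavelengths
#'
#' Elementwise [partial_pathlength()] across a wavelength vector (a single
#' Hankel grid is shared across the batch).
#'
#' @inheritParams partial_pathlength
#' @param wavelengths nm vector.
#' @return numeric vector of \code{<L_i>} per wavelength, mm.
#' @export
pathlength_spectrum <- function(stack, r, wavelengths, layer_index,
                                table = hb_extinction()) {
  partial_pathlength(stack, r, layer_index, wavelengths, table)
}
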
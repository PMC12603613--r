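---
title: "Multi-layer self-calibrated transabdominal fetal pulse oximetry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-layer self-calibrated transabdominal fetal pulse oximetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Transabdominal fetal pulse oximetry tries to read fetal arterial oxygen
saturation (SaO2, estimated optically as SpO2) through the maternal abdomen
with near-infrared light in reflectance geometry. Two things make this much
harder than adult finger oximetry. First, fetal saturations are low
(30--70%), far outside the range where empirically calibrated adult pulse
oximeters are valid, and a fetal calibration study is not feasible. Second,
light must cross several maternal layers (adipose, rectus muscle + uterus)
before sampling fetal tissue, so the detected pulsatile signal mixes maternal
and fetal contributions with different saturations, hemoglobin
concentrations and heart rates.

`fetox` implements a *self-calibrated* estimator that avoids empirical
calibration by modelling how the photon pathlength itself depends on
saturation, and a *multi-layer* extension that attributes absorption changes
to the correct tissue layer through photon partial pathlengths.

## The model

**Modified Beer--Lambert law.** The cardiac pulsation produces an optical
density change per wavelength,

$$\Delta\mathrm{OD}^{\lambda} = \ln(I_d^{\lambda}/I_s^{\lambda})
  = \langle L\rangle^{\lambda}\,\Delta\mu_a^{\lambda},$$

with $I_d, I_s$ diastolic/systolic intensities. Absorption is modelled as
hemoglobin-dominated,
$\mu_a = [\varepsilon_{HbO}S + \varepsilon_{Hb}(1-S)]\,\mathrm{HbT}$, and the
arterial pulsation as a small fractional HbT increase (5% by default), so
$\Delta\mu_a = [\varepsilon_{HbO}S + \varepsilon_{Hb}(1-S)]\cdot
f\,\mathrm{HbT}$.

**Single-layer form.** For a homogeneous semi-infinite medium the mean
pathlength has the closed diffusion form implemented in
`mean_pathlength_semi_infinite()`,
$\langle L\rangle = \tfrac{3}{2}\mu_s' r^2 / (r\sqrt{3\mu_a\mu_s'} + 1)$,
with $r$ the source--detector (SD) distance. Because $\mu_a$ depends on $S$,
so does $\langle L\rangle$: that dependence is what replaces the empirical
calibration curve.

**Multi-layer form.** In layered tissue
$\Delta\mathrm{OD} = \sum_i \langle L_i\rangle \Delta\mu_{a,i}$, and after
the fetal component is isolated (the fetal heart rate differs from the
maternal one) only the fetal term survives:
$\Delta\mathrm{OD}_{fetus} = \langle L_{fetus}\rangle\,\Delta\mu_{a,fetus}$.
The fetal partial pathlength is the logarithmic derivative of the diffuse
reflectance, $\langle L_i\rangle(r) = -\partial \ln R(r)/\partial\mu_{a,i}$,
evaluated by central finite differences
(step $\max(10^{-4}, 0.01\,\mu_{a,i})\,\mathrm{mm}^{-1}$) on the layered
diffusion model described below.

**Fitting.** Measured and model spectra are normalized at a reference
wavelength (the first, by default), which cancels detector gain, pulse
amplitude and every other wavelength-independent factor, leaving only
spectral shape. SpO2 is the grid-search minimizer of the residual sum of
squares over 0--100% in 1% steps; ties break toward the lower saturation and
a minimum at a grid boundary raises the `railed` flag. The candidate
saturation drives *both* the pulsatile spectrum and the fetal baseline
$\mu_a$ inside the pathlength model. We adopted this convention after
verifying that it reproduces the expected perturbation phenomenology
(underestimated $\mu_a$ or $\mu_s'$ inputs bias SpO2 upward, thickness
underestimation biases upward); the alternative — holding the fetal baseline
at an assumed saturation — inverts the thickness-underestimation bias and
was rejected.

## The layered diffusion solver

The forward model is the steady-state diffusion Green's function of an
N-layer laterally infinite slab (terminal layer semi-infinite), solved in
Hankel space. Per layer, $D_i = 1/(3\mu_{s,i}')$ (kept independent of
$\mu_a$, so the pathlength derivative has no diffusion-coefficient term) and
$\alpha_i = \sqrt{s^2 + 3\mu_{a,i}\mu_{s,i}'}$. The layers below the source
layer are folded into a surface admittance by a `tanh` recursion that is
stable for any thickness; the extrapolated boundary uses the Groenhuis
polynomial for the internal reflection parameter at refractive index 1.4
(tissue) / 1.0 (exterior), and the surface reflectance operator is the
partial-current combination $0.118\,\phi + 0.306\,J$.

Numerically, the one-layer (semi-infinite) part of the kernel is inverted
analytically (image-source solution), and only the multi-layer *correction*
— which vanishes identically for a homogeneous stack and decays in spatial
frequency on the scale of the first-layer thickness — is integrated, with
composite Gauss--Legendre panels aligned to the half-oscillations of
$J_0(sr)$ and a tail cutoff of 27.6 e-folds ($<10^{-12}$ of the integrand
peak). Two consequences are worth knowing:

* the homogeneous N-layer solution collapses to the semi-infinite one
  *exactly* (the test suite checks $<10^{-6}$ relative);
* the closed-form mean pathlength used by the single-layer estimator and the
  total pathlength $-\partial\ln R/\partial\mu_a$ of the layered solver are
  different diffusion formulations; they agree to about 1% at $r = 30$ mm
  for typical properties, and the suite asserts agreement at the 10% level
  rather than forcing identity.

## Monte-Carlo validator

An independent check of the transport model is a white Monte Carlo in the
same slab geometry: photons random-walk with isotropic scattering at
$\mu_s = \mu_s'$ (similarity relation; the anisotropy of real tissue is not
modelled), no absorption during the walk, probabilistic Fresnel reflection
at the top surface, and termination below 150 mm. Each escaping photon's
exit radius and per-layer pathlengths are recorded, so any absorption vector
can be applied afterwards as $\exp(-\sum_i \mu_{a,i} L_i)$. This makes the
diastole/systole contrast noise-correlated: the same photons appear in both
states, and the fetal $\Delta\mathrm{OD}$ is resolvable with $10^6$--$10^7$
photons instead of the $10^9$-photon scale a two-run voxel simulation would
need. Detectors are 10 mm squares averaged in the radially symmetric
geometry by exact arc-fraction weighting, tabulated at a 0.1 mm pitch.

Because the Monte Carlo resolves the true angular escape distribution while
the diffusion reflectance uses the partial-current surface operator, their
*absolute* scales differ by a flat factor of roughly 10%; the reflectance is
defined up to a fixed normalization throughout, and comparisons estimate
that single factor before asserting shape agreement (within 5% over
$r$ = 20--60 mm at $10^7$ photons).

## Virtual cohorts and the synthetic recording

The cohort generator reproduces the simulation design: fixed layer
thicknesses per fetal-depth preset (20 mm depth: 5 mm adipose + 15 mm
muscle/uterus; 35 mm: 20 + 15), maternal SaO2 drawn once per subject from
U(0.90, 1.00) and shared by both maternal layers, fetal SaO2 from
U(0.30, 0.70), a 5% systolic fetal $\mu_a$ pulsation, and six wavelengths
700--860 nm. The per-layer HbT ranges (20--60, 40--80, 60--100 uM), the
scattering amplitude range (0.35--1.5 mm$^{-1}$, maternal forced at or above
fetal) and power range (0.7--1.4, drawn per layer) are only shown
graphically in the source experiments; the defaults bracket the printed
in-vivo values and are config-overridable. They should be read as
approximations, not measured population statistics.

The synthetic abdominal recording emulates a hypoxia experiment: a two-layer
sheep-style stack (15 mm maternal tissue, semi-infinite fetal layer, the
756--855 nm wavelength set), 50 Hz sampling, a maternal pulsation at 1.2 Hz,
a fetal pulsation whose saturation follows a programmed trajectory
(80% baseline, descent to 25%, recovery to 75%) with optional step
tachycardia, and multiplicative log-normal noise. What it does *not*
emulate: motion and contraction artifacts, probe-coupling drifts, breathing
modulation, the true broadband interference bursts of in-vivo data, or any
mismatch between the forward physics and the estimator's model (the
inverse-crime tier is deliberate). Passing end-to-end tests therefore
demonstrate correctness of the pipeline's bookkeeping and the identifiability
of the saturation from spectral shape — not field performance on real
recordings.

## Signal extraction

Intensities are converted to $\Delta\mathrm{OD}(t) = -\ln(I/I_0)$ with $I_0$
the channel mean. The cardiac reference is high-pass filtered at 1 Hz
(3rd-order zero-phase Butterworth). Spectrograms use a 20 s Hann window with
50% overlap and 4x zero-padding; the fetal heart rate is the
maximum-energy ridge through the fetal band (default 1.6--4 Hz, maternal
band 0.8--1.6 Hz) found by dynamic programming with a quadratic jump
penalty (scaled so that a full-band jump costs about 100 frame-normalized
power units; the penalty weight is exposed). The fetal spectrum per frame is
the spectrogram *magnitude* at the ridge bin, whose arbitrary scale is
harmless because the fit normalizes spectra.

## Cleaning and evaluation

Raw SpO2 traces are cleaned in three stages: estimates above 95% become
missing (boundary-railed failures cap near 100%), a missing-aware Hampel
filter (2 robust SDs, 360 s window) replaces outliers, and a missing-aware
Gaussian smoother (sigma = window/6) suppresses residual noise. The rail
stage is an exact projection (idempotent); the Hampel stage is nearly one
(median replacement slightly shifts neighbouring window statistics, so a
second pass can touch a few more points); the smoother is a genuine filter
and deliberately not idempotent. In perturbation studies, railed estimates enter
the MAE at their capped value — excluding them would hide exactly the
failures the thickness experiment is designed to expose.

## Design choices and known limitations

* **Extinction table.** Bundled as a text CSV, spline-interpolated from
  classic tabulated oxy/deoxyhemoglobin anchor values to a 2 nm grid,
  pre-converted to natural-log mm$^{-1}$uM$^{-1}$. Water, lipid and melanin
  absorption are omitted (hemoglobin-dominated approximation).
* **Which rail a failed fit hits.** Under 20% thickness *overestimation* the
  fit degenerates and rails; with this solver the boundary hit is 0% rather
  than 100%. The magnitude of the collapse (MAE ~ 50%, every estimate
  railed) is robust; the side is sensitive to the exact layered reflectance
  expression and should not be over-interpreted.
* **Problem sizes.** The shipped experiments use 50-subject cohorts per
  depth, $10^6$--$10^7$ Monte-Carlo photons, and 20-minute synthetic
  recordings; these sizes resolve every tested effect while keeping the full
  suite reproducible on one CPU.
* **Geometry.** Flat stratified layers, no abdominal curvature, no skin or
  amniotic-fluid layer, no detector numerical aperture. The terminal layer
  must be semi-infinite and the source depth $1/\mu_s'$ must lie inside the
  first layer (enforced with an error).

## A minimal session

```r
library(fetox)

# one virtual subject at the 35 mm depth preset
cfg <- cohort_config(n_subjects = 1, fetal_depth = 35, seed = 1)
st <- sample_virtual_subject(cfg, 1)

# forward fetal spectrum at SD 60 mm, truth = sampled fetal SaO2
truth <- attr(st, "truth")$fetal_sao2
m <- analytical_dod_fetal(truth, st, 60)

# estimate back
ctx <- fit_context("multi_layer", stack = st)
estimate_spo2(m, ctx)
```
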
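---
title: "Comparing optical, DXA and mammographic breast density: models and methods"
author: "osdensity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing optical, DXA and mammographic breast density: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Breast density — the proportion of fibroglandular (collagen- and water-rich)
tissue relative to fatty tissue — is one of the strongest biomarkers of
breast cancer risk, but mammography cannot be used in adolescents. Two
alternatives exist: dual-energy X-ray absorptiometry (DXA), which yields a
percent fibroglandular volume (%FGV) from a two-compartment decomposition of
the imaged breast, and red/near-infrared optical spectroscopy (OS), which
recovers bulk tissue composition (water, lipid, collagen, oxy- and
deoxy-hemoglobin) plus light-scattering parameters from transmission
spectra. Whether these modalities measure the same thing is an empirical
question that is answered by comparing them in the same participants:
adolescent daughters (OS + DXA) and their mothers (OS + DXA + mammography),
with group contrasts, mother–daughter pair correlations, and partial
correlations between device measures adjusted for age and BMI.

The raw study data are not publicly deposited, so this package makes the
whole comparison *pipeline* testable instead: a synthetic cohort generator
with known ground truth feeds the same spectral-fitting, index and
statistical machinery that real data would, and every stage is validated by
parameter-recovery, oracle-equivalence and calibration properties.

## Forward model

A breast held in the measurement cup is modeled as a homogeneous diffusive
slab of cup-dependent thickness (45/55/65/75 mm for cups A–D), with six
lateral source–detector offsets (0–50 mm) on the exit face. Absorption is
the Beer–Lambert mixture over the five chromophores,

$$\mu_a(\lambda) = \sum_i c_i\,\varepsilon_i(\lambda),$$

with concentrations $c_i$ in percent of tissue volume and specific
absorption $\varepsilon_i$ in mm⁻¹ per percent; scattering follows the
power law $\mu_s'(\lambda) = A\,(\lambda/\lambda_0)^{-b}$ with amplitude
$A$ (mm⁻¹ at the reference wavelength $\lambda_0 = 800$ nm, configurable)
and dimensionless power $b$. The detected signal is the steady-state
diffusion-approximation transmittance of the slab with extrapolated
boundaries: the isotropic source at depth $z_0 = 1/\mu_s'$ is mirrored in
the boundaries at $-z_e$ and $d + z_e$ ($z_e = 2AD$, $D = 1/3(\mu_a +
\mu_s')$), and the photon flux across the exit face is the signed sum over
the image-source dipole chain. The implementation sums 25 dipole orders per
side; the test suite and the acceptance script verify agreement with a
10,000-term brute-force series to better than 1e-9 relative over a grid of
optical properties (measured agreement is at machine precision).

An analytic forward model was chosen over Monte-Carlo photon-transport
look-up tables deliberately: it is exact for its geometry, fast enough for
multi-start fitting at desk scale, and — because the synthetic generator
and the inverse fit share it — the package's validation surface (parameter
recovery, optimizer-versus-grid equivalence, statistical calibration) does
not depend on which forward model is used.

### Chromophore basis

The literature extinction spectra are not redistributable here, so the
packaged basis (`reference_basis()`, exported as
`inst/extdata/chromophore_basis_synthetic.csv`) is a *synthetic* stand-in:
smooth Gaussian-mixture curves with the physically correct features — the
water peak near 978 nm, the lipid peak near 928 nm, collagen's 1035 nm peak
with a 910 nm shoulder, the steep deoxy-hemoglobin rise toward 650 nm with
its 760 nm bump, and the broad oxy-hemoglobin rise over 700–1000 nm — at
literature-scale magnitudes (hemoglobin curves are scaled so 1%
concentration corresponds to about 23 µM heme). These peak placements are
exactly what makes the 905/940/985 nm quality-control rules meaningful. A
`toy_basis()` of well-separated Gaussians is provided for fast,
well-conditioned unit tests. The basis is a configuration option and any
user-supplied CSV in the same format is accepted (`load_basis()`).

## Spectral pipeline

*Usability filter.* A spectrum is retained iff it has usable data at **≥ 7
wavelengths** (matching the 7 unknown parameters), **at 985 nm**, and **at
905 nm or 940 nm** — the rules that separate the primary lipid and water
absorption peaks. The 905/940/985 wavelengths count toward the ≥ 7 rule.
Exclusions are logged with machine-readable reasons, with the wavelength
count checked first (a 6-wavelength spectrum is logged as
`too_few_wavelengths` even if it also lacks 985 nm).

*Constrained multi-start fit.* The 7 parameters (water, lipid, collagen,
total hemoglobin, oxygenated fraction, amplitude, power) are fitted per
spectrum by bound-constrained Levenberg–Marquardt (`minpack.lm::nls.lm`) on
log-signal residuals from `n_starts = 8` Latin-hypercube starting points
over the bounds. Defaults for the bounds are water 4–90%, lipid 10–95%,
collagen 1–30%, total hemoglobin 0.2–1%, amplitude 0.1–4 mm⁻¹, power
0.05–5, and the joint cap: water + lipid + collagen + hemoglobin < 100%
(the remainder is unmodeled chromophores such as myoglobin). Numerical
choices, each configurable:

* **Residual scale**: log signals by default, since transmitted intensities
  span several decades across offsets; linear residuals are an option.
* **Joint constraints**: hemoglobin is fitted as total + oxygenated
  fraction, which turns the oxy+deoxy bound into a box bound; the sum cap is
  a quadratic penalty appended to the residual vector, with feasibility
  (sum ≤ cap + 1e-9) required at the solution for a fit to count as
  converged.
* **"At bounds"** means within 1e-6 of a bound in normalized [0, 1]
  parameter coordinates.
* **Selection**: the best fit is the smallest least-squares objective among
  converged candidates with **no more than 2 parameters at bounds**; if
  none qualifies, the spectrum is marked failed and contributes nothing
  downstream. Ties break by fewer parameters at bounds, then lower start
  index, so selection is deterministic.
* **Determinism**: per-spectrum start seeds are derived from the master
  seed and the spectrum key, so pipeline output is independent of row
  order.

Spectra are fitted independently (no joint fit across offsets); accepted
fits are averaged **per spectrum, unweighted, across both breasts** into one
composition per participant, mirroring how the instrument's analysis
averages before computing indices. Participants with no accepted fits are
flagged `no_usable_spectra` and excluded.

With the default 16-wavelength grid (650–1060 nm including 905, 940,
985 nm), noise-free recovery is essentially exact: the acceptance suite
requires ≥ 48 of 50 generator-drawn spectra recovered within 1 percentage
point for water/lipid/collagen (0.05 for hemoglobin and scattering power),
and median errors under 1% multiplicative noise below 5 points; measured
medians are well under 1.5 points. Identifiability from a *single*
source–detector distance rests on the spectral shape constraints (basis
curves plus the scattering power law); the multi-start scheme exists
because the 7-parameter objective has occasional local minima — roughly one
spectrum in fifty still lands in one at the default 8 starts, which is why
the selection rule and the multi-start count are exposed as options.

## Density indices

From the averaged composition (computed *after* averaging, not
per-spectrum):

* **%BDI** = (collagen + water) / (collagen + water + lipid) × 100. The
  printed form of this definition brackets ambiguously; the ratio reading is
  the only dimensionally sensible one and is used here.
* **Optical index** = log((collagen + water) × power) / lipid, with natural
  log and concentrations in percent units. At the reference daughter group
  means (water 17.2, collagen 21.3, lipid 46.0, power 1.3) this evaluates
  to 0.0851, which is the right magnitude for the published group mean
  (0.12) given that a mean of per-person ratios need not equal the ratio at
  the means; log10 or volume-fraction conventions land an order of
  magnitude away. The base is configurable.
* **%collagen-water** = collagen + water (the absolute-scale OS measure).
* **%FGV, AFGV** (DXA) and **%MBD, AMBD** (mammography): per-side percent
  (tissue volume / total volume × 100) first, then the unweighted mean over
  both breasts; absolute measures are means of per-side volumes. A missing
  side is permitted and flagged.

## Synthetic cohort generator

The generator emulates the study conditions so that every downstream stage
is testable against known truth. Its defaults are anchored to the reference
cohort's published group summaries (`cohort_reference_summaries()`): 42
mother–daughter pairs; daughter ages 14–17 (mean 15.1, SD 0.6), mothers
36–62 (47.5, 7.1); BMI 24.2 (5.1) and 30.7 (6.3); %BDI 46.0 (9.8) and 38.9
(9.1); and so on for lipid, water, collagen, hemoglobin, scattering,
breast volumes (derived from the %FGV and AFGV anchors) and the imaging
scales, including the compressed mammographic percent scale (%MBD mean 7.3,
SD 4.1, mothers only — daughters never receive mammographic measures).

Design of the dependence structure:

* Standardized true density loads on age, BMI and a latent residual with
  weights $(w_a, w_b, w_r)$, $w_a^2 + w_b^2 + w_r^2 = 1$ (defaults
  $w_a = 0.10/0.15$, $w_b = -0.35$), so density genuinely depends on the
  covariates and partial-correlation adjustment is exercised. Age and BMI
  are truncated normals; their standardization uses the analytic truncated
  means so the anchors are hit.
* The latent residual is shared within pairs with correlation
  $\rho/(w_{r,d}\,w_{r,m})$, making the configured `pair_rho` equal the
  pair correlation of true density itself (default 0.32, the published
  %BDI pair correlation). Configurations with `pair_rho` above
  $w_{r,d}w_{r,m} \approx 0.86$ are rejected.
* The composition *realizes* the latent density exactly: lipid and the
  collagen share of collagen+water are drawn from the anchor distributions
  and deterministically clamped into the jointly feasible box (all five
  bounds plus the < 100% cap), then collagen + water is solved from
  %BDI = t. Every draw satisfies every bound; high-density tails sit at the
  collagen cap, as real constrained fits would.
* Imaging measures are affine in true density with a direct BMI term
  (confounding), noise split into a shared and a per-side component
  (left/right correlations ≥ 0.9, matching the published 0.78–0.94 range),
  and volumes lognormal with per-side jitter.
* Spectral noise is multiplicative log-normal per wavelength (the
  instrument's signals are positive and the study reports no noise model);
  dropout is independent Bernoulli per wavelength, default probability 0.3.
  The study's own retention (241 of 2,016 spectra usable) implies heavier,
  spectrum-level-correlated missingness that an independent-dropout model
  cannot reproduce; the default instead keeps per-spectrum QC retention
  near 60% so that all QC rules fire regularly while most participants
  retain data. Both parameters, and the within-participant between-spectra
  variance (not reported in the study), are configurable.

What passing tests therefore show about real data — and what they do not:
recovery and calibration results certify the *inverse machinery and
statistics* under the generator's assumptions (homogeneous slab, shared
basis, independent noise and dropout). They do not certify the forward
model or basis against real breasts, where heterogeneity, probe-volume
effects and pectoral-muscle contamination (strongest in small cups) break
the homogeneous-slab assumption.

## Statistical machinery

Group contrasts use the pooled-variance Student t-test by default (Welch is
an option): recomputing the reference cohort's printed t-test p-values from
its printed summaries reproduces %BDI p = 0.0012 (printed 0.001), lipid
0.0067 (0.01), collagen 0.0142 (0.02) and AFGV 0.188 (0.19) — agreement to
one unit of the printed decimal, which is all the 1-decimal rounding of the
printed means and SDs supports. Pair correlations are Pearson over complete
pairs; partial correlations are computed by the residual method (least-
squares projection on covariates plus intercept, then Pearson on
residuals), with p from $t = r\sqrt{(n-2-k)/(1-r^2)}$, two-sided throughout,
significance at 0.05, no multiple-testing adjustment, complete cases per
comparison. The residual method is verified against the precision-matrix
formula to 1e-10 on random data, and reduces exactly to Pearson with zero
covariates. Influential-point sensitivity removes observations with
pre-removal |z| > 2 on either *measure* (covariates are not screened) in a
single pass and reports both results.

Two calibration properties tie the generator and statistics together, at
the study's own sample sizes:

* **Estimand recovery**: 200 cohorts generated with a true conditional
  correlation of 0.5 between %BDI and %FGV given age and BMI
  (`calibrate_fgv_link()` solves the link noise for the target), n = 42 per
  group. The mean pipeline estimate must lie within 0.05 of 0.5, and the
  spread of Fisher-z-transformed estimates must match the analytic
  $1/\sqrt{n-3-k}$ within 25% ($1/\sqrt{n-3-k}$ is the z-scale standard
  error; on the r scale the corresponding SD at $\rho = 0.5$ is
  $(1-\rho^2)/\sqrt{n-3-k}$, so the comparison is made on the z scale where
  the approximation is meant to hold). This loop exercises the generator →
  indices → partial-correlation path; the spectral-fitting stage is
  validated separately to sub-point accuracy by the recovery and grid-
  oracle properties, and running ~500,000 spectral fits inside the loop
  would add nothing to the estimand.
* **Type-I calibration**: 2,000 mother cohorts (n = 39) generated under
  conditional independence; the rejection rate at α = 0.05 must lie in
  [0.037, 0.063].

## Problem sizes and reproducibility

The analysis drivers under `analysis/` run the pipeline at full study
scale: 42 pairs, 2,016 simulated spectra, multi-start fitting of every
retained spectrum (a few minutes on one core). The test suite and
`scripts/acceptance.R` use the sizes stated above — 50 spectra per
recovery study, 20 grid-oracle instances, 10-point forward-model grid,
5,000-pair cohorts for distributional anchors, 200 and 2,000 replicate
cohorts for the calibration properties — chosen as the package's standard
verification sizes. Every random quantity descends from one master seed;
per-spectrum seeds are derived from the spectrum key so results do not
depend on processing order.

## Known limitations

* The homogeneous-slab diffusion model ignores tissue heterogeneity,
  boundary curvature, and the cup/frame mechanics; cup thicknesses and
  offsets are plausible defaults, not the instrument's engineering values.
* The synthetic basis is a stand-in with correct features, not the
  literature curves; absolute fitted concentrations are only as meaningful
  as the basis, which is why all validation is recovery-based.
* The hemoglobin percent-to-µM conversion is approximate (the published
  bound "0.2–1% (4.9–23 µM)" implies a non-constant factor; 23 µM per 1%
  is used for reporting).
* Independent per-wavelength dropout understates the clustered missingness
  of real sessions.
* Menstrual-cycle, menopausal-status and hormone-use covariates are out of
  scope, as are DXA calibration, image segmentation and dense-volume
  software internals: the pipeline starts from per-breast volumes.
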
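# osdensity

Comparing optical, DXA and mammographic measures of breast density and
breast tissue composition.

Breast density — the share of fibroglandular (collagen- and water-rich)
tissue in the breast — is a strong breast cancer risk biomarker, but
mammography cannot be used before screening age. Red/near-infrared optical
spectroscopy (OS) and dual-energy X-ray absorptiometry (DXA) can. This
package implements, as a fully testable pipeline with synthetic data of
known ground truth, the machinery needed to compare the three modalities in
a paired mother–daughter cohort:

* a **slab forward model** for transmission spectra (diffusion
  approximation with extrapolated-boundary image sources), with a packaged
  chromophore specific-absorption basis;
* the **spectral pipeline**: usability filtering (≥ 7 wavelengths, 985 nm
  present, 905 or 940 nm present), constrained multi-start least-squares
  fitting of the 7 chromophore/scattering parameters
  (water 4–90%, lipid 10–95%, collagen 1–30%, total hemoglobin 0.2–1%,
  amplitude 0.1–4 mm⁻¹, power 0.05–5, chromophore sum < 100%),
  best-fit selection with at most 2 parameters at bounds, and unweighted
  averaging over all usable spectra from both breasts;
* **density indices**:
  `%BDI = (collagen + water)/(collagen + water + lipid) × 100`,
  `optical index = log((collagen + water) · scattering power)/lipid`,
  %collagen-water, and side-averaged %FGV/AFGV (DXA) and %MBD/AMBD
  (mammography);
* a **synthetic paired-cohort generator** anchored to published group
  summaries (42 daughters, 39 mothers), with mother–daughter density
  correlation, age/BMI confounding, spectral noise and wavelength dropout,
  and imaging measures linked to true density;
* the **comparison statistics**: standardization, pooled-variance
  two-sample t-tests, Pearson pair correlations, partial correlations
  adjusted for age and BMI (residual method), influential-point
  sensitivity (|z| > 2), and the three report tables.

See `vignettes/device-comparison.Rmd` for the models, assumptions,
numerical choices and limitations.

## Worked example

The `analysis/` drivers run the full pipeline at study scale (42 pairs,
2,016 spectra) and write their tables under `results/`:

```sh
Rscript analysis/01_simulate_cohort.R   # truths, spectra, imaging, covariates
Rscript analysis/02_fit_spectra.R       # QC + constrained multi-start fitting
Rscript analysis/03_compute_indices.R   # %BDI, optical index, %FGV, %MBD, ...
Rscript analysis/04_compare_devices.R   # t-tests, pair and partial correlations
```

Stage 2 prints the QC accounting and fit acceptance (default seed 20180601):

```
QC: 1297 retained; excluded: missing_905_940=118, missing_985=587, too_few_wavelengths=14
fits accepted: 1286 of 1297 retained spectra
```

and stage 4 prints the comparison tables; the key lines from that run are

```
  BDI from OS, %               D 47.36 (7.83)  M 37.65 (8.58)  p=0.000  pair r=0.23
  ...
  %BDI from OS vs %FGV from DXA                    D 0.80 (p=0.000)  M 0.92 (p=0.000)
  %FGV from DXA vs %MBD from mammograms            D NA  M 0.78 (p=0.000)
  ...
sensitivity (%FGV vs %MBD, mothers): full r=0.78, after removing 1 influential point(s) r=0.76
```

The fitted %BDI reproduces the configured group difference (daughters
denser than mothers), mammographic cells are NA for daughters, and the
partial correlations between device measures reflect the configured link
strengths and noise — on synthetic data the devices agree exactly as well
as they were configured to, which is the point: the pipeline's estimates
are validated against known ground truth.

A minimal in-R session:

```r
library(osdensity)
cfg <- cohort_config(n_pairs = 4, seed = 7)
coh <- simulate_cohort(cfg)                       # truths, spectra, imaging
fit <- run_spectral_pipeline(coh$spectra, seed = 7)
m   <- compute_density_measures(fit$compositions, coh$measures)
rep <- build_report(m, coh$covariates)
rep$table2
```

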
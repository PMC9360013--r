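Package: osdensity
Title: Comparing Optical, DXA and Mammographic Measures of Breast Density
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for comparing breast density and breast tissue composition
    measured by red/near-infrared optical spectroscopy (OS), dual-energy X-ray
    absorptiometry (DXA) and mammography. Provides a diffusion-approximation
    slab forward model for transmission spectra, constrained multi-start
    chromophore fitting (water, lipid, collagen, oxy- and deoxy-hemoglobin plus
    scattering amplitude and power) with spectrum quality-control rules,
    density indices (percent breast density index, optical index, percent and
    absolute fibroglandular volume, percent and absolute mammographic density),
    a synthetic paired mother-daughter cohort generator with known ground
    truth, and the statistical comparison machinery: two-sample t-tests,
    Pearson pair correlations, covariate-adjusted partial correlations,
    influential-point sensitivity, and device-comparison report tables.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    lhs,
    minpack.lm,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    ggplot2,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
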
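#' Reference group summary statistics used as distributional anchors
#'
#' Published group summaries (mean, SD, n) of breast density and tissue
#' composition measures from a mother-daughter device-comparison cohort
#' (42 adolescent daughters, 39 adult mothers). The synthetic cohort
#' generator is anchored to these values, and the two-sample t-tests in the
#' report tables can be recomputed directly from them.
#'
#' @return A tibble with columns `measure`, `daughter_mean`, `daughter_sd`,
#'   `daughter_n`, `mother_mean`, `mother_sd`, `mother_n`.
#' @export
cohort_reference_summaries <- function() {
  tibble::tribble(
    ~measure,        ~daughter_mean, ~daughter_sd, ~mother_mean, ~mother_sd,
    "age",           15.1,           0.6,          47.5,         7.1,
    "bmi",           24.2,           5.1,          30.7,         6.3,
    "pct_bdi",       46.0,           9.8,          38.9,         9.1,
    "pct_fgv",       45.2,           15.4,         31.6,         9.9,
    "pct_mbd",       NA,             NA,           7.3,          4.1,
    "afgv_cm3",      219.1,          78.9,         245.6,        100.1,
    "ambd_cm3",      NA,             NA,           64.3,         23.6,
    "optical_index", 0.12,           0.68,         -0.20,        0.95,
    "lipid",         46.0,           10.8,         52.6,         10.5,
    "water",         17.2,           4.8,          15.1,         7.3,
    "collagen",      21.3,           5.7,          17.9,         6.5,
    "total_hb",      0.61,           0.16,         0.58,         0.15,
    "amplitude",     1.7,            0.5,          1.6,          0.5,
    "power",         1.3,            0.5,          1.4,          0.8
  ) |>
    dplyr::mutate(daughter_n = 42L, mother_n = 39L)
}

.group_defaults <- function(group) {
  if (group == "daughter") {
    list(age_mean = 15.1, age_sd = 0.6, age_min = 14, age_max = 17,
         bmi_mean = 24.2, bmi_sd = 5.1, bmi_min = 15, bmi_max = 55,
         bdi_mean = 46.0, bdi_sd = 9.8,
         lipid_mean = 46.0, lipid_sd = 10.8,
         collagen_share_mean = 0.553, collagen_share_sd = 0.04,
         thb_mean = 0.61, thb_sd = 0.16,
         oxyfrac_mean = 0.70, oxyfrac_sd = 0.05,
         amp_mean = 1.7, amp_sd = 0.5,
         power_mean = 1.3, power_sd = 0.5,
         volume_mean = 485, volume_cv = 0.30,
         weight_age = 0.10, weight_bmi = -0.35)
  } else {
    list(age_mean = 47.5, age_sd = 7.1, age_min = 36, age_max = 62,
         bmi_mean = 30.7, bmi_sd = 6.3, bmi_min = 15, bmi_max = 55,
         bdi_mean = 38.9, bdi_sd = 9.1,
         lipid_mean = 52.6, lipid_sd = 10.5,
         collagen_share_mean = 0.542, collagen_share_sd = 0.04,
         thb_mean = 0.58, thb_sd = 0.15,
         oxyfrac_mean = 0.65, oxyfrac_sd = 0.05,
         amp_mean = 1.6, amp_sd = 0.5,
         power_mean = 1.4, power_sd = 0.8,
         volume_mean = 777, volume_cv = 0.30,
         weight_age = 0.15, weight_bmi = -0.35)
  }
}

.imaging_defaults <- function() {
  # Affine links from true percent density to the imaging percent scales.
  # Intercepts place the group means at the reference anchors; noise SDs are
  # chosen so the marginal SDs land near the anchors given the link slopes
  # and the density-BMI correlation (see the methods vignette).
  list(
    daughter = list(
      fgv = list(intercept = -10.0, slope = 1.2, bmi_slope = -1.0,
                 noise_sd = 5.6, noise_share = 0.8)),
    mother = list(
      fgv = list(intercept = 0.48, slope = 0.8, bmi_slope = -0.6,
                 noise_sd = 3.4, noise_share = 0.8),
      mbd = list(intercept = -4.37, slope = 0.3, bmi_slope = -0.2,
                 noise_sd = 2.3, noise_share = 0.8,
                 volume_mean = 880, volume_cv = 0.30))
  )
}

#' Configuration of the synthetic paired cohort generator
#'
#' Defaults emulate the reference cohort: 42 mother-daughter pairs, group
#' means/SDs from [cohort_reference_summaries()], a mother-daughter
#' correlation of 0.32 for true percent density, 1% multiplicative
#' (log-normal) measurement noise per wavelength, and a 0.3 independent
#' per-wavelength dropout probability.
#'
#' @param n_pairs number of mother-daughter pairs (>= 2).
#' @param seed master integer seed; the whole cohort (truths, spectra,
#'   imaging measures) is bit-reproducible given it.
#' @param pair_rho mother-daughter correlation of true percent density, in
#'   [0, 1); must not exceed the product of the groups' residual density
#'   loadings (~0.86 with default covariate weights).
#' @param noise_sd SD of the multiplicative log-normal spectral noise
#'   (log scale), >= 0.
#' @param dropout_prob independent per-wavelength dropout probability, in
#'   [0, 1].
#' @param n_positions probe placements per source-detector distance (2 gives
#'   the instrument's 12 spectra per breast).
#' @param side_volume_sd SD of the per-side log volume jitter.
#' @param groups per-group parameter lists (see `osdensity:::.group_defaults`).
#' @param imaging imaging link parameters (see
#'   `osdensity:::.imaging_defaults`).
#' @param wavelengths measurement wavelength grid.
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_pairs = 42, seed = 1L, pair_rho = 0.32,
                          noise_sd = 0.01, dropout_prob = 0.3,
                          n_positions = 2, side_volume_sd = 0.04,
                          groups = list(daughter = .group_defaults("daughter"),
                                        mother = .group_defaults("mother")),
                          imaging = .imaging_defaults(),
                          wavelengths = default_wavelengths()) {
  cfg <- list(n_pairs = as.integer(n_pairs), seed = as.integer(seed),
              pair_rho = pair_rho, noise_sd = noise_sd,
              dropout_prob = dropout_prob, n_positions = as.integer(n_positions),
              side_volume_sd = side_volume_sd, groups = groups,
              imaging = imaging, wavelengths = wavelengths)
  validate_cohort_config(cfg)
}

#' Validate a cohort configuration
#' @param cfg a cohort configuration list.
#' @return The validated config, classed `cohort_config`.
#' @export
validate_cohort_config <- function(cfg) {
  if (cfg$n_pairs < 2) .stopf("n_pairs must be >= 2")
  if (cfg$dropout_prob < 0 || cfg$dropout_prob > 1)
    .stopf("dropout_prob must be in [0, 1]")
  if (cfg$noise_sd < 0) .stopf("noise_sd must be >= 0")
  if (cfg$pair_rho < 0 || cfg$pair_rho >= 1)
    .stopf("pair_rho must be in [0, 1)")
  for (g in c("daughter", "mother")) {
    gc <- cfg$groups[[g]]
    if (is.null(gc)) .stopf("missing group config: %s", g)
    sds <- grepl("_sd$", names(gc))
    if (any(unlist(gc[sds]) < 0)) .stopf("group '%s': SDs must be >= 0", g)
    if (gc$weight_age^2 + gc$weight_bmi^2 >= 1)
      .stopf("group '%s': weight_age^2 + weight_bmi^2 must be < 1", g)
  }
  wr <- vapply(c("daughter", "mother"), function(g) {
    gc <- cfg$groups[[g]]
    sqrt(1 - gc$weight_age^2 - gc$weight_bmi^2)
  }, numeric(1))
  if (cfg$pair_rho > prod(wr) + 1e-12)
    .stopf("pair_rho must be <= %.3f given the covariate weights", prod(wr))
  structure(cfg, class = "cohort_config")
}

# residual loading of standardized density after age and BMI
.w_resid <- function(gc) sqrt(1 - gc$weight_age^2 - gc$weight_bmi^2)

# Internal vectorized sampler: n participants of one group with given latent
# residuals (length n). RNG draw order is fixed; all draws are vectorized.
.sample_group <- function(group, cfg, n, latent_r) {
  gc <- cfg$groups[[group]]
  age <- .rtnorm(n, gc$age_mean, gc$age_sd, gc$age_min, gc$age_max)
  a_std <- (age - .tnorm_mean(gc$age_mean, gc$age_sd, gc$age_min, gc$age_max)) /
    gc$age_sd
  bmi <- .rtnorm(n, gc$bmi_mean, gc$bmi_sd, gc$bmi_min, gc$bmi_max)
  b_std <- (bmi - .tnorm_mean(gc$bmi_mean, gc$bmi_sd, gc$bmi_min, gc$bmi_max)) /
    gc$bmi_sd
  t <- gc$bdi_mean + gc$bdi_sd *
    (gc$weight_age * a_std + gc$weight_bmi * b_std + .w_resid(gc) * latent_r)
  t <- pmin(pmax(t, 8), 85)

  thb <- .rtnorm(n, gc$thb_mean, gc$thb_sd, 0.25, 0.98)
  oxyf <- .rtnorm(n, gc$oxyfrac_mean, gc$oxyfrac_sd, 0.30, 0.95)
  lipid0 <- .rtnorm(n, gc$lipid_mean, gc$lipid_sd, 10, 95)
  share0 <- .rtnorm(n, gc$collagen_share_mean, gc$collagen_share_sd, 0.05, 0.95)

  # clamp lipid and the collagen share into the jointly feasible box so the
  # composition realizes %BDI = t exactly while satisfying every bound
  l_lo <- pmax(10, 5.5 * (100 - t) / t)
  l_hi <- pmin(95, 0.98 * (100 - thb) * (100 - t) / 100)
  lipid <- pmin(pmax(lipid0, l_lo), l_hi)
  cw <- lipid * t / (100 - t)
  s_lo <- pmax(1 / cw, 1 - 90 / cw, 0.02)
  s_hi <- pmin(30 / cw, 1 - 4 / cw, 0.95)
  share <- pmin(pmax(share0, s_lo), s_hi)
  # guard the bound arithmetic against floating-point overshoot, preserving
  # collagen + water = cw so the realized %BDI stays exact
  collagen <- pmin(pmax(share * cw, 1), 30)
  water <- pmin(pmax(cw - collagen, 4), 90)

  amp <- .rtnorm(n, gc$amp_mean, gc$amp_sd, 0.3, 3.5)
  pow <- .rtnorm(n, gc$power_mean, gc$power_sd, 0.2, 4.0)

  sdlog <- sqrt(log1p(gc$volume_cv^2))
  vol <- exp(rnorm(n) * sdlog + log(gc$volume_mean) - sdlog^2 / 2)
  vol_left <- vol * exp(rnorm(n, 0, cfg$side_volume_sd))
  vol_right <- vol * exp(rnorm(n, 0, cfg$side_volume_sd))
  cup <- cut(vol, c(-Inf, 350, 550, 850, Inf), labels = c("A", "B", "C", "D"))

  tibble::tibble(group = group, age = age, bmi = bmi,
                 water = water, lipid = lipid, collagen = collagen,
                 oxyhb = oxyf * thb, deoxyhb = (1 - oxyf) * thb,
                 total_hb = thb, amplitude = amp, power = pow,
                 true_pct_density = t,
                 vol_left_cm3 = vol_left, vol_right_cm3 = vol_right,
                 cup_size = as.character(cup))
}

#' Sample one participant's ground truth
#'
#' Draws age, BMI, tissue composition, scattering and breast volumes for one
#' participant of the given group from the configured (truncated) anchor
#' distributions. The composition is constructed so that its percent breast
#' density index equals the participant's latent true percent density
#' exactly, and every composition bound holds for every draw.
#'
#' @param group `"daughter"` or `"mother"`.
#' @param config a [cohort_config()].
#' @return One-row tibble of ground truth.
#' @export
sample_participant <- function(group, config) {
  if (!group %in% c("daughter", "mother")) .stopf("unknown group: %s", group)
  config <- validate_cohort_config(config)
  r <- rnorm(1)
  out <- .sample_group(group, config, 1, r)
  tibble::tibble(participant_id = "X1", pair_id = NA_integer_, out)
}

.generate_cohort_truths <- function(config) {
  n <- config$n_pairs
  rho_r <- config$pair_rho /
    (.w_resid(config$groups$daughter) * .w_resid(config$groups$mother))
  zp <- rnorm(n)
  r_d <- sqrt(rho_r) * zp + sqrt(1 - rho_r) * rnorm(n)
  r_m <- sqrt(rho_r) * zp + sqrt(1 - rho_r) * rnorm(n)
  daughters <- .sample_group("daughter", config, n, r_d)
  mothers <- .sample_group("mother", config, n, r_m)
  dplyr::bind_rows(
    tibble::tibble(participant_id = sprintf("D%03d", seq_len(n)),
                   pair_id = seq_len(n), daughters),
    tibble::tibble(participant_id = sprintf("M%03d", seq_len(n)),
                   pair_id = seq_len(n), mothers))
}

#' Generate a paired mother-daughter cohort of ground truths
#'
#' Mother-daughter dependence is induced by a latent density factor shared
#' within pairs; the configured `pair_rho` is the correlation of true percent
#' density between pair members.
#'
#' @param config a [cohort_config()].
#' @return A tibble with `2 * n_pairs` rows (daughters then mothers), one per
#'   participant, with pair ids, covariates, composition, scattering,
#'   per-side breast volumes and true percent density.
#' @export
generate_paired_cohort <- function(config) {
  config <- validate_cohort_config(config)
  withr::with_seed(config$seed, .generate_cohort_truths(config))
}

.measure_spectra_impl <- function(truth, config, basis) {
  geom <- cup_geometry(truth$cup_size)
  wl <- config$wavelengths
  comp <- tissue_composition(truth$water, truth$lipid, truth$collagen,
                             truth$oxyhb, truth$deoxyhb)
  sc <- scattering_params(truth$amplitude, truth$power)
  rows <- list()
  for (side in c("left", "right")) {
    for (off in geom$offsets_mm) {
      for (pos in seq_len(config$n_positions)) {
        sim <- simulate_spectrum(comp, sc, geom, off, wl, basis)
        noise <- exp(rnorm(length(wl), 0, config$noise_sd))
        usable <- as.integer(runif(length(wl)) >= config$dropout_prob)
        rows[[length(rows) + 1]] <- tibble::tibble(
          participant_id = truth$participant_id, side = side,
          spectrum_id = sprintf("d%02d-p%d", off, pos),
          cup_size = truth$cup_size, offset_mm = off,
          wavelength_nm = wl,
          signal = ifelse(usable == 1, sim$signal * noise, NA_real_),
          usable = usable)
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Simulate the optical measurement session for one participant
#'
#' Generates up to 12 spectra per breast (6 source-detector distances x
#' `n_positions` placements, both breasts), applying multiplicative
#' log-normal noise per wavelength and independent Bernoulli wavelength
#' dropout. Dropped wavelengths have `usable = 0` and `NA` signal.
#'
#' @param truth one-row truth tibble (from [sample_participant()] or
#'   [generate_paired_cohort()]).
#' @param config a [cohort_config()].
#' @param basis a [chromophore_basis()].
#' @return Long-format spectra tibble (see [qc_filter()]).
#' @export
measure_spectra <- function(truth, config, basis = reference_basis()) {
  config <- validate_cohort_config(config)
  if (nrow(truth) != 1) .stopf("truth must be a single participant row")
  .measure_spectra_impl(truth, config, basis)
}

.imaging_group <- function(truths, config) {
  g <- truths$group[1]
  n <- nrow(truths)
  gc <- config$groups[[g]]
  im <- config$imaging[[g]]
  link_pct <- function(lk, lo = 0.5) {
    shared <- rnorm(n, 0, lk$noise_sd * sqrt(lk$noise_share))
    side <- function() rnorm(n, 0, lk$noise_sd * sqrt(1 - lk$noise_share))
    base <- lk$intercept + lk$slope * truths$true_pct_density +
      lk$bmi_slope * (truths$bmi - gc$bmi_mean)
    list(left = pmin(pmax(base + shared + side(), lo), 95),
         right = pmin(pmax(base + shared + side(), lo), 95))
  }
  fgv_pct <- link_pct(im$fgv)
  out <- tibble::tibble(
    participant_id = truths$participant_id,
    fgv_left_cm3 = fgv_pct$left / 100 * truths$vol_left_cm3,
    vol_left_cm3 = truths$vol_left_cm3,
    fgv_right_cm3 = fgv_pct$right / 100 * truths$vol_right_cm3,
    vol_right_cm3 = truths$vol_right_cm3,
    dense_left_cm3 = NA_real_, mammo_vol_left_cm3 = NA_real_,
    dense_right_cm3 = NA_real_, mammo_vol_right_cm3 = NA_real_)
  if (g == "mother") {
    lk <- im$mbd
    sdlog <- sqrt(log1p(lk$volume_cv^2))
    mv <- exp(rnorm(n) * sdlog + log(lk$volume_mean) - sdlog^2 / 2)
    mvl <- mv * exp(rnorm(n, 0, config$side_volume_sd))
    mvr <- mv * exp(rnorm(n, 0, config$side_volume_sd))
    mbd_pct <- link_pct(lk, lo = 0.2)
    out$dense_left_cm3 <- mbd_pct$left / 100 * mvl
    out$mammo_vol_left_cm3 <- mvl
    out$dense_right_cm3 <- mbd_pct$right / 100 * mvr
    out$mammo_vol_right_cm3 <- mvr
  }
  out
}

#' Generate imaging-derived density measures for participants
#'
#' Per-breast DXA fibroglandular volumes (all participants) and mammographic
#' dense volumes (mothers only) are linked to true percent density by
#' configurable affine links with BMI confounding and Gaussian noise split
#' into a shared and a per-side component (left/right correlation >= 0.9 at
#' the defaults). The mammographic percent scale is compressed relative to
#' the DXA scale.
#'
#' @param truths truth tibble rows (single group per call, or mixed: groups
#'   are handled separately in daughter-then-mother order).
#' @param config a [cohort_config()].
#' @return Tibble of per-breast volumes: `fgv_*`, `vol_*` and, for mothers,
#'   `dense_*`, `mammo_vol_*` (NA for daughters).
#' @export
generate_imaging_measures <- function(truths, config) {
  config <- validate_cohort_config(config)
  parts <- split(truths, factor(truths$group, levels = c("daughter", "mother")))
  res <- dplyr::bind_rows(lapply(parts[vapply(parts, nrow, 1L) > 0],
                                 .imaging_group, config = config))
  res[match(truths$participant_id, res$participant_id), ]
}

#' Simulate a complete synthetic cohort
#'
#' Runs the whole generator under one master seed: paired ground truths,
#' optical spectra with noise and dropout, imaging measures, and the
#' covariate table. Bit-reproducible given the config.
#'
#' @param config a [cohort_config()].
#' @param basis a [chromophore_basis()].
#' @param spectra if `FALSE`, skip the (comparatively expensive) spectral
#'   measurement simulation.
#' @return A list with `truth`, `spectra`, `measures` and `covariates`
#'   tibbles.
#' @export
simulate_cohort <- function(config, basis = reference_basis(), spectra = TRUE) {
  config <- validate_cohort_config(config)
  withr::with_seed(config$seed, {
    truth <- .generate_cohort_truths(config)
    spect <- if (spectra) {
      dplyr::bind_rows(lapply(seq_len(nrow(truth)), function(i)
        .measure_spectra_impl(truth[i, ], config, basis)))
    } else NULL
    measures <- generate_imaging_measures(truth, config)
    covariates <- truth[c("participant_id", "pair_id", "group", "age", "bmi")]
    list(truth = truth, spectra = spect, measures = measures,
         covariates = covariates)
  })
}

#' Calibrate the DXA link to a target conditional correlation
#'
#' Adjusts one group's fibroglandular-volume link so that, conditional on age
#' and BMI, the correlation between true percent density and the (side-
#' averaged) percent fibroglandular volume equals `conditional_r`. Used for
#' estimand-recovery and type-I-error studies.
#'
#' @param config a [cohort_config()].
#' @param group `"daughter"` or `"mother"`.
#' @param conditional_r target conditional correlation in [0, 1); 0 sets the
#'   link slope to zero (conditional independence).
#' @return The modified config.
#' @export
calibrate_fgv_link <- function(config, group = "daughter", conditional_r = 0.5) {
  config <- validate_cohort_config(config)
  gc <- config$groups[[group]]
  lk <- config$imaging[[group]]$fgv
  sigma_c <- gc$bdi_sd * .w_resid(gc)   # conditional SD of density given age, BMI
  avg_factor <- sqrt(lk$noise_share + (1 - lk$noise_share) / 2)
  if (conditional_r <= 0) {
    lk$slope <- 0
    lk$intercept <- 31.6
    lk$noise_sd <- 9.9 / avg_factor
  } else {
    lk$slope <- 1
    lk$noise_sd <- sigma_c * sqrt(1 / conditional_r^2 - 1) / avg_factor
    lk$intercept <- 45.2 - lk$slope * gc$bdi_mean
  }
  config$imaging[[group]]$fgv <- lk
  validate_cohort_config(config)
}
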
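# Shared fixtures and independent oracles, built in code at test time.

# An interior ground truth well inside every fit bound.
interior_truth <- function(water = 17.2, lipid = 46.0, collagen = 21.3,
                           total_hb = 0.61, oxy_frac = 0.7,
                           amplitude = 1.7, power = 1.3) {
  list(water = water, lipid = lipid, collagen = collagen,
       total_hb = total_hb, oxyhb = oxy_frac * total_hb,
       deoxyhb = (1 - oxy_frac) * total_hb,
       amplitude = amplitude, power = power)
}

random_interior_truth <- function() {
  thb <- runif(1, 0.3, 0.9)
  f <- runif(1, 0.5, 0.85)
  interior_truth(water = runif(1, 8, 25), lipid = runif(1, 30, 55),
                 collagen = runif(1, 8, 25), total_hb = thb, oxy_frac = f,
                 amplitude = runif(1, 0.8, 2.5), power = runif(1, 0.5, 2.5))
}

# Long-format single spectrum simulated from a truth (optionally noisy).
make_spectrum_tbl <- function(truth, cup = "B", offset = 0, noise = 0,
                              wavelengths = default_wavelengths(),
                              basis = reference_basis(),
                              participant = "p1", side = "left",
                              spectrum_id = "s1") {
  g <- cup_geometry(cup)
  sim <- simulate_spectrum(
    tissue_composition(truth$water, truth$lipid, truth$collagen,
                       truth$oxyhb, truth$deoxyhb),
    scattering_params(truth$amplitude, truth$power),
    g, offset, wavelengths, basis)
  sig <- sim$signal
  if (noise > 0) sig <- sig * exp(rnorm(length(sig), 0, noise))
  tibble::tibble(participant_id = participant, side = side,
                 spectrum_id = spectrum_id, cup_size = cup,
                 offset_mm = offset, wavelength_nm = sim$wavelength_nm,
                 signal = sig, usable = 1L)
}

# A 12-spectrum table with known wavelength availability:
# 3 spectra fail the >= 7 rule, 2 have >= 7 but miss 985, 2 have >= 7 and 985
# but miss both 905 and 940, and 5 pass every rule.
qc_fixture_12 <- function() {
  sets <- list(
    few1    = c(650, 680, 730, 755, 850, 985),
    few2    = c(650, 705, 808, 905, 985),
    few3    = c(650, 680, 705, 730),
    no985_1 = c(650, 680, 730, 755, 850, 905, 940),
    no985_2 = c(650, 680, 705, 730, 755, 780, 940),
    nopk_1  = c(650, 680, 705, 730, 755, 850, 985),
    nopk_2  = c(650, 680, 705, 730, 780, 850, 960, 985),
    pass1   = c(650, 680, 730, 755, 810, 905, 985),
    pass2   = c(650, 680, 705, 730, 755, 780, 940, 985),
    pass3   = default_wavelengths(),
    pass4   = c(650, 705, 780, 850, 905, 940, 985),
    pass5   = c(680, 730, 808, 875, 930, 940, 960, 985)
  )
  rows <- lapply(names(sets), function(id) {
    wl <- sets[[id]]
    tibble::tibble(participant_id = "q1", side = "left", spectrum_id = id,
                   cup_size = "B", offset_mm = 0, wavelength_nm = wl,
                   signal = 1e-8, usable = 1L)
  })
  dplyr::bind_rows(rows)
}

qc_fixture_expected <- function() {
  c(few1 = "too_few_wavelengths", few2 = "too_few_wavelengths",
    few3 = "too_few_wavelengths", no985_1 = "missing_985",
    no985_2 = "missing_985", nopk_1 = "missing_905_940",
    nopk_2 = "missing_905_940")
}

# Independent image-source series oracle for the slab forward model: plain
# scalar sum over explicit source depths, `terms` dipole orders per side.
series_oracle <- function(mu_a, mu_s, d, rho, A = 1, terms = 5000) {
  D <- 1 / (3 * (mu_a + mu_s))
  z0 <- 1 / mu_s
  ze <- 2 * A * D
  mueff <- sqrt(mu_a / D)
  per <- 2 * (d + 2 * ze)
  tot <- 0
  for (m in seq(-terms, terms - 1)) {
    zpos <- z0 + m * per
    zneg <- -z0 - 2 * ze + m * per
    z <- d - zpos
    r <- sqrt(z^2 + rho^2)
    tot <- tot + z * (mueff + 1 / r) * exp(-mueff * r) / r^2
    z <- d - zneg
    r <- sqrt(z^2 + rho^2)
    tot <- tot - z * (mueff + 1 / r) * exp(-mueff * r) / r^2
  }
  tot / (4 * pi)
}

# Independent partial-correlation oracle: precision-matrix (inverse of the
# correlation matrix of [x, y, Z]) formula.
precision_partial_r <- function(x, y, Z) {
  S <- stats::cor(cbind(x, y, Z))
  P <- solve(S)
  -P[1, 2] / sqrt(P[1, 1] * P[2, 2])
}
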
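#' Chromophore names used throughout the package
#'
#' Order is water, lipid, collagen, oxyhemoglobin, deoxyhemoglobin.
#' @export
CHROMOPHORES <- c("water", "lipid", "collagen", "oxyhb", "deoxyhb")

#' Construct a chromophore specific-absorption basis
#'
#' A basis holds, for each chromophore, its specific absorption spectrum in
#' mm^-1 per percent tissue-volume concentration, tabulated on a strictly
#' increasing wavelength grid covering the red/near-infrared measurement band.
#'
#' @param wavelength_nm strictly increasing numeric grid (nm).
#' @param eps numeric matrix, one column per chromophore in the order of
#'   [CHROMOPHORES], all values >= 0, units mm^-1 per percent.
#' @return An object of class `chromophore_basis`.
#' @export
chromophore_basis <- function(wavelength_nm, eps) {
  wavelength_nm <- as.numeric(wavelength_nm)
  eps <- as.matrix(eps)
  if (any(!is.finite(wavelength_nm)) || any(diff(wavelength_nm) <= 0))
    .stopf("basis wavelengths must be finite and strictly increasing")
  if (nrow(eps) != length(wavelength_nm) || ncol(eps) != length(CHROMOPHORES))
    .stopf("eps must be a %d x %d matrix", length(wavelength_nm), length(CHROMOPHORES))
  if (any(!is.finite(eps)) || any(eps < 0))
    .stopf("specific absorption values must be finite and >= 0")
  colnames(eps) <- CHROMOPHORES
  structure(list(wavelength_nm = wavelength_nm, eps = eps),
            class = "chromophore_basis")
}

#' @export
print.chromophore_basis <- function(x, ...) {
  cat(sprintf("<chromophore_basis> %d wavelengths, %.0f-%.0f nm, chromophores: %s\n",
              length(x$wavelength_nm), min(x$wavelength_nm), max(x$wavelength_nm),
              paste(CHROMOPHORES, collapse = ", ")))
  invisible(x)
}

.gauss <- function(wl, center, width) exp(-((wl - center) / width)^2)

# Smooth synthetic stand-ins for the literature specific-absorption curves,
# mm^-1 per percent concentration. Peak locations and magnitudes follow the
# well-known tissue features: water ~975 nm, lipid ~930 nm, collagen ~1035 nm
# with a shoulder near 910 nm, oxyhemoglobin rising over 700-1000 nm,
# deoxyhemoglobin strong at 650 nm with a bump near 760 nm. Hemoglobin curves
# are scaled so that 1% concentration corresponds to ~23 uM heme.
.reference_eps <- function(wl) {
  water <- 2e-6 +
    2.4e-5 * .gauss(wl, 740, 22) +
    3.5e-5 * .gauss(wl, 840, 50) +
    4.3e-4 * .gauss(wl, 978, 32) +
    1.5e-4 * .gauss(wl, 1070, 50)
  lipid <- 1.5e-6 +
    6e-6   * .gauss(wl, 760, 20) +
    1.1e-4 * .gauss(wl, 928, 22) +
    4e-5   * .gauss(wl, 1005, 35) +
    6e-5   * .gauss(wl, 1040, 30)
  collagen <- 2.2e-5 +
    2e-5   * .gauss(wl, 650, 90) +
    5e-5   * .gauss(wl, 910, 60) +
    1.7e-4 * .gauss(wl, 1035, 45)
  # molar extinction shapes (1/cm/M scale) times 2.303 * 23e-6 M / 10 mm
  k <- 2.303 * 23e-6 / 10 * 1000  # per 1000 of the shape value below
  oxy_shape <- 0.28 + 0.9 / (1 + exp(-(wl - 790) / 45)) *
    exp(-pmax(0, wl - 1000)^2 / (2 * 150^2))
  deoxy_shape <- 0.4 + 3.35 * exp(-pmax(0, wl - 650) / 60) +
    0.6 * .gauss(wl, 757, 28)
  cbind(water = water, lipid = lipid, collagen = collagen,
        oxyhb = k * oxy_shape, deoxyhb = k * deoxy_shape)
}

#' Packaged reference chromophore basis
#'
#' Returns the package's default specific-absorption basis over 650-1060 nm.
#' The curves are smooth synthetic approximations to the literature spectra
#' (see the methods vignette); the same basis drives both the synthetic
#' spectrum generator and the inverse fit. A copy is shipped as
#' `inst/extdata/chromophore_basis_synthetic.csv`.
#'
#' @param step grid spacing in nm (default 2).
#' @return A [chromophore_basis()].
#' @export
reference_basis <- function(step = 2) {
  wl <- seq(650, 1060, by = step)
  chromophore_basis(wl, .reference_eps(wl))
}

#' Toy chromophore basis for fast, well-conditioned unit tests
#'
#' Five well-separated Gaussian absorption peaks with the same peak placement
#' conventions as the reference basis (water near 980 nm, lipid near 920 nm).
#'
#' @return A [chromophore_basis()].
#' @export
toy_basis <- function() {
  wl <- seq(650, 1060, by = 5)
  eps <- cbind(
    water    = 1e-6 + 4.0e-4 * .gauss(wl, 980, 25),
    lipid    = 1e-6 + 1.2e-4 * .gauss(wl, 920, 18),
    collagen = 1e-6 + 1.7e-4 * .gauss(wl, 1030, 30) + 3e-5 * .gauss(wl, 680, 40),
    oxyhb    = 1e-6 + 4.0e-3 * .gauss(wl, 800, 120),
    deoxyhb  = 5e-4 + 2.0e-2 * .gauss(wl, 660, 40) + 3e-3 * .gauss(wl, 760, 25)
  )
  chromophore_basis(wl, eps)
}

#' Read a chromophore basis from a CSV file
#'
#' Expected columns: `wavelength_nm`, `eps_water`, `eps_lipid`, `eps_collagen`,
#' `eps_oxyhb`, `eps_deoxyhb`; header required, wavelengths strictly
#' increasing, all specific-absorption values >= 0. Lines starting with `#`
#' are ignored.
#'
#' @param path file path.
#' @return A [chromophore_basis()].
#' @export
load_basis <- function(path) {
  if (!file.exists(path)) .stopf("basis file not found: %s", path)
  df <- read.csv(path, comment.char = "#")
  need <- c("wavelength_nm", paste0("eps_", CHROMOPHORES))
  miss <- setdiff(need, names(df))
  if (length(miss)) .stopf("basis file missing column(s): %s", paste(miss, collapse = ", "))
  chromophore_basis(df$wavelength_nm, as.matrix(df[paste0("eps_", CHROMOPHORES)]))
}

# Internal: interpolate the basis at given wavelengths -> n x 5 matrix.
.basis_eps_at <- function(basis, wavelength_nm) {
  rng <- range(basis$wavelength_nm)
  if (any(wavelength_nm < rng[1] - 1e-9) || any(wavelength_nm > rng[2] + 1e-9))
    .stopf("wavelength outside basis range [%g, %g] nm", rng[1], rng[2])
  out <- vapply(CHROMOPHORES, function(ch)
    approx(basis$wavelength_nm, basis$eps[, ch], xout = wavelength_nm,
           rule = 1)$y,
    numeric(length(wavelength_nm)))
  matrix(out, nrow = length(wavelength_nm),
         dimnames = list(NULL, CHROMOPHORES))
}

#' Tissue composition (five chromophores, percent of tissue volume)
#'
#' @param water,lipid,collagen,oxyhb,deoxyhb concentrations in percent of
#'   tissue volume; each >= 0 and their sum must be < 100 (the remainder is
#'   unmodeled chromophores such as myoglobin).
#' @return A named numeric vector of class `tissue_composition`.
#' @export
tissue_composition <- function(water, lipid, collagen, oxyhb, deoxyhb) {
  x <- c(water = water, lipid = lipid, collagen = collagen,
         oxyhb = oxyhb, deoxyhb = deoxyhb)
  if (any(!is.finite(x)) || any(x < 0))
    .stopf("all concentrations must be finite and >= 0")
  if (sum(x) >= 100)
    .stopf("chromophore concentrations must sum to < 100%% (got %.2f)", sum(x))
  structure(x, class = "tissue_composition")
}

#' Scattering power-law parameters
#'
#' @param amplitude reduced scattering coefficient (mm^-1) at the reference
#'   wavelength; > 0.
#' @param power dimensionless scattering power; > 0.
#' @return A named numeric vector of class `scattering_params`.
#' @export
scattering_params <- function(amplitude, power) {
  if (!is.finite(amplitude) || amplitude <= 0) .stopf("amplitude must be > 0")
  if (!is.finite(power) || power <= 0) .stopf("power must be > 0")
  structure(c(amplitude = amplitude, power = power), class = "scattering_params")
}

#' Tissue absorption coefficient from a chromophore mixture
#'
#' Linear (Beer-Lambert) mixing of the specific-absorption curves:
#' mu_a(lambda) = sum_i c_i * eps_i(lambda).
#'
#' @param composition a [tissue_composition()] (or named vector with the five
#'   chromophore concentrations in percent).
#' @param basis a [chromophore_basis()].
#' @param wavelength wavelengths in nm, within the basis grid range.
#' @return mu_a in mm^-1, one value per wavelength.
#' @export
absorption_coefficient <- function(composition, basis, wavelength) {
  conc <- unclass(composition)[CHROMOPHORES]
  if (any(is.na(conc))) .stopf("composition must contain: %s", paste(CHROMOPHORES, collapse = ", "))
  eps <- .basis_eps_at(basis, wavelength)
  as.vector(eps %*% conc)
}

#' Reduced scattering coefficient from the power law
#'
#' mu_s'(lambda) = amplitude * (lambda / reference_wavelength)^(-power).
#'
#' @param params a [scattering_params()] (or named vector with `amplitude`
#'   and `power`).
#' @param wavelength wavelengths in nm (> 0).
#' @param reference_wavelength reference wavelength in nm (default 800).
#' @return mu_s' in mm^-1, one value per wavelength.
#' @export
reduced_scattering <- function(params, wavelength, reference_wavelength = 800) {
  p <- unclass(params)
  if (any(wavelength <= 0) || reference_wavelength <= 0)
    .stopf("wavelengths must be > 0")
  p[["amplitude"]] * (wavelength / reference_wavelength)^(-p[["power"]])
}
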
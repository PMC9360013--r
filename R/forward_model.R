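#' Slab measurement geometry
#'
#' The breast held in the measurement cup is modeled as a homogeneous slab of
#' the cup-dependent thickness; light enters on one face and six detector
#' positions on the opposite face collect transmitted light at fixed lateral
#' source-detector offsets.
#'
#' @param thickness_mm slab thickness in mm (> 0).
#' @param offsets_mm exactly six distinct lateral source-detector offsets in
#'   mm, each >= 0 (default 0, 10, ..., 50).
#' @param cup_size optional cup label.
#' @return An object of class `slab_geometry`.
#' @export
slab_geometry <- function(thickness_mm, offsets_mm = seq(0, 50, by = 10),
                          cup_size = NA_character_) {
  if (!is.finite(thickness_mm) || thickness_mm <= 0)
    .stopf("slab thickness must be > 0")
  offsets_mm <- as.numeric(offsets_mm)
  if (length(offsets_mm) != 6 || anyDuplicated(offsets_mm) || any(offsets_mm < 0))
    .stopf("geometry requires exactly 6 distinct offsets >= 0")
  structure(list(thickness_mm = thickness_mm, offsets_mm = offsets_mm,
                 cup_size = cup_size),
            class = "slab_geometry")
}

#' Cup-size geometry defaults
#'
#' Maps the four cup labels to default slab thicknesses (A/B/C/D ->
#' 45/55/65/75 mm) with the standard six offsets.
#'
#' @param cup_size one of "A", "B", "C", "D".
#' @return A [slab_geometry()].
#' @export
cup_geometry <- function(cup_size) {
  thick <- c(A = 45, B = 55, C = 65, D = 75)[[as.character(cup_size)]]
  if (is.null(thick) || is.na(thick)) .stopf("unknown cup size: %s", cup_size)
  slab_geometry(thick, cup_size = as.character(cup_size))
}

#' Continuous-wave transmittance of a diffusive slab
#'
#' Steady-state diffusion approximation for a homogeneous slab with
#' extrapolated boundaries: the isotropic source at depth `z0 = 1/mu_s'` is
#' mirrored in the two extrapolated boundaries (at `-z_e` and `d + z_e`,
#' `z_e = 2AD`), and the transmitted photon flux across the exit face at
#' lateral offset `rho` is the signed sum over the resulting image-source
#' dipole chain. The series converges exponentially; `n_image_pairs` orders
#' are summed on each side.
#'
#' @param mu_a absorption coefficient(s), mm^-1, >= 0 (vectorized).
#' @param mu_s_prime reduced scattering coefficient(s), mm^-1, > 0
#'   (vectorized, recycled against `mu_a`).
#' @param geometry a [slab_geometry()].
#' @param offset_mm lateral source-detector offset; must be one of the
#'   geometry's offsets.
#' @param n_image_pairs image-source orders summed on each side of the slab.
#' @param boundary_A internal-reflection parameter of the extrapolated
#'   boundary condition (1 = refractive-index matched).
#' @return Dimensionless detected signal(s), > 0; strictly decreasing in
#'   `mu_a`, in slab thickness and in offset.
#' @export
slab_transmittance <- function(mu_a, mu_s_prime, geometry, offset_mm,
                               n_image_pairs = 25, boundary_A = 1) {
  if (any(!is.finite(mu_a)) || any(mu_a < 0)) .stopf("mu_a must be >= 0")
  if (any(!is.finite(mu_s_prime)) || any(mu_s_prime <= 0))
    .stopf("diffusion approximation requires mu_s' > 0")
  if (!inherits(geometry, "slab_geometry")) .stopf("geometry must be a slab_geometry")
  if (!any(abs(geometry$offsets_mm - offset_mm) < 1e-9))
    .stopf("offset %g mm is not one of the geometry offsets", offset_mm)
  n <- max(length(mu_a), length(mu_s_prime))
  mu_a <- rep_len(mu_a, n)
  mu_s_prime <- rep_len(mu_s_prime, n)

  d <- geometry$thickness_mm
  D <- 1 / (3 * (mu_a + mu_s_prime))
  z0 <- 1 / mu_s_prime
  ze <- 2 * boundary_A * D
  mueff <- sqrt(mu_a / D)
  period <- 2 * (d + 2 * ze)

  m <- seq.int(-n_image_pairs, n_image_pairs)
  # n x m matrices of signed image depths relative to the exit face
  shift <- outer(period, m)                  # n x m
  z3 <- (d - z0) - shift                     # positive sources
  z4 <- (d + z0 + 2 * ze) - shift            # negative (image) sources
  flux_term <- function(z) {
    r <- sqrt(z^2 + offset_mm^2)
    z * (mueff + 1 / r) * exp(-mueff * r) / r^2
  }
  rowSums(flux_term(z3) - flux_term(z4)) / (4 * pi)
}

#' Default 16-wavelength measurement grid
#'
#' Sixteen wavelengths spanning 650-1060 nm, including the diagnostic
#' 905, 940 and 985 nm bands used by the spectrum quality-control rules.
#'
#' @return Numeric vector of wavelengths (nm).
#' @export
default_wavelengths <- function() {
  c(650, 680, 705, 730, 755, 780, 808, 830, 850, 875,
    905, 930, 940, 960, 985, 1060)
}

#' Simulate a transmission spectrum for a given tissue state
#'
#' Evaluates the slab forward model wavelength by wavelength: absorption from
#' the chromophore mixture, scattering from the power law, then diffuse
#' transmittance at the requested source-detector offset. Deterministic given
#' its inputs.
#'
#' @param composition a [tissue_composition()].
#' @param scattering a [scattering_params()].
#' @param geometry a [slab_geometry()].
#' @param offset_mm lateral offset, one of the geometry's offsets.
#' @param wavelengths wavelengths in nm, all within 650-1060.
#' @param basis a [chromophore_basis()] (default [reference_basis()]).
#' @param reference_wavelength scattering reference wavelength (nm).
#' @param n_image_pairs see [slab_transmittance()].
#' @return A tibble with columns `wavelength_nm` and `signal`.
#' @export
simulate_spectrum <- function(composition, scattering, geometry, offset_mm,
                              wavelengths, basis = reference_basis(),
                              reference_wavelength = 800, n_image_pairs = 25) {
  if (length(wavelengths) == 0) .stopf("at least one wavelength is required")
  if (any(wavelengths < 650 - 1e-9) || any(wavelengths > 1060 + 1e-9))
    .stopf("wavelengths must lie within 650-1060 nm")
  mu_a <- absorption_coefficient(composition, basis, wavelengths)
  mu_s <- reduced_scattering(scattering, wavelengths, reference_wavelength)
  sig <- slab_transmittance(mu_a, mu_s, geometry, offset_mm, n_image_pairs)
  tibble::tibble(wavelength_nm = as.numeric(wavelengths), signal = sig)
}
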
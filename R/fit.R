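#' Fit bounds for the seven chromophore and scattering parameters
#'
#' Defaults are the physiologically motivated constraints used throughout:
#' water 4-90%, lipid 10-95%, collagen 1-30%, total hemoglobin (oxy + deoxy)
#' 0.2-1%, scattering amplitude 0.1-4 mm^-1, scattering power 0.05-5, and a
#' joint cap of 100% on the sum of all chromophore concentrations.
#'
#' @param water,lipid,collagen,total_hb,amplitude,power length-2 numeric
#'   `c(lower, upper)` bounds.
#' @param sum_cap upper cap on water + lipid + collagen + total hemoglobin.
#' @return An object of class `fit_bounds`.
#' @export
fit_bounds <- function(water = c(4, 90), lipid = c(10, 95),
                       collagen = c(1, 30), total_hb = c(0.2, 1),
                       amplitude = c(0.1, 4), power = c(0.05, 5),
                       sum_cap = 100) {
  b <- list(water = water, lipid = lipid, collagen = collagen,
            total_hb = total_hb, amplitude = amplitude, power = power)
  for (nm in names(b)) {
    v <- as.numeric(b[[nm]])
    if (length(v) != 2 || !all(is.finite(v)) || v[1] >= v[2])
      .stopf("bound '%s' must be c(lower, upper) with lower < upper", nm)
    b[[nm]] <- v
  }
  if (!is.finite(sum_cap) || sum_cap <= 0) .stopf("sum_cap must be > 0")
  structure(c(b, list(sum_cap = sum_cap)), class = "fit_bounds")
}

# Internal parameter vector layout used by the optimizer:
# water, lipid, collagen, total_hb, oxy_frac, amplitude, power
.par_names <- c("water", "lipid", "collagen", "total_hb", "oxy_frac",
                "amplitude", "power")

.par_box <- function(bounds) {
  lo <- c(bounds$water[1], bounds$lipid[1], bounds$collagen[1],
          bounds$total_hb[1], 0, bounds$amplitude[1], bounds$power[1])
  hi <- c(bounds$water[2], bounds$lipid[2], bounds$collagen[2],
          bounds$total_hb[2], 1, bounds$amplitude[2], bounds$power[2])
  names(lo) <- names(hi) <- .par_names
  list(lo = lo, hi = hi)
}

# Internal: spectrum-level usability mask and QC verdict.
.qc_one <- function(wavelength_nm, signal, usable) {
  ok <- usable != 0 & is.finite(signal) & signal > 0
  wl <- wavelength_nm[ok]
  has <- function(x) any(abs(wl - x) <= 0.5)
  if (length(wl) < 7) return("too_few_wavelengths")
  if (!has(985)) return("missing_985")
  if (!has(905) && !has(940)) return("missing_905_940")
  NA_character_
}

#' Spectrum usability filter
#'
#' A spectrum is retained iff it has usable data at >= 7 wavelengths
#' (matching the 7 unknown parameters), usable data at 985 nm, and usable
#' data at 905 nm or 940 nm (separating the primary lipid and water
#' absorption peaks). A wavelength is usable when its flag is set and its
#' signal is finite and positive. The filter is a pure function of the set of
#' spectra: input order never changes the verdicts.
#'
#' @param spectra long-format tibble with columns `participant_id`, `side`,
#'   `spectrum_id`, `wavelength_nm`, `signal`, `usable` (plus any others,
#'   e.g. `cup_size`, `offset_mm`, carried through).
#' @return A list with `retained` (rows of retained spectra, input order) and
#'   `exclusions` (one row per excluded spectrum with a machine-readable
#'   `reason`: `too_few_wavelengths`, `missing_985` or `missing_905_940`).
#' @export
qc_filter <- function(spectra) {
  key_cols <- c("participant_id", "side", "spectrum_id")
  need <- c(key_cols, "wavelength_nm", "signal", "usable")
  miss <- setdiff(need, names(spectra))
  if (length(miss)) .stopf("spectra table missing column(s): %s",
                           paste(miss, collapse = ", "))
  if (nrow(spectra) == 0) {
    return(list(retained = spectra,
                exclusions = tibble::tibble(participant_id = character(),
                                            side = character(),
                                            spectrum_id = character(),
                                            reason = character())))
  }
  verdicts <- spectra |>
    dplyr::group_by(dplyr::across(dplyr::all_of(key_cols))) |>
    dplyr::summarise(reason = .qc_one(.data$wavelength_nm, .data$signal,
                                      .data$usable),
                     .groups = "drop")
  excl <- verdicts |> dplyr::filter(!is.na(.data$reason))
  keep <- verdicts |> dplyr::filter(is.na(.data$reason)) |>
    dplyr::select(dplyr::all_of(key_cols))
  list(retained = dplyr::semi_join(spectra, keep, by = key_cols),
       exclusions = excl)
}

#' Fit one spectrum by constrained multi-start least squares
#'
#' Minimizes the sum over usable wavelengths of squared differences between
#' the measured and simulated signals (log scale by default, since signals
#' span decades) over the 7 parameters, subject to the box bounds, the joint
#' total-hemoglobin bound on oxy + deoxy, and the < 100% cap on the chromophore
#' sum. Starting points are a Latin-hypercube sample over the bounds with a
#' fixed seed; each start is polished by bound-constrained Levenberg-Marquardt.
#'
#' @param spectrum long-format tibble rows of a single spectrum (columns
#'   `wavelength_nm`, `signal`, `usable`, plus `offset_mm` and `cup_size`
#'   unless `geometry`/`offset_mm` are given explicitly).
#' @param basis a [chromophore_basis()].
#' @param bounds a [fit_bounds()].
#' @param geometry a [slab_geometry()]; default derived from the spectrum's
#'   `cup_size` via [cup_geometry()].
#' @param offset_mm lateral offset; default the spectrum's `offset_mm`.
#' @param n_starts number of starting points (>= 1).
#' @param seed integer seed for the start sample (local; does not touch the
#'   global RNG stream).
#' @param residual_scale `"log"` (default) or `"linear"`.
#' @param fixed optional named list of parameters (from
#'   `water, lipid, collagen, total_hb, oxy_frac, amplitude, power`) held
#'   fixed at the given values.
#' @param reference_wavelength scattering reference wavelength (nm).
#' @param n_image_pairs see [slab_transmittance()].
#' @param control passed to [minpack.lm::nls.lm.control()].
#' @return A tibble of class `fit_results`, one row per start, sorted by
#'   `sse` (ties: fewer `n_at_bounds`, then lower `start_index`), with the
#'   five chromophore concentrations, scattering parameters, `sse`,
#'   `n_at_bounds` (parameters within 1e-6 of a bound in normalized
#'   coordinates) and `converged`.
#' @export
fit_spectrum <- function(spectrum, basis = reference_basis(),
                         bounds = fit_bounds(), geometry = NULL,
                         offset_mm = NULL, n_starts = 8, seed = 1L,
                         residual_scale = c("log", "linear"), fixed = NULL,
                         reference_wavelength = 800, n_image_pairs = 25,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ftol = 1e-13, ptol = 1e-13)) {
  residual_scale <- match.arg(residual_scale)
  if (n_starts < 1) .stopf("n_starts must be >= 1")
  reason <- .qc_one(spectrum$wavelength_nm, spectrum$signal, spectrum$usable)
  if (!is.na(reason))
    .stopf("spectrum fails the usability filter (%s); run qc_filter() first", reason)
  if (is.null(offset_mm)) offset_mm <- unique(spectrum$offset_mm)
  if (length(offset_mm) != 1 || !is.finite(offset_mm))
    .stopf("spectrum must have a single finite offset_mm")
  if (is.null(geometry)) {
    cup <- unique(spectrum$cup_size)
    if (length(cup) != 1) .stopf("spectrum must have a single cup_size")
    geometry <- cup_geometry(cup)
  }

  ok <- spectrum$usable != 0 & is.finite(spectrum$signal) & spectrum$signal > 0
  wl <- spectrum$wavelength_nm[ok]
  y <- spectrum$signal[ok]
  eps <- .basis_eps_at(basis, wl)
  wl_ratio_log <- log(wl / reference_wavelength)
  target <- if (residual_scale == "log") log(y) else y

  box <- .par_box(bounds)
  lo <- box$lo; hi <- box$hi; span <- hi - lo
  if (!is.null(fixed)) {
    bad <- setdiff(names(fixed), .par_names)
    if (length(bad)) .stopf("unknown fixed parameter(s): %s", paste(bad, collapse = ", "))
  }
  free <- setdiff(.par_names, names(fixed))
  u_fixed <- rep(NA_real_, 7); names(u_fixed) <- .par_names
  for (nm in names(fixed)) u_fixed[nm] <- (fixed[[nm]] - lo[nm]) / span[nm]

  full_u <- function(u_free) {
    u <- u_fixed
    u[free] <- u_free
    u
  }
  theta_of <- function(u) lo + u * span
  sim_signal <- function(th) {
    conc <- c(th["water"], th["lipid"], th["collagen"],
              th["oxy_frac"] * th["total_hb"],
              (1 - th["oxy_frac"]) * th["total_hb"])
    mu_a <- as.vector(eps %*% conc)
    mu_s <- th[["amplitude"]] * exp(-th[["power"]] * wl_ratio_log)
    slab_transmittance(mu_a, mu_s, geometry, offset_mm, n_image_pairs)
  }
  resid_fn <- function(u_free) {
    th <- theta_of(full_u(u_free))
    sim <- sim_signal(th)
    r <- if (residual_scale == "log") target - log(sim) else target - sim
    csum <- th[["water"]] + th[["lipid"]] + th[["collagen"]] + th[["total_hb"]]
    c(r, 1e3 * max(0, csum - bounds$sum_cap))
  }

  starts <- withr::with_seed(seed, lhs::randomLHS(n_starts, length(free)))
  rows <- vector("list", n_starts)
  for (i in seq_len(n_starts)) {
    res <- minpack.lm::nls.lm(par = starts[i, ], lower = rep(0, length(free)),
                              upper = rep(1, length(free)), fn = resid_fn,
                              control = control)
    u <- full_u(res$par)
    th <- theta_of(u)
    r <- target - (if (residual_scale == "log") log(sim_signal(th)) else sim_signal(th))
    csum <- th[["water"]] + th[["lipid"]] + th[["collagen"]] + th[["total_hb"]]
    feasible <- csum <= bounds$sum_cap + 1e-9
    rows[[i]] <- tibble::tibble(
      start_index = i,
      water = th[["water"]], lipid = th[["lipid"]], collagen = th[["collagen"]],
      oxyhb = th[["oxy_frac"]] * th[["total_hb"]],
      deoxyhb = (1 - th[["oxy_frac"]]) * th[["total_hb"]],
      total_hb = th[["total_hb"]],
      amplitude = th[["amplitude"]], power = th[["power"]],
      sse = sum(r^2),
      n_at_bounds = sum(u < 1e-6 | u > 1 - 1e-6),
      converged = res$info %in% 1:4 && feasible
    )
  }
  out <- dplyr::bind_rows(rows)
  out <- out[order(out$sse, out$n_at_bounds, out$start_index), ]
  class(out) <- c("fit_results", class(out))
  out
}

#' Select the best fit among multi-start candidates
#'
#' Returns the candidate with the smallest least-squares objective among
#' converged candidates with no more than 2 parameters at their bounds.
#' Ties are broken by fewer parameters at bounds, then lower start index.
#' If no candidate qualifies, an explicit fit-failure marker is returned and
#' the spectrum contributes nothing downstream.
#'
#' @param candidates a [fit_spectrum()] result (non-empty).
#' @param max_at_bounds maximum allowed parameters at bounds (default 2).
#' @return A one-row tibble, or a `fit_failure` object (see
#'   [is_fit_failure()]).
#' @export
select_best_fit <- function(candidates, max_at_bounds = 2) {
  if (is.null(candidates) || nrow(candidates) == 0)
    .stopf("candidate list must be non-empty")
  ok <- candidates$converged & candidates$n_at_bounds <= max_at_bounds
  if (!any(ok)) return(structure(list(), class = "fit_failure"))
  qual <- candidates[ok, ]
  qual <- qual[order(qual$sse, qual$n_at_bounds, qual$start_index), ]
  tibble::as_tibble(qual[1, ])
}

#' Test for the fit-failure marker
#' @param x object returned by [select_best_fit()].
#' @return `TRUE` if `x` marks a failed fit.
#' @export
is_fit_failure <- function(x) inherits(x, "fit_failure")

#' Average accepted fits into one participant composition
#'
#' Unweighted arithmetic mean of every fitted parameter across all accepted
#' spectra from both breasts (each usable spectrum counts equally).
#'
#' @param fits tibble of accepted best fits with a `side` column and the
#'   fitted parameter columns; at least one row.
#' @return One-row tibble with mean composition, mean scattering,
#'   `n_spectra_used` and per-side counts.
#' @export
aggregate_participant <- function(fits) {
  if (is.null(fits) || nrow(fits) == 0)
    .stopf("at least one accepted fit is required")
  cols <- c("water", "lipid", "collagen", "oxyhb", "deoxyhb", "total_hb",
            "amplitude", "power")
  out <- as.list(colMeans(fits[cols]))
  tibble::tibble(!!!out,
                 n_spectra_used = nrow(fits),
                 n_left = sum(fits$side == "left"),
                 n_right = sum(fits$side == "right"))
}

#' Run the full spectral pipeline on a long-format spectra table
#'
#' Applies the usability filter, fits every retained spectrum by constrained
#' multi-start least squares, selects each spectrum's best fit (discarding
#' fits with more than 2 parameters at bounds), and averages accepted fits
#' within participant. Per-spectrum start seeds are derived from the master
#' seed and the spectrum key, so results are deterministic and independent of
#' row order.
#'
#' @param spectra long-format spectra tibble (see [qc_filter()]; also needs
#'   `cup_size` and `offset_mm`).
#' @param basis,bounds,n_starts,residual_scale,reference_wavelength,control
#'   passed to [fit_spectrum()].
#' @param seed master integer seed.
#' @return A list with `compositions` (one row per participant with >= 1
#'   accepted fit), `exclusions` (QC log), `fit_log` (per retained spectrum:
#'   key, accepted flag, sse, n_at_bounds) and `participants_excluded`
#'   (participants with no usable spectra).
#' @export
run_spectral_pipeline <- function(spectra, basis = reference_basis(),
                                  bounds = fit_bounds(), n_starts = 8,
                                  seed = 1L, residual_scale = "log",
                                  reference_wavelength = 800,
                                  control = minpack.lm::nls.lm.control(
                                    maxiter = 200, ftol = 1e-13, ptol = 1e-13)) {
  qc <- qc_filter(spectra)
  key_cols <- c("participant_id", "side", "spectrum_id")
  retained <- qc$retained
  keys <- unique(retained[key_cols])
  keys <- keys[order(keys$participant_id, keys$side, keys$spectrum_id), ]
  accepted <- list()
  log_rows <- list()
  for (i in seq_len(nrow(keys))) {
    k <- keys[i, ]
    sp <- dplyr::semi_join(retained, k, by = key_cols)
    spec_seed <- as.integer(
      (as.numeric(seed) +
         .string_hash(c(k$participant_id, k$side, k$spectrum_id))) %%
        2147483647)
    fits <- fit_spectrum(sp, basis = basis, bounds = bounds,
                         n_starts = n_starts, seed = spec_seed,
                         residual_scale = residual_scale,
                         reference_wavelength = reference_wavelength,
                         control = control)
    best <- select_best_fit(fits)
    if (is_fit_failure(best)) {
      log_rows[[i]] <- dplyr::bind_cols(
        k, tibble::tibble(accepted = FALSE, sse = NA_real_,
                          n_at_bounds = NA_integer_))
    } else {
      log_rows[[i]] <- dplyr::bind_cols(
        k, tibble::tibble(accepted = TRUE, sse = best$sse,
                          n_at_bounds = best$n_at_bounds))
      accepted[[length(accepted) + 1]] <- dplyr::bind_cols(k, best)
    }
  }
  fit_log <- dplyr::bind_rows(log_rows)
  accepted <- dplyr::bind_rows(accepted)
  all_ids <- unique(spectra$participant_id)
  if (nrow(accepted) > 0) {
    compositions <- accepted |>
      dplyr::group_by(.data$participant_id) |>
      dplyr::group_modify(~ aggregate_participant(.x)) |>
      dplyr::ungroup()
  } else {
    compositions <- tibble::tibble(participant_id = character())
  }
  no_data <- setdiff(all_ids, compositions$participant_id)
  list(compositions = compositions,
       exclusions = qc$exclusions,
       fit_log = fit_log,
       participants_excluded = tibble::tibble(
         participant_id = no_data,
         reason = rep("no_usable_spectra", length(no_data))))
}
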
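#' Percent breast density index from optical composition
#'
#' %BDI = (collagen + water) / (collagen + water + lipid) * 100, computed
#' from the participant-averaged chromophore concentrations. Invariant to
#' rescaling all three inputs by a common factor and strictly decreasing in
#' lipid.
#'
#' @param water,collagen,lipid concentrations in percent (each >= 0;
#'   vectorized).
#' @return %BDI in \[0, 100\].
#' @export
percent_bdi <- function(water, collagen, lipid) {
  if (any(c(water, collagen, lipid) < 0, na.rm = TRUE))
    .stopf("concentrations must be >= 0")
  denom <- collagen + water + lipid
  if (any(denom <= 0, na.rm = TRUE))
    .stopf("collagen + water + lipid must be > 0")
  (collagen + water) / denom * 100
}

#' Optical index from composition and scattering power
#'
#' log((collagen + water) * power) / lipid with natural log and
#' concentrations in percent units (the log base is configurable).
#'
#' @param water,collagen,lipid concentrations in percent.
#' @param power scattering power (dimensionless).
#' @param base log base (default `exp(1)`).
#' @return Dimensionless optical index (vectorized).
#' @export
optical_index <- function(water, collagen, lipid, power, base = exp(1)) {
  arg <- (collagen + water) * power
  if (any(arg <= 0, na.rm = TRUE))
    .stopf("(collagen + water) * power must be > 0")
  if (any(lipid <= 0, na.rm = TRUE)) .stopf("lipid must be > 0")
  log(arg, base = base) / lipid
}

#' Sum of percent collagen and percent water
#'
#' The absolute-scale optical measure compared against absolute
#' fibroglandular and dense volumes.
#'
#' @param collagen,water concentrations in percent (>= 0).
#' @return %collagen-water (vectorized).
#' @export
percent_collagen_water <- function(collagen, water) {
  if (any(c(collagen, water) < 0, na.rm = TRUE))
    .stopf("concentrations must be >= 0")
  collagen + water
}

# shared side-then-average percent/absolute computation for DXA and mammography
.percent_volumetric <- function(num_left, vol_left, num_right, vol_right, what) {
  sides <- list(left = c(num_left, vol_left), right = c(num_right, vol_right))
  pct <- abs_ <- c()
  for (s in names(sides)) {
    v <- sides[[s]]
    if (any(is.na(v))) next
    if (v[2] <= 0) .stopf("%s: total volume must be > 0 (%s side)", what, s)
    if (v[1] < 0 || v[1] > v[2])
      .stopf("%s: per-side volume must lie in [0, total volume] (%s side)", what, s)
    pct <- c(pct, v[1] / v[2] * 100)
    abs_ <- c(abs_, v[1])
  }
  if (length(pct) == 0)
    return(tibble::tibble(percent = NA_real_, absolute_cm3 = NA_real_,
                          n_sides = 0L))
  tibble::tibble(percent = mean(pct), absolute_cm3 = mean(abs_),
                 n_sides = length(pct))
}

#' Percent and absolute fibroglandular volume from DXA
#'
#' The per-side percent (FGV / total volume * 100) is computed first, then
#' the unweighted mean over both breasts; the absolute measure is the mean of
#' the per-side fibroglandular volumes. A missing side (`NA`s) is permitted:
#' the other side's values are returned with `n_sides = 1`.
#'
#' @param fgv_left,vol_left,fgv_right,vol_right per-side fibroglandular and
#'   total breast volumes (cm^3); `0 <= fgv <= vol`, `vol > 0`.
#' @return One-row tibble: `percent`, `absolute_cm3`, `n_sides`.
#' @export
percent_fgv <- function(fgv_left, vol_left, fgv_right, vol_right) {
  .percent_volumetric(fgv_left, vol_left, fgv_right, vol_right, "FGV")
}

#' Percent and absolute mammographic breast density
#'
#' Dense volume relative to total breast volume times 100, averaged over both
#' breasts, as [percent_fgv()].
#'
#' @param dense_left,vol_left,dense_right,vol_right per-side dense and total
#'   breast volumes (cm^3).
#' @return One-row tibble: `percent`, `absolute_cm3`, `n_sides`.
#' @export
percent_mbd <- function(dense_left, vol_left, dense_right, vol_right) {
  .percent_volumetric(dense_left, vol_left, dense_right, vol_right, "MBD")
}

#' Compute all per-participant density measures
#'
#' Joins fitted (or true) compositions with per-breast imaging volumes and
#' derives the full measure set: %BDI, optical index, %collagen-water, %FGV,
#' AFGV and (where mammography exists) %MBD, AMBD. Indices are computed from
#' the participant-averaged composition.
#'
#' @param compositions tibble with `participant_id`, `water`, `lipid`,
#'   `collagen`, `total_hb`, `amplitude`, `power` (e.g. from
#'   [run_spectral_pipeline()]'s `compositions`).
#' @param measures tibble of per-breast volumes as produced by
#'   [generate_imaging_measures()] (optional; omit for OS-only measures).
#' @return Tibble with one row per participant present in `compositions`.
#' @export
compute_density_measures <- function(compositions, measures = NULL) {
  out <- tibble::tibble(
    participant_id = compositions$participant_id,
    pct_bdi = percent_bdi(compositions$water, compositions$collagen,
                          compositions$lipid),
    optical_index = optical_index(compositions$water, compositions$collagen,
                                  compositions$lipid, compositions$power),
    pct_collagen_water = percent_collagen_water(compositions$collagen,
                                                compositions$water),
    water = compositions$water, lipid = compositions$lipid,
    collagen = compositions$collagen, total_hb = compositions$total_hb,
    amplitude = compositions$amplitude, power = compositions$power,
    pct_fgv = NA_real_, afgv_cm3 = NA_real_,
    pct_mbd = NA_real_, ambd_cm3 = NA_real_)
  if (!is.null(measures)) {
    m <- measures[match(out$participant_id, measures$participant_id), ]
    for (i in seq_len(nrow(out))) {
      fg <- percent_fgv(m$fgv_left_cm3[i], m$vol_left_cm3[i],
                        m$fgv_right_cm3[i], m$vol_right_cm3[i])
      out$pct_fgv[i] <- fg$percent
      out$afgv_cm3[i] <- fg$absolute_cm3
      mb <- percent_mbd(m$dense_left_cm3[i], m$mammo_vol_left_cm3[i],
                        m$dense_right_cm3[i], m$mammo_vol_right_cm3[i])
      out$pct_mbd[i] <- mb$percent
      out$ambd_cm3[i] <- mb$absolute_cm3
    }
  }
  out
}
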
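.read_csv_checked <- function(path, required, numeric_cols, what) {
  if (!file.exists(path)) .stopf("%s file not found: %s", what, path)
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss)) .stopf("%s table missing column(s): %s", what,
                           paste(miss, collapse = ", "))
  for (col in intersect(numeric_cols, names(df))) {
    v <- df[[col]]
    if (is.character(v)) {
      suppress <- suppressWarnings(as.numeric(v))
      bad <- which(!is.na(v) & v != "" & is.na(suppress))
      if (length(bad)) .stopf("%s table: non-numeric value '%s' in column '%s' (row %d)",
                              what, v[bad[1]], col, bad[1])
      df[[col]] <- suppress
    }
  }
  tibble::as_tibble(df)
}

#' Read and validate a long-format spectra table
#'
#' Required columns: `participant_id`, `side`, `spectrum_id`, `cup_size`,
#' `offset_mm`, `wavelength_nm`, `signal`, `usable`. Wavelengths must lie
#' within 650-1060 nm and the (participant, side, spectrum, wavelength) key
#' must be unique; violations are reported with their row number / key.
#' Lines starting with `#` are ignored.
#'
#' @param path CSV file path.
#' @return A validated tibble.
#' @export
read_spectra_table <- function(path) {
  df <- .read_csv_checked(
    path,
    required = c("participant_id", "side", "spectrum_id", "cup_size",
                 "offset_mm", "wavelength_nm", "signal", "usable"),
    numeric_cols = c("offset_mm", "wavelength_nm", "signal", "usable"),
    what = "spectra")
  bad_wl <- which(!is.na(df$wavelength_nm) &
                    (df$wavelength_nm < 650 | df$wavelength_nm > 1060))
  if (length(bad_wl))
    .stopf("spectra table: wavelength %g nm outside 650-1060 nm (row %d)",
           df$wavelength_nm[bad_wl[1]], bad_wl[1])
  bad_side <- which(!df$side %in% c("left", "right"))
  if (length(bad_side))
    .stopf("spectra table: side must be 'left' or 'right' (row %d)", bad_side[1])
  key <- paste(df$participant_id, df$side, df$spectrum_id, df$wavelength_nm,
               sep = "|")
  dup <- which(duplicated(key))
  if (length(dup))
    .stopf("spectra table: duplicated key '%s' (row %d)", key[dup[1]], dup[1])
  df
}

#' Read and validate a per-breast volumetric measures table
#'
#' Required columns: `participant_id` plus the per-side DXA columns
#' `fgv_left_cm3`, `vol_left_cm3`, `fgv_right_cm3`, `vol_right_cm3`;
#' mammographic columns (`dense_*_cm3`, `mammo_vol_*_cm3`) are optional /
#' may be NA (daughters).
#'
#' @param path CSV file path.
#' @return A validated tibble.
#' @export
read_measures_table <- function(path) {
  num <- c("fgv_left_cm3", "vol_left_cm3", "fgv_right_cm3", "vol_right_cm3",
           "dense_left_cm3", "mammo_vol_left_cm3", "dense_right_cm3",
           "mammo_vol_right_cm3")
  df <- .read_csv_checked(path, required = c("participant_id", num[1:4]),
                          numeric_cols = num, what = "measures")
  dup <- which(duplicated(df$participant_id))
  if (length(dup))
    .stopf("measures table: duplicated participant_id '%s' (row %d)",
           df$participant_id[dup[1]], dup[1])
  df
}

#' Read and validate a covariates table
#'
#' Required columns: `participant_id`, `pair_id`, `group` (daughter/mother),
#' `age`, `bmi`.
#'
#' @param path CSV file path.
#' @return A validated tibble.
#' @export
read_covariates_table <- function(path) {
  df <- .read_csv_checked(path,
                          required = c("participant_id", "pair_id", "group",
                                       "age", "bmi"),
                          numeric_cols = c("pair_id", "age", "bmi"),
                          what = "covariates")
  bad <- which(!df$group %in% c("daughter", "mother"))
  if (length(bad))
    .stopf("covariates table: unknown group '%s' (row %d)", df$group[bad[1]],
           bad[1])
  dup <- which(duplicated(df$participant_id))
  if (length(dup))
    .stopf("covariates table: duplicated participant_id (row %d)", dup[1])
  df
}

#' Write an output table with a provenance header
#'
#' Prepends a `#` comment line carrying the package version, the seed and
#' the configuration hash, then the CSV body. Files written this way are
#' readable by all `read_*_table()` functions.
#'
#' @param df data frame to write.
#' @param path output path (directories are created).
#' @param seed integer seed used for the run (or `NA`).
#' @param config a configuration list (hashed with [config_hash()]) or `NULL`.
#' @return `path`, invisibly.
#' @export
write_output_table <- function(df, path, seed = NA, config = NULL) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  hash <- if (is.null(config)) "none" else config_hash(config)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# osdensity %s; seed=%s; config_hash=%s",
                     as.character(packageVersion("osdensity")),
                     as.character(seed), hash), con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Deterministic hash of a configuration
#'
#' @param config any serializable list.
#' @return An 8-hex-digit string.
#' @export
config_hash <- function(config) {
  sprintf("%08x", .string_hash(yaml::as.yaml(unclass(config))))
}

#' Assemble a full pipeline configuration
#'
#' Bundles the cohort generator settings, fit bounds and fitting options
#' into one validated object whose defaults reproduce the package's stated
#' constants. Unknown fields are rejected.
#'
#' @param cohort a [cohort_config()].
#' @param bounds a [fit_bounds()].
#' @param n_starts multi-start count for spectral fitting.
#' @param residual_scale `"log"` or `"linear"`.
#' @param basis `"reference"` or `"toy"`.
#' @param t_var_equal pooled-variance t-tests if `TRUE`.
#' @param seed master seed (defaults to the cohort seed).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(), bounds = fit_bounds(),
                            n_starts = 8, residual_scale = "log",
                            basis = "reference", t_var_equal = TRUE,
                            seed = cohort$seed) {
  if (!residual_scale %in% c("log", "linear"))
    .stopf("residual_scale must be 'log' or 'linear'")
  if (!basis %in% c("reference", "toy")) .stopf("basis must be 'reference' or 'toy'")
  structure(list(seed = as.integer(seed), cohort = cohort, bounds = bounds,
                 n_starts = as.integer(n_starts),
                 residual_scale = residual_scale, basis = basis,
                 t_var_equal = isTRUE(t_var_equal)),
            class = "pipeline_config")
}

.cfg_fields <- c("seed", "cohort", "bounds", "n_starts", "residual_scale",
                 "basis", "t_var_equal")

#' Load a pipeline configuration from YAML
#'
#' Missing fields take their defaults; unknown top-level or nested fields
#' are rejected. A load -> [save_pipeline_config()] -> load round trip
#' yields an identical configuration.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
load_pipeline_config <- function(path) {
  if (!file.exists(path)) .stopf("config file not found: %s", path)
  raw <- yaml::read_yaml(path)
  unknown <- setdiff(names(raw), .cfg_fields)
  if (length(unknown)) .stopf("unknown config field(s): %s",
                              paste(unknown, collapse = ", "))
  defaults <- pipeline_config()
  cohort <- defaults$cohort
  if (!is.null(raw$cohort)) {
    unknown <- setdiff(names(raw$cohort), names(unclass(cohort)))
    if (length(unknown)) .stopf("unknown cohort config field(s): %s",
                                paste(unknown, collapse = ", "))
    merged <- utils::modifyList(unclass(cohort), raw$cohort)
    merged$n_pairs <- as.integer(merged$n_pairs)
    merged$seed <- as.integer(merged$seed)
    merged$n_positions <- as.integer(merged$n_positions)
    cohort <- validate_cohort_config(merged)
  }
  bounds <- defaults$bounds
  if (!is.null(raw$bounds)) {
    unknown <- setdiff(names(raw$bounds), names(unclass(bounds)))
    if (length(unknown)) .stopf("unknown bounds field(s): %s",
                                paste(unknown, collapse = ", "))
    args <- utils::modifyList(unclass(bounds), raw$bounds)
    bounds <- do.call(fit_bounds, args)
  }
  pipeline_config(
    cohort = cohort, bounds = bounds,
    n_starts = if (is.null(raw$n_starts)) defaults$n_starts else raw$n_starts,
    residual_scale = if (is.null(raw$residual_scale)) defaults$residual_scale
                     else raw$residual_scale,
    basis = if (is.null(raw$basis)) defaults$basis else raw$basis,
    t_var_equal = if (is.null(raw$t_var_equal)) defaults$t_var_equal
                  else raw$t_var_equal,
    seed = if (is.null(raw$seed)) cohort$seed else raw$seed)
}

#' Save a pipeline configuration to YAML
#'
#' @param config a `pipeline_config`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_pipeline_config <- function(config, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  out <- unclass(config)
  out$cohort <- unclass(out$cohort)
  out$bounds <- unclass(out$bounds)
  yaml::write_yaml(out, path)
  invisible(path)
}
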
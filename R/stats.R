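#' Standardize a numeric vector to mean 0, SD 1
#'
#' @param x numeric vector with at least 2 non-missing values and positive
#'   sample SD. `NA`s are preserved in place.
#' @return z-scores (sample SD, denominator n - 1).
#' @export
standardize <- function(x) {
  v <- x[!is.na(x)]
  if (length(v) < 2) .stopf("standardize needs at least 2 non-missing values")
  s <- sd(v)
  if (s == 0) .stopf("standardize is undefined for a constant vector")
  (x - mean(v)) / s
}

.stat_result <- function(estimate, statistic, df, p, n) {
  tibble::tibble(estimate = estimate, statistic = statistic, df = df,
                 p_value = p, n = n)
}

#' Two-sample t-test from group summaries
#'
#' Pooled-variance Student t-test (default) or Welch test computed from the
#' printed group means, SDs and sizes; two-sided p.
#'
#' @param mean1,sd1,n1,mean2,sd2,n2 group summaries (`n >= 2`, `sd >= 0`).
#' @param var_equal pooled variance if `TRUE` (default), Welch otherwise.
#' @return A one-row result tibble (`estimate` is mean1 - mean2).
#' @export
two_sample_t_summary <- function(mean1, sd1, n1, mean2, sd2, n2,
                                 var_equal = TRUE) {
  if (n1 < 2 || n2 < 2) .stopf("both groups need n >= 2")
  if (sd1 < 0 || sd2 < 0) .stopf("SDs must be >= 0")
  diff <- mean1 - mean2
  if (sd1 == 0 && sd2 == 0) {
    if (diff == 0) return(.stat_result(0, 0, n1 + n2 - 2, 1, n1 + n2))
    .stopf("zero variance with unequal means: t is undefined")
  }
  if (var_equal) {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    v1 <- sd1^2 / n1
    v2 <- sd2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  t <- diff / se
  .stat_result(diff, t, df, 2 * pt(-abs(t), df), n1 + n2)
}

#' Two-sample t-test from raw vectors
#'
#' @param x,y numeric vectors (`NA`s dropped; each needs >= 2 values).
#' @param var_equal pooled variance if `TRUE` (default), Welch otherwise.
#' @return A one-row result tibble (`estimate` is mean(x) - mean(y)).
#' @export
two_sample_t <- function(x, y, var_equal = TRUE) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  two_sample_t_summary(mean(x), sd(x), length(x), mean(y), sd(y), length(y),
                       var_equal = var_equal)
}

#' Pearson correlation with a two-sided p-value
#'
#' p from `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom.
#'
#' @param x,y equal-length numeric vectors; pairwise-complete cases are used
#'   and at least 3 are required; neither may be constant.
#' @return A one-row result tibble (`estimate` is r).
#' @export
pearson_with_p <- function(x, y) {
  if (length(x) != length(y)) .stopf("x and y must have equal length")
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) .stopf("at least 3 complete pairs are required")
  if (sd(x) == 0 || sd(y) == 0)
    .stopf("correlation is undefined for a constant vector")
  r <- cor(x, y)
  if (abs(r) >= 1) return(.stat_result(r, sign(r) * Inf, n - 2, 0, n))
  t <- r * sqrt((n - 2) / (1 - r^2))
  .stat_result(r, t, n - 2, 2 * pt(-abs(t), n - 2), n)
}

#' Partial correlation adjusted for covariates
#'
#' Pearson correlation of the residuals of `x` and `y` after least-squares
#' projection on the covariates plus an intercept; p from t on `n - 2 - k`
#' degrees of freedom. With no covariates this reduces exactly to
#' [pearson_with_p()].
#'
#' @param x,y numeric vectors.
#' @param covariates numeric matrix or data frame with one column per
#'   covariate (or `NULL`). Complete cases across `x`, `y` and the covariates
#'   are used; `n >= k + 3` required; the design must be full rank.
#' @return A one-row result tibble (`estimate` is the partial r).
#' @export
partial_correlation <- function(x, y, covariates = NULL) {
  if (is.null(covariates) || NCOL(covariates) == 0 ||
      (is.matrix(covariates) && ncol(covariates) == 0))
    return(pearson_with_p(x, y))
  Z <- as.matrix(covariates)
  if (length(x) != length(y) || nrow(Z) != length(x))
    .stopf("x, y and covariates must have matching lengths")
  ok <- complete.cases(x, y, Z)
  x <- x[ok]; y <- y[ok]; Z <- Z[ok, , drop = FALSE]
  k <- ncol(Z)
  n <- length(x)
  if (n < k + 3) .stopf("need n >= k + 3 observations (have %d, k = %d)", n, k)
  design <- cbind(`(Intercept)` = 1, Z)
  qrd <- qr(design)
  if (qrd$rank < ncol(design))
    .stopf("covariate matrix is rank deficient (collinear columns)")
  rx <- qr.resid(qrd, x)
  ry <- qr.resid(qrd, y)
  if (sd(rx) == 0 || sd(ry) == 0)
    .stopf("a variable is fully explained by the covariates")
  r <- cor(rx, ry)
  df <- n - 2 - k
  if (abs(r) >= 1) return(.stat_result(r, sign(r) * Inf, df, 0, n))
  t <- r * sqrt(df / (1 - r^2))
  .stat_result(r, t, df, 2 * pt(-abs(t), df), n)
}

#' Influential-point sensitivity for a partial correlation
#'
#' Standardizes `x` and `y`, removes observations whose pre-removal |z|
#' exceeds `threshold` on either measure (single pass; covariates are not
#' screened), and recomputes the partial correlation.
#'
#' @param x,y numeric vectors.
#' @param covariates as in [partial_correlation()].
#' @param threshold |z| cutoff (default 2).
#' @return A list: `full` and `reduced` result tibbles, and `n_removed`.
#' @export
sensitivity_excluding_outliers <- function(x, y, covariates = NULL,
                                           threshold = 2) {
  full <- partial_correlation(x, y, covariates)
  zx <- standardize(x)
  zy <- standardize(y)
  drop <- (!is.na(zx) & abs(zx) > threshold) | (!is.na(zy) & abs(zy) > threshold)
  keep <- !drop
  k <- if (is.null(covariates)) 0 else NCOL(covariates)
  if (sum(keep & complete.cases(x, y)) < k + 3)
    .stopf("fewer than k + 3 observations remain after outlier removal")
  Zr <- if (is.null(covariates)) NULL else
    as.matrix(covariates)[keep, , drop = FALSE]
  reduced <- partial_correlation(x[keep], y[keep], Zr)
  list(full = full, reduced = reduced, n_removed = sum(drop, na.rm = TRUE))
}

# measures shown in the group-summary table, in report order
.report_measures <- function() {
  c(pct_bdi = "BDI from OS, %", pct_fgv = "FGV from DXA, %",
    pct_mbd = "MBD from mammograms, %", afgv_cm3 = "FGV from DXA, cm3",
    ambd_cm3 = "MBD from mammograms, cm3", optical_index = "Optical index",
    lipid = "Lipid, %", water = "Water, %", collagen = "Collagen, %",
    total_hb = "Total hemoglobin, %", amplitude = "Scattering amplitude, mm-1",
    power = "Scattering power")
}

.pair_vectors <- function(df, col) {
  wide <- df[!is.na(df$pair_id), c("pair_id", "group", col)]
  d <- wide[wide$group == "daughter", ]
  m <- wide[wide$group == "mother", ]
  ids <- intersect(d$pair_id, m$pair_id)
  list(daughter = d[[col]][match(ids, d$pair_id)],
       mother = m[[col]][match(ids, m$pair_id)])
}

.partial_cell <- function(df, xcol, ycol, grp) {
  sub <- df[df$group == grp, ]
  ok <- complete.cases(sub[[xcol]], sub[[ycol]], sub$age, sub$bmi)
  if (sum(ok) < 5)
    return(tibble::tibble(r_partial = NA_real_, p_value = NA_real_,
                          n = sum(ok)))
  res <- partial_correlation(sub[[xcol]], sub[[ycol]],
                             cbind(age = sub$age, bmi = sub$bmi))
  tibble::tibble(r_partial = res$estimate, p_value = res$p_value, n = res$n)
}

#' Build the device-comparison report tables
#'
#' Produces the three analysis tables: (1) group summaries with two-sample
#' t-tests and mother-daughter pair correlations; (2) partial correlations
#' (adjusted for age and BMI) between relative density measures (%BDI, %FGV,
#' %MBD) and between absolute measures (%collagen-water, AFGV, AMBD) by
#' group; (3) partial correlations of the individual OS measures with %FGV
#' (both groups) and %MBD (mothers). Comparisons unavailable for a group
#' (mammography in daughters) are explicit `NA` cells. Results are invariant
#' to input row order.
#'
#' @param measures per-participant measures tibble (see
#'   [compute_density_measures()]).
#' @param covariates tibble with `participant_id`, `pair_id`, `group`,
#'   `age`, `bmi`.
#' @param var_equal t-test variant for the summary table (pooled if `TRUE`).
#' @return A list of tibbles: `table1`, `table2`, `table3`.
#' @export
build_report <- function(measures, covariates, var_equal = TRUE) {
  need <- c("participant_id", "pair_id", "group", "age", "bmi")
  miss <- setdiff(need, names(covariates))
  if (length(miss)) .stopf("covariates table missing column(s): %s",
                           paste(miss, collapse = ", "))
  if (!"participant_id" %in% names(measures))
    .stopf("measures table missing column(s): participant_id")
  df <- dplyr::inner_join(covariates, measures, by = "participant_id")
  df <- df[order(df$group, df$pair_id, df$participant_id), ]

  meas <- .report_measures()
  meas <- meas[names(meas) %in% names(df)]
  t1 <- lapply(names(meas), function(col) {
    dvals <- df[[col]][df$group == "daughter" & !is.na(df[[col]])]
    mvals <- df[[col]][df$group == "mother" & !is.na(df[[col]])]
    tt <- if (length(dvals) >= 2 && length(mvals) >= 2)
      two_sample_t(dvals, mvals, var_equal = var_equal)$p_value else NA_real_
    pv <- .pair_vectors(df, col)
    pr <- if (sum(complete.cases(pv$daughter, pv$mother)) >= 3 &&
              sd(pv$daughter, na.rm = TRUE) > 0 && sd(pv$mother, na.rm = TRUE) > 0)
      pearson_with_p(pv$daughter, pv$mother) else NULL
    tibble::tibble(
      measure = meas[[col]], column = col,
      daughter_mean = if (length(dvals)) mean(dvals) else NA_real_,
      daughter_sd = if (length(dvals) > 1) sd(dvals) else NA_real_,
      daughter_n = length(dvals),
      mother_mean = if (length(mvals)) mean(mvals) else NA_real_,
      mother_sd = if (length(mvals) > 1) sd(mvals) else NA_real_,
      mother_n = length(mvals),
      t_test_p = tt,
      pair_r = if (is.null(pr)) NA_real_ else pr$estimate,
      pair_p = if (is.null(pr)) NA_real_ else pr$p_value)
  })
  table1 <- dplyr::bind_rows(t1)

  t2_pairs <- tibble::tribble(
    ~scale, ~x, ~y, ~label,
    "relative", "pct_bdi", "pct_fgv", "%BDI from OS vs %FGV from DXA",
    "relative", "pct_bdi", "pct_mbd", "%BDI from OS vs %MBD from mammograms",
    "relative", "pct_fgv", "pct_mbd", "%FGV from DXA vs %MBD from mammograms",
    "absolute", "pct_collagen_water", "afgv_cm3", "%Collagen-Water from OS vs AFGV from DXA",
    "absolute", "pct_collagen_water", "ambd_cm3", "%Collagen-Water from OS vs AMBD from mammograms",
    "absolute", "afgv_cm3", "ambd_cm3", "AFGV from DXA vs AMBD from mammograms")
  t2 <- lapply(seq_len(nrow(t2_pairs)), function(i) {
    p <- t2_pairs[i, ]
    d <- .partial_cell(df, p$x, p$y, "daughter")
    m <- .partial_cell(df, p$x, p$y, "mother")
    tibble::tibble(scale = p$scale, comparison = p$label,
                   daughter_r_partial = d$r_partial, daughter_p = d$p_value,
                   mother_r_partial = m$r_partial, mother_p = m$p_value)
  })
  table2 <- dplyr::bind_rows(t2)

  os_measures <- c("optical_index", "lipid", "water", "collagen", "total_hb",
                   "amplitude", "power")
  t3 <- lapply(os_measures, function(col) {
    d_fgv <- .partial_cell(df, col, "pct_fgv", "daughter")
    m_fgv <- .partial_cell(df, col, "pct_fgv", "mother")
    m_mbd <- .partial_cell(df, col, "pct_mbd", "mother")
    tibble::tibble(os_measure = col,
                   fgv_daughter_r = d_fgv$r_partial, fgv_daughter_p = d_fgv$p_value,
                   fgv_mother_r = m_fgv$r_partial, fgv_mother_p = m_fgv$p_value,
                   mbd_mother_r = m_mbd$r_partial, mbd_mother_p = m_mbd$p_value)
  })
  table3 <- dplyr::bind_rows(t3)

  list(table1 = table1, table2 = table2, table3 = table3)
}

#' Scatter plot of a standardized measure pair
#'
#' Convenience figure mirroring the device-comparison scatter plots: both
#' measures standardized to mean 0, SD 1, one panel per group.
#'
#' @param measures,covariates as in [build_report()].
#' @param x,y measure column names.
#' @return A ggplot object.
#' @export
plot_measure_pair <- function(measures, covariates, x, y) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    .stopf("ggplot2 is required for plotting")
  df <- dplyr::inner_join(covariates, measures, by = "participant_id")
  df <- df[complete.cases(df[[x]], df[[y]]), ]
  df$zx <- standardize(df[[x]])
  df$zy <- standardize(df[[y]])
  ggplot2::ggplot(df, ggplot2::aes(.data$zx, .data$zy)) +
    ggplot2::geom_point(shape = 18, size = 2) +
    ggplot2::facet_wrap(~group) +
    ggplot2::labs(x = paste(x, "(z)"), y = paste(y, "(z)"))
}
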
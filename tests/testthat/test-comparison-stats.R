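test_that("standardization yields mean 0, SD 1 and is affine-invariant", {
  expect_equal(standardize(c(1, 2, 3)), c(-1, 0, 1))
  z <- standardize(rnorm(50, 10, 3))
  expect_lt(abs(mean(z)), 1e-12)
  expect_lt(abs(sd(z) - 1), 1e-12)
  expect_equal(standardize(z), z, tolerance = 1e-12)          # idempotent
  x <- c(4, 8, 15, 16, 23, 42)
  expect_equal(standardize(3 * x - 7), standardize(x), tolerance = 1e-12)
  expect_error(standardize(rep(5, 4)), "constant")
  expect_error(standardize(3), "at least 2")
})

test_that("two-sample t-tests match stats::t.test and printed-summary forms", {
  set.seed(8)
  x <- rnorm(20, 5, 2)
  y <- rnorm(25, 4, 3)
  for (ve in c(TRUE, FALSE)) {
    ours <- two_sample_t(x, y, var_equal = ve)
    ref <- t.test(x, y, var.equal = ve)
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(ours$df, unname(ref$parameter), tolerance = 1e-12)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
    # summary form agrees with the raw-vector form
    summ <- two_sample_t_summary(mean(x), sd(x), 20, mean(y), sd(y), 25,
                                 var_equal = ve)
    expect_equal(summ$p_value, ours$p_value, tolerance = 1e-12)
  }
  ident <- two_sample_t(c(1, 2, 3), c(3, 1, 2))
  expect_equal(ident$statistic, 0)
  expect_equal(ident$p_value, 1)
  expect_equal(two_sample_t_summary(5, 0, 10, 5, 0, 10)$p_value, 1)
  expect_error(two_sample_t_summary(5, 0, 10, 6, 0, 10), "zero variance")
  expect_error(two_sample_t_summary(5, 1, 1, 6, 1, 10), "n >= 2")
})

test_that("Pearson correlation and p-value match an independent computation", {
  # small printed fixture: hand-computed covariance / SD ratio
  x <- c(2.1, 3.4, 1.8, 5.0, 4.2, 3.3, 2.7, 4.8, 3.9, 2.2)
  y <- c(12.0, 14.1, 11.2, 18.9, 16.0, 14.8, 12.9, 18.1, 15.5, 11.9)
  n <- length(x)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  ours <- pearson_with_p(x, y)
  expect_equal(ours$estimate, r_hand, tolerance = 1e-12)
  ref <- cor.test(x, y)
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
  expect_equal(ours$df, n - 2)

  expect_equal(pearson_with_p(x, 2 * x + 1)$estimate, 1)
  big <- withr::with_seed(9, list(a = rnorm(5000), b = rnorm(5000)))
  expect_lt(abs(pearson_with_p(big$a, big$b)$estimate), 0.05)
  expect_error(pearson_with_p(x, rep(1, n)), "constant")
  expect_error(pearson_with_p(1:2, 2:1), "3 complete")
})

test_that("partial correlation equals the precision-matrix oracle", {
  set.seed(12)
  for (i in 1:20) {
    n <- sample(15:60, 1)
    k <- sample(1:3, 1)
    Z <- matrix(rnorm(n * k), n, k)
    x <- rnorm(n) + Z %*% rnorm(k)
    y <- rnorm(n) + Z %*% rnorm(k)
    ours <- partial_correlation(as.vector(x), as.vector(y), Z)
    expect_equal(ours$estimate, precision_partial_r(x, y, Z),
                 tolerance = 1e-10)
    expect_equal(ours$df, n - 2 - k)
    # symmetry and affine invariance
    expect_equal(partial_correlation(as.vector(y), as.vector(x), Z)$estimate,
                 ours$estimate, tolerance = 1e-12)
    expect_equal(partial_correlation(2 * as.vector(x) - 3, as.vector(y) / 7,
                                     sweep(Z, 2, rnorm(k), "*"))$estimate,
                 ours$estimate, tolerance = 1e-10)
  }
  # zero covariates reduce exactly to Pearson
  x <- rnorm(30); y <- rnorm(30)
  expect_equal(partial_correlation(x, y, NULL), pearson_with_p(x, y))
  expect_equal(partial_correlation(x, y, matrix(numeric(0), 30, 0)),
               pearson_with_p(x, y))
  # collinear covariates are rejected
  Zbad <- cbind(1:30, 2 * (1:30))
  expect_error(partial_correlation(x, y, Zbad), "rank deficient")
  expect_error(partial_correlation(x[1:3], y[1:3], Zbad[1:3, 1, drop = FALSE]),
               "k \\+ 3")
})

test_that("partial correlation recovers a known conditional correlation", {
  # x and y share a conditional correlation of 0.5 given two covariates
  set.seed(33)
  reps <- 200
  n <- 42
  est <- vapply(seq_len(reps), function(i) {
    Z <- cbind(rnorm(n), rnorm(n))
    shared <- rnorm(n)
    x <- Z %*% c(0.8, -0.5) + shared + rnorm(n)
    y <- Z %*% c(-0.3, 0.7) + shared + rnorm(n)
    partial_correlation(as.vector(x), as.vector(y), Z)$estimate
  }, numeric(1))
  expect_lt(abs(mean(est) - 0.5), 0.05)
})

test_that("influential-point screening is a single pre-removal pass", {
  set.seed(14)
  n <- 40
  Z <- cbind(age = rnorm(n, 45, 7), bmi = rnorm(n, 30, 5))
  # bounded grids whose standardized values stay within |z| <= 2:
  # reduced result must be identical to the full result
  xs <- seq(-1, 1, length.out = n)
  ys <- xs + 0.1 * sin(5 * xs)
  stopifnot(max(abs(standardize(xs))) < 2, max(abs(standardize(ys))) < 2)
  res <- sensitivity_excluding_outliers(xs, ys, Z)
  expect_equal(res$n_removed, 0)
  expect_equal(res$reduced, res$full)

  # one planted extreme point is removed
  x2 <- c(xs, 10)
  y2 <- c(ys, 0)
  Z2 <- rbind(Z, c(45, 30))
  res2 <- sensitivity_excluding_outliers(x2, y2, Z2)
  expect_equal(res2$n_removed, 1)
  expect_equal(res2$reduced$n, n)

  # single pass: points that would exceed |z| > 2 only after removal stay in
  x3 <- c(rep(0, 10), 1.9, 10)
  y3 <- seq_along(x3)
  res3 <- sensitivity_excluding_outliers(x3, y3, NULL)
  expect_equal(res3$n_removed, 1)  # only the planted 10; not the 1.9
})

test_that("report tables cover all comparisons and mark unavailable cells NA", {
  cfg <- cohort_config(n_pairs = 25, seed = 17)
  sim <- simulate_cohort(cfg, spectra = FALSE)
  comp <- sim$truth
  meas <- compute_density_measures(comp, sim$measures)
  rep <- build_report(meas, sim$covariates)

  expect_named(rep, c("table1", "table2", "table3"))
  t1 <- rep$table1
  expect_true(all(c("pct_bdi", "pct_mbd", "lipid") %in% t1$column))
  expect_equal(t1$daughter_n[t1$column == "pct_mbd"], 0)
  expect_true(is.na(t1$daughter_mean[t1$column == "pct_mbd"]))
  expect_true(is.finite(t1$mother_mean[t1$column == "pct_mbd"]))
  expect_true(all(is.finite(t1$t_test_p[t1$column %in%
                                          c("pct_bdi", "lipid", "water")])))
  # pair correlations computed over complete pairs
  expect_true(all(abs(t1$pair_r) <= 1, na.rm = TRUE))

  t2 <- rep$table2
  expect_equal(nrow(t2), 6)
  mbd_rows <- grepl("MBD", t2$comparison)
  expect_true(all(is.na(t2$daughter_r_partial[mbd_rows])))
  expect_true(all(is.finite(t2$mother_r_partial[mbd_rows])))
  expect_true(all(is.finite(t2$daughter_r_partial[!mbd_rows])))

  t3 <- rep$table3
  expect_equal(nrow(t3), 7)
  expect_true(all(is.finite(t3$fgv_daughter_r)))
  expect_true(all(is.finite(t3$mbd_mother_r)))

  # permuting input rows leaves every table unchanged
  perm_m <- withr::with_seed(2, meas[sample(nrow(meas)), ])
  perm_c <- withr::with_seed(3, sim$covariates[sample(nrow(sim$covariates)), ])
  rep2 <- build_report(perm_m, perm_c)
  expect_equal(rep2, rep)

  expect_error(build_report(meas, sim$covariates[, 1:3]), "missing column")
})

test_that("noise-free identity links give near-perfect relative correlations", {
  cfg <- cohort_config(n_pairs = 30, seed = 19)
  for (g in c("daughter", "mother"))
    cfg$imaging[[g]]$fgv <- list(intercept = 0, slope = 1, bmi_slope = 0,
                                 noise_sd = 0, noise_share = 0.8)
  sim <- simulate_cohort(cfg, spectra = FALSE)
  meas <- compute_density_measures(sim$truth, sim$measures)
  rep <- build_report(meas, sim$covariates)
  row <- rep$table2[rep$table2$comparison == "%BDI from OS vs %FGV from DXA", ]
  expect_gt(row$daughter_r_partial, 0.99)
  expect_gt(row$mother_r_partial, 0.99)
})
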
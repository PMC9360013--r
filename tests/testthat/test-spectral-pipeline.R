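test_that("usability filter implements the wavelength rules exactly", {
  # six usable wavelengths: excluded as too few, even though 985 is absent too
  s6 <- make_spectrum_tbl(interior_truth(),
                          wavelengths = c(650, 680, 730, 755, 810, 850))
  res <- qc_filter(s6)
  expect_equal(nrow(res$retained), 0)
  expect_equal(res$exclusions$reason, "too_few_wavelengths")

  # seven wavelengths with 985 and 905: retained
  s7 <- make_spectrum_tbl(interior_truth(),
                          wavelengths = c(650, 680, 730, 755, 810, 905, 985))
  res <- qc_filter(s7)
  expect_equal(nrow(res$retained), 7)
  expect_equal(nrow(res$exclusions), 0)

  # seven wavelengths without 985: excluded for the missing water peak
  s985 <- make_spectrum_tbl(interior_truth(),
                            wavelengths = c(650, 680, 730, 755, 810, 850, 905))
  expect_equal(qc_filter(s985)$exclusions$reason, "missing_985")

  # constructed 12-spectrum fixture: verdicts are exact and order-invariant
  fx <- qc_fixture_12()
  res <- qc_filter(fx)
  expect_equal(length(unique(res$retained$spectrum_id)), 5)
  want <- qc_fixture_expected()
  got <- setNames(res$exclusions$reason, res$exclusions$spectrum_id)
  expect_mapequal(as.list(got), as.list(want))
  perm <- withr::with_seed(1, fx[sample(nrow(fx)), ])
  res_p <- qc_filter(perm)
  expect_setequal(unique(res_p$retained$spectrum_id),
                  unique(res$retained$spectrum_id))
  expect_mapequal(as.list(setNames(res_p$exclusions$reason,
                                   res_p$exclusions$spectrum_id)),
                  as.list(want))

  # unusable flags drop a wavelength: an 8-wavelength spectrum losing 985
  # still has >= 7 usable but fails the water-peak rule
  s8 <- make_spectrum_tbl(interior_truth(),
                          wavelengths = c(650, 680, 730, 755, 810, 850, 905, 985))
  s8$usable[s8$wavelength_nm == 985] <- 0L
  expect_equal(qc_filter(s8)$exclusions$reason, "missing_985")
  expect_equal(nrow(qc_filter(s7[0, ])$retained), 0)
})

test_that("noise-free spectra are recovered within bounds, deterministically", {
  set.seed(7)
  for (i in 1:3) {
    truth <- random_interior_truth()
    sp <- make_spectrum_tbl(truth, cup = sample(c("A", "B", "C"), 1),
                            offset = sample(c(0, 20), 1))
    fits <- fit_spectrum(sp, seed = i)
    best <- select_best_fit(fits)
    expect_false(is_fit_failure(best))
    expect_lt(abs(best$water - truth$water), 0.2)
    expect_lt(abs(best$lipid - truth$lipid), 0.2)
    expect_lt(abs(best$collagen - truth$collagen), 0.2)
    expect_lt(abs(best$total_hb - truth$total_hb), 0.02)
    expect_lt(abs(best$power - truth$power), 0.02)
    # every candidate satisfies the box bounds and the joint constraints
    b <- fit_bounds()
    expect_true(all(fits$water >= b$water[1] & fits$water <= b$water[2]))
    expect_true(all(fits$lipid >= b$lipid[1] & fits$lipid <= b$lipid[2]))
    expect_true(all(fits$collagen >= b$collagen[1] & fits$collagen <= b$collagen[2]))
    expect_true(all(fits$total_hb >= b$total_hb[1] - 1e-9 &
                      fits$total_hb <= b$total_hb[2] + 1e-9))
    expect_equal(fits$total_hb, fits$oxyhb + fits$deoxyhb, tolerance = 1e-12)
    ok <- fits$converged
    expect_true(all((fits$water + fits$lipid + fits$collagen +
                       fits$total_hb)[ok] <= b$sum_cap + 1e-9))
    expect_true(all(diff(fits$sse) >= 0))  # sorted by objective
  }

  sp <- make_spectrum_tbl(interior_truth())
  expect_identical(fit_spectrum(sp, seed = 3), fit_spectrum(sp, seed = 3))

  # truth placed at the collagen upper bound is detected as at-bounds
  at_bound <- interior_truth(collagen = 30)
  spb <- make_spectrum_tbl(at_bound)
  bestb <- select_best_fit(fit_spectrum(spb, seed = 2), max_at_bounds = 7)
  expect_gte(bestb$n_at_bounds, 1)

  # spectra failing QC are a precondition error
  bad <- make_spectrum_tbl(interior_truth(), wavelengths = c(650, 700, 750))
  expect_error(fit_spectrum(bad), "usability")
})

test_that("best-fit selection applies the at-bounds rule then minimum sse", {
  cand <- tibble::tibble(start_index = 1:3, sse = c(3, 1, 2),
                         n_at_bounds = c(0L, 3L, 1L),
                         converged = TRUE,
                         water = 17, lipid = 46, collagen = 21,
                         oxyhb = 0.4, deoxyhb = 0.2, total_hb = 0.6,
                         amplitude = 1.7, power = 1.3)
  best <- select_best_fit(cand)
  expect_equal(best$sse, 2)
  expect_equal(best$n_at_bounds, 1L)

  single <- cand[1, ]
  expect_equal(select_best_fit(single)$start_index, 1L)

  allbad <- cand
  allbad$n_at_bounds <- c(3L, 4L, 7L)
  expect_true(is_fit_failure(select_best_fit(allbad)))
  # exhaustively: no candidate qualifies under the stated rule
  expect_true(all(allbad$n_at_bounds > 2))

  unconv <- cand
  unconv$converged <- c(FALSE, FALSE, TRUE)
  expect_equal(select_best_fit(unconv)$start_index, 3L)

  tie <- cand
  tie$sse <- c(1, 1, 1)
  tie$n_at_bounds <- c(1L, 0L, 0L)
  expect_equal(select_best_fit(tie)$start_index, 2L)  # fewer at bounds, then index

  expect_error(select_best_fit(cand[0, ]), "non-empty")
})

test_that("participant aggregation is the unweighted mean over spectra", {
  row <- function(w, side = "left")
    tibble::tibble(side = side, water = w, lipid = 46, collagen = 21,
                   oxyhb = 0.4, deoxyhb = 0.2, total_hb = 0.6,
                   amplitude = 1.7, power = 1.3)
  two <- dplyr::bind_rows(row(16), row(18, "right"))
  agg <- aggregate_participant(two)
  expect_equal(agg$water, 17)
  expect_equal(agg$n_spectra_used, 2)
  expect_equal(agg$n_left, 1)
  expect_equal(agg$n_right, 1)

  one <- row(16.5)
  expect_equal(aggregate_participant(one)$water, 16.5)

  set.seed(11)
  five <- dplyr::bind_rows(lapply(1:5, function(i)
    tibble::tibble(side = sample(c("left", "right"), 1),
                   water = runif(1, 5, 30), lipid = runif(1, 20, 60),
                   collagen = runif(1, 2, 28), oxyhb = runif(1, 0.2, 0.7),
                   deoxyhb = runif(1, 0.05, 0.3), total_hb = 0,
                   amplitude = runif(1, 0.5, 3), power = runif(1, 0.3, 3))))
  five$total_hb <- five$oxyhb + five$deoxyhb
  agg5 <- aggregate_participant(five)
  for (col in c("water", "lipid", "collagen", "amplitude", "power"))
    expect_equal(agg5[[col]], sum(five[[col]]) / 5, tolerance = 1e-12)

  expect_error(aggregate_participant(five[0, ]), "at least one")
})

test_that("the pipeline recovers a noiseless cohort and logs exclusions", {
  cfg <- cohort_config(n_pairs = 2, seed = 11, n_positions = 1,
                       dropout_prob = 0, noise_sd = 0)
  coh <- simulate_cohort(cfg)
  sp <- dplyr::filter(coh$spectra, offset_mm == 0)
  # knock out one participant entirely: all its wavelengths unusable
  sp$usable[sp$participant_id == "M002"] <- 0L
  res <- run_spectral_pipeline(sp, seed = 5)
  expect_false("M002" %in% res$compositions$participant_id)
  expect_equal(res$participants_excluded$participant_id, "M002")
  expect_true(all(res$exclusions$participant_id == "M002"))

  truth <- coh$truth[match(res$compositions$participant_id,
                           coh$truth$participant_id), ]
  expect_lt(max(abs(res$compositions$water - truth$water)), 1)
  expect_lt(max(abs(res$compositions$lipid - truth$lipid)), 1)
  expect_lt(max(abs(res$compositions$collagen - truth$collagen)), 1)

  # deterministic rerun, and invariant to row order
  res2 <- run_spectral_pipeline(sp, seed = 5)
  expect_identical(res$compositions, res2$compositions)
  perm <- withr::with_seed(3, sp[sample(nrow(sp)), ])
  res3 <- run_spectral_pipeline(perm, seed = 5)
  expect_equal(res$compositions, res3$compositions)
})

test_that("tolerance tightening monotonically improves noise-free recovery", {
  truth <- interior_truth(water = 14, lipid = 50, collagen = 18,
                          total_hb = 0.5, amplitude = 1.2, power = 1.0)
  sp <- make_spectrum_tbl(truth, cup = "C")
  err_at <- function(tol) {
    ctl <- minpack.lm::nls.lm.control(maxiter = 400, ftol = tol, ptol = tol)
    best <- select_best_fit(fit_spectrum(sp, seed = 4, n_starts = 4,
                                         control = ctl))
    max(abs(c(best$water - truth$water, best$lipid - truth$lipid,
              best$collagen - truth$collagen)))
  }
  errs <- vapply(c(1e-3, 1e-7, 1e-12), err_at, numeric(1))
  expect_true(all(diff(errs) <= 1e-9))
  expect_lt(errs[3], 1e-3)
})
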
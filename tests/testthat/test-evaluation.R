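# Validation statistics, cross-validation, model search, comparisons.

test_that("calibration statistics match hand arithmetic", {
  st <- calib_stats(c(0, 1, 2), c(0, 1, 1))
  expect_equal(st$rmse, sqrt(1 / 3), tolerance = 1e-12)
  expect_equal(st$r2, 0.5, tolerance = 1e-12)
  perfect <- calib_stats(c(1, 2, 3), c(1, 2, 3))
  expect_equal(perfect$r2, 1)
  expect_equal(perfect$rmse, 0)
  expect_equal(calib_stats(c(1, 2, 3), rep(2, 3))$r2, 0)
  expect_error(calib_stats(rep(1, 3), c(1, 2, 3)), "zero variance")
})

test_that("calibration/validation splits are seeded, disjoint and exhaustive", {
  ids <- sprintf("S%03d", 1:838)
  sp <- split_calibration_validation(ids, 120, seed = 5)
  expect_length(sp$val, 120)
  expect_length(sp$cal, 718)
  expect_length(intersect(sp$cal, sp$val), 0)
  expect_setequal(c(sp$cal, sp$val), ids)
  expect_identical(sp, split_calibration_validation(ids, 120, seed = 5))
  sp2 <- split_calibration_validation(letters[1:5], 4, seed = 1)
  expect_length(sp2$cal, 1)
  expect_error(split_calibration_validation(ids, 0, seed = 1), "positive")
})

test_that("cross-validation recovers noiseless linear structure and honours folds", {
  set.seed(71)
  grid <- seq(4000, 4400, 4)
  n <- 40
  y <- rnorm(n, 20, 4)
  m <- outer(y, exp(-0.5 * ((grid - 4200) / 50)^2) * 0.01) +
    matrix(rnorm(n * length(grid), 0.3, 0.001), n)
  s <- spectrum_set(grid, m, sprintf("C%02d", 1:n))
  res <- cross_validate(s, y, pretreatment_spec("NONE"), rank_max = 4,
                        cv = cv_spec(10, 2))
  expect_gt(res$r2cv, 0.999)
  expect_equal(res$rpd * res$rmsecv, sd(y), tolerance = 1e-10)
  # leave-one-out runs and agrees with 10-fold within sampling noise
  loo <- cross_validate(s, y, pretreatment_spec("NONE"), rank_max = 4,
                        cv = cv_spec(n, 2))
  expect_lt(abs(loo$r2cv - res$r2cv), 0.01)
  expect_error(cross_validate(s, y, rank_max = 39, cv = cv_spec(10, 2)),
               "fewer than rank")
})

test_that("MSC cross-validation refits the reference per training fold", {
  refs <- generate_reference_traits(60, seed = 72)
  s <- generate_nir_spectra(refs, spectra_config(seed = 73))
  res <- cross_validate(s, refs$cri, pretreatment_spec("MSC"), rank_max = 5,
                        cv = cv_spec(5, 3))
  expect_true(is.finite(res$r2cv))
  # no optimistic leakage: CV never beats the training fit by more than noise
  rec <- evaluate_candidate(s, refs$cri, pretreatment_spec("MSC"),
                            rank_max = 5, cv = cv_spec(5, 3))
  expect_lte(rec$r2cv, rec$r2 + 0.05)
})

test_that("external validation enforces disjointness and the RPD identity", {
  refs <- generate_reference_traits(80, seed = 74)
  s <- generate_nir_spectra(refs, spectra_config(seed = 75))
  sp <- split_calibration_validation(s$ids, 20, seed = 4)
  m <- fit_calibration(s[sp$cal], refs$cri[match(sp$cal, refs$id)],
                       pretreatment_spec("SNV"), rank = 4, trait = "cri")
  ev <- external_validate(m, s[sp$val], refs$cri[match(sp$val, refs$id)])
  expect_equal(ev$rpd * ev$rmsep, sd(refs$cri[match(sp$val, refs$id)]),
               tolerance = 1e-10)
  expect_error(external_validate(m, s[sp$cal][1:10],
                                 refs$cri[match(sp$cal[1:10], refs$id)]),
               "overlap")
})

test_that("model search enumerates, ranks and is reproducible", {
  refs <- generate_reference_traits(60, seed = 76)
  cfg <- spectra_config(wn_lo = 4000, wn_hi = 6000,
                        bands = data.frame(trait = "cri", center = 4500,
                                           width = 100, amplitude = 0.002),
                        seed = 77)
  s <- generate_nir_spectra(refs, cfg)
  blocks <- make_intervals(s$grid, 2)
  regions <- region_candidates(blocks, cap = 3)
  recs <- search_models(s, refs, "cri",
                        pretreatments = c("SNV", "SSL"),
                        region_sets = regions,
                        rank_max = 4, cv = cv_spec(5, 8))
  expect_equal(nrow(recs), 6)               # 2 pretreatments x 3 subsets
  # the signal lives in block 1 (4500 cm^-1 band): the winner includes it
  expect_true(grepl("5000 - 4000|6000 - 4000", recs$regions[1]))
  # ranking is a total order on (rmsecv, -r2cv, rank)
  expect_true(all(diff(recs$rmsecv) >= 0))
  recs2 <- search_models(s, refs, "cri", pretreatments = c("SNV", "SSL"),
                         region_sets = regions, rank_max = 4,
                         cv = cv_spec(5, 8))
  expect_identical(recs, recs2)
})

test_that("merging an empty validation set reproduces the original record", {
  refs <- generate_reference_traits(50, seed = 78)
  s <- generate_nir_spectra(refs, spectra_config(seed = 79))
  rec <- evaluate_candidate(s, refs$cri, pretreatment_spec("SNV"),
                            region_set(c(4000, 8000)), rank_max = 4,
                            cv = cv_spec(5, 9), trait = "cri")
  merged <- merge_validation_and_refit(rec, s, refs, "cri", rank_max = 4,
                                       cv = cv_spec(5, 9))
  expect_equal(merged$r2cv, rec$r2cv, tolerance = 1e-10)
  expect_equal(merged$rmsecv, rec$rmsecv, tolerance = 1e-10)
  expect_lte(merged$n, rec$n + 0)
})

test_that("RMSE F-test behaves like the two-sided F distribution", {
  eq <- compare_rmse(1.5, 100, 1.5, 100)
  expect_equal(eq$f, 1)
  expect_equal(eq$p, 1)
  expect_equal(eq$stars, "")
  dbl <- compare_rmse(2, 50, 1, 60)
  expect_equal(dbl$f, 4)
  expect_equal(dbl$df1, 49)
  expect_equal(dbl$df2, 59)
  expect_equal(dbl$p, min(1, 2 * pf(4, 49, 59, lower.tail = FALSE)),
               tolerance = 1e-12)
  expect_equal(dbl$stars, "**")
  expect_error(compare_rmse(0, 10, 1, 10), "positive")
})

test_that("Fisher-z R^2 comparison matches the transform arithmetic", {
  # r = 0.8 -> z = atanh(0.8) = 0.5 * log(9)
  z <- compare_r2(0.64, 100, 0.64, 100)
  expect_equal(z$z1, 0.5 * log(9), tolerance = 1e-10)
  expect_equal(z$statistic, 0)
  expect_equal(z$p, 1)
  z0 <- compare_r2(0, 50, 0, 50)
  expect_equal(z0$z1, 0)
  expect_error(compare_r2(1, 50, 0.5, 50), "Fisher z")
  expect_error(compare_r2(0.5, 3, 0.5, 50), "n > 3")
})
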
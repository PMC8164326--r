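# Synthetic-data generators: determinism, distribution match, closure
# with the analysis operations.

test_that("reference trait generation reproduces the configured distribution", {
  refs <- generate_reference_traits(1000, seed = 11)
  expect_lt(abs(mean(refs$true_cri) - 42.8), 0.2)
  # moment-matched truncated sampling: observed sds track configured sds
  big <- generate_reference_traits(5000, seed = 12)
  cfg <- trait_config()
  obs_sd <- c(sd(big$cri), sd(big$asl_dm), sd(big$ail_dm), sd(big$cw_frac))
  target <- sqrt(cfg$traits$sd^2 + cfg$traits$noise_sd^2)
  expect_true(all(abs(obs_sd / target - 1) < 0.05))
  true_sd <- c(sd(big$true_cri), sd(big$true_asl_dm), sd(big$true_ail_dm),
               sd(big$true_cw_frac))
  expect_true(all(abs(true_sd / cfg$traits$sd - 1) < 0.05))
  # all values within configured ranges
  expect_true(all(big$cri >= 21.6 & big$cri <= 55.6))
  expect_true(all(big$true_ail_dm >= 9.2 & big$true_ail_dm <= 25.3))
})

test_that("trait generation is deterministic and total lignin is exact", {
  a <- generate_reference_traits(50, seed = 3)
  b <- generate_reference_traits(50, seed = 3)
  expect_identical(a, b)
  expect_equal(a$true_total_dm, a$true_asl_dm + a$true_ail_dm, tolerance = 1e-12)
  expect_equal(a$total_dm, a$asl_dm + a$ail_dm, tolerance = 1e-12)
  # zero measurement noise: observed equals truth exactly
  cfg0 <- trait_config()
  cfg0$traits$noise_sd[] <- 0
  r0 <- generate_reference_traits(40, cfg0, seed = 4)
  expect_identical(r0$cri, r0$true_cri)
  expect_identical(r0$asl_dm, r0$true_asl_dm)
  validate_reference_table(r0)
})

test_that("a non-positive-semidefinite correlation matrix is rejected", {
  R <- default_trait_correlation()
  R[1, 2] <- R[2, 1] <- 0.99
  R[1, 3] <- R[3, 1] <- 0.99
  R[2, 3] <- R[3, 2] <- -0.99
  expect_error(trait_config(correlation = R), "positive semidefinite")
  R2 <- default_trait_correlation(); R2[1, 2] <- 0.5
  expect_error(trait_config(correlation = R2), "symmetric")
})

test_that("artifact-free single-band spectra are proportional to the trait", {
  refs <- data.frame(id = c("a", "b", "c"),
                     true_cri = c(10, 20, 40), stringsAsFactors = FALSE)
  cfg <- spectra_config(bands = data.frame(trait = "cri", center = 5000,
                                           width = 100, amplitude = 0.01),
                        offset_sd = 0, slope_sd = 0, scatter_log_sd = 0,
                        noise_sd = 0, background_amplitude = 0,
                        batch_shift_sd = 0, seed = 1)
  s <- generate_nir_spectra(refs, cfg)
  expect_equal(s$absorbance[2, ], 2 * s$absorbance[1, ], tolerance = 1e-12)
  expect_equal(s$absorbance[3, ], 4 * s$absorbance[1, ], tolerance = 1e-12)
})

test_that("SNV cancels pure multiplicative scatter between equal-trait samples", {
  refs <- data.frame(id = c("a", "b"), true_cri = c(30, 30),
                     stringsAsFactors = FALSE)
  cfg <- spectra_config(bands = data.frame(trait = "cri", center = 5000,
                                           width = 100, amplitude = 0.01),
                        offset_sd = 0, slope_sd = 0, scatter_log_sd = 0.3,
                        noise_sd = 0, batch_shift_sd = 0, seed = 9)
  s <- generate_nir_spectra(refs, cfg)
  expect_gt(max(abs(s$absorbance[1, ] - s$absorbance[2, ])), 1e-6)
  z <- snv(s$absorbance)
  expect_lt(max(abs(z[1, ] - z[2, ])), 1e-10)
})

test_that("spectra generation validates bands and is deterministic", {
  refs <- generate_reference_traits(5, seed = 1)
  bad <- spectra_config(bands = data.frame(trait = "cri", center = 13000,
                                           width = 100, amplitude = 0.01))
  expect_error(generate_nir_spectra(refs, bad), "outside the wavenumber grid")
  cfg <- spectra_config(seed = 6)
  expect_identical(generate_nir_spectra(refs, cfg)$absorbance,
                   generate_nir_spectra(refs, cfg)$absorbance)
})

test_that("generated diffractograms close under the Segal computation", {
  for (target in c(25, 42.8, 55)) {
    cfg <- xrd_config(noise_sd = 0)
    d <- generate_xrd(target, cfg)
    res <- compute_cri(d)
    expect_lt(abs(res$cri - target), 0.1)
    # extrema located where the convention expects them
    expect_true(res$angle_200 > 21 && res$angle_200 < 24)
    expect_true(res$angle_am > 17 && res$angle_am < 20)
  }
  expect_error(generate_xrd(0), "between 0 and 100")
  expect_error(generate_xrd(120), "between 0 and 100")
  expect_error(generate_xrd(99.5), "exceeds the maximum achievable")
})

test_that("wet-chemistry generation inverts exactly at zero noise", {
  refs <- generate_reference_traits(30, seed = 21)
  wet <- generate_wetchem_raw(refs, seed = 2, a205_rel_sd = 0, mass_sd = 0)
  rec <- assay_reference_table(wet)
  expect_equal(rec$asl_dm, refs$true_asl_dm, tolerance = 1e-10)
  expect_equal(rec$ail_dm, refs$true_ail_dm, tolerance = 1e-10)
  expect_equal(rec$cw_frac, refs$true_cw_frac, tolerance = 1e-10)
  expect_equal(rec$total_cw, refs$true_total_cw, tolerance = 1e-10)
})

test_that("noisy wet-chemistry recovery is unbiased at the simulation scale", {
  refs <- generate_reference_traits(200, seed = 22)
  wet <- generate_wetchem_raw(refs, seed = 23)
  rec <- assay_reference_table(wet)
  # mean-zero measurement noise: the mean recovery error shrinks as
  # 1/sqrt(n); assert within 3 standard errors of zero
  asl_noise_sd <- sd(rec$asl_dm - refs$true_asl_dm)
  expect_lt(abs(mean(rec$asl_dm - refs$true_asl_dm)),
            3 * asl_noise_sd / sqrt(200))
  ail_noise_sd <- sd(rec$ail_dm - refs$true_ail_dm)
  expect_lt(abs(mean(rec$ail_dm - refs$true_ail_dm)),
            3 * ail_noise_sd / sqrt(200))
})
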
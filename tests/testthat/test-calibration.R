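# PCA / GH screening and NIPALS PLS against independent oracles.

test_that("PCA retains the smallest component count reaching the variance target", {
  set.seed(41)
  scores3 <- matrix(rnorm(60 * 3), 60, 3) %*% diag(c(5, 2, 1))
  load3 <- qr.Q(qr(matrix(rnorm(30 * 3), 30, 3)))
  X <- scores3 %*% t(load3)
  p <- fit_pca(X, var_threshold = 0.99)
  expect_equal(p$k, 3)
  expect_equal(fit_pca(X, var_threshold = 0)$k, 1)
  # Eckart-Young: k-component reconstruction error equals discarded variance
  p2 <- fit_pca(X + rnorm(60 * 30, 0, 0.1), var_threshold = 0.95, k_max = 5)
  expect_true(all(diff(p2$var_frac) < 1e-12))
  expect_lte(sum(p2$var_frac), 1 + 1e-12)
  expect_lt(max(abs(colMeans(p2$scores))), 1e-10)
})

test_that("GH equals covariance-inverse Mahalanobis distance over k", {
  set.seed(42)
  X <- matrix(rnorm(30 * 5), 30, 5) %*% diag(c(3, 2, 1.5, 1, 0.5))
  p <- fit_pca(X, var_threshold = 1, k_max = 5)
  expect_equal(p$k, 5)
  gh <- gh_distances(p)
  oracle <- mahalanobis(X, colMeans(X), cov(X)) / 5
  expect_lt(max(abs(gh - oracle)), 1e-8)
  expect_equal(mean(gh), (30 - 1) / 30, tolerance = 1e-10)
  # sample at the centroid scores zero
  Xc <- rbind(X, colMeans(X))
  pc <- fit_pca(Xc, var_threshold = 1, k_max = 5)
  expect_lt(gh_distances(pc)[31], 0.05)
})

test_that("GH screening removes planted outliers and only them", {
  s <- generate_nir_spectra(generate_reference_traits(60, seed = 51),
                            spectra_config(seed = 52))
  spiked <- s$absorbance
  spiked[7, ] <- spiked[7, ] + 10 * apply(s$absorbance, 2, sd)
  s2 <- spectrum_set(s$grid, spiked, s$ids, s$meta)
  el <- eliminate_outliers(s2, threshold = 3)
  expect_true(el$report$removed[7])
  expect_false(s$ids[7] %in% el$set$ids)
  # threshold Inf is the identity
  el_inf <- eliminate_outliers(s2, threshold = Inf)
  expect_equal(el_inf$set$ids, s2$ids)
  # deterministic
  el2 <- eliminate_outliers(s2, threshold = 3)
  expect_identical(el$report, el2$report)
})

test_that("NIPALS PLS matches least-squares oracles", {
  # univariate X at rank 1 is the simple regression line
  X <- matrix(c(1, 2, 3), ncol = 1)
  m <- fit_pls(X, c(2, 4, 6), 1)
  expect_equal(m$coef, 2, tolerance = 1e-12)
  expect_equal(m$intercept, 0, tolerance = 1e-12)
  expect_equal(m$fitted, c(2, 4, 6), tolerance = 1e-12)
  # full rank equals multiple OLS on 50 random small instances
  set.seed(43)
  for (i in 1:50) {
    n <- sample(8:15, 1); p <- sample(2:5, 1)
    Xi <- matrix(rnorm(n * p), n, p)
    yi <- rnorm(n)
    mi <- fit_pls(Xi, yi, p)
    ols <- unname(fitted(lm(yi ~ Xi)))
    expect_lt(max(abs(mi$fitted - ols)), 1e-8)
  }
})

test_that("PLS internal structure is consistent", {
  set.seed(44)
  X <- matrix(rnorm(40 * 20), 40, 20)
  y <- X[, 1] - 2 * X[, 5] + rnorm(40, 0, 0.1)
  m <- fit_pls(X, y, 6)
  # collapsed coefficients equal the latent-variable route
  R <- m$W %*% solve(crossprod(m$P, m$W))
  Tm <- sweep(X, 2, m$x_mean) %*% R
  latent <- m$y_mean + as.numeric(Tm %*% m$q)
  expect_lt(max(abs(latent - m$fitted)), 1e-10)
  # the mean training spectrum predicts the training mean response
  expect_equal(predict(m, matrix(m$x_mean, 1)), mean(y), tolerance = 1e-10)
  # RMSEC is non-increasing in rank
  rmsec <- vapply(1:8, function(a)
    sqrt(mean((fit_pls(X, y, a)$fitted - y)^2)), numeric(1))
  expect_true(all(diff(rmsec) < 1e-12))
  expect_error(fit_pls(X, rep(1, 40), 2), "zero-variance")
  expect_error(fit_pls(X, y, 40), "exceeds")
})

test_that("rank selection minimises RMSECV with parsimony ties", {
  set.seed(45)
  # noiseless 2-latent-factor data: tiny RMSECV at small rank
  Tm <- matrix(rnorm(60 * 2), 60, 2)
  X <- Tm %*% matrix(rnorm(2 * 25), 2, 25)
  y <- Tm %*% c(1, -2)
  # components beyond the true rank have no covariance left to extract:
  # NIPALS truncates with a warning
  expect_warning(fit_pls(X, y, 8), "rank truncated")
  r <- suppressWarnings(select_rank(X, y, rank_max = 8, cv = cv_spec(10, 7)))
  expect_lte(r, 4)
  expect_lt(attr(r, "rmsecv")[r], 1e-6)
  expect_equal(as.integer(select_rank(X, y, rank_max = 1, cv = cv_spec(5, 7))), 1L)
  # pure-noise response: no rank helps, RMSECV stays near sd(y)
  y0 <- rnorm(60)
  r0 <- suppressWarnings(select_rank(X, y0, rank_max = 8, cv = cv_spec(10, 7)))
  expect_gt(min(attr(r0, "rmsecv")), 0.8 * sd(y0))
})

test_that("fitted calibration models predict consistently", {
  refs <- generate_reference_traits(50, seed = 61)
  s <- generate_nir_spectra(refs, spectra_config(seed = 62))
  m <- fit_calibration(s, refs$cri, pretreatment_spec("SNV"),
                       region_set(c(4000, 9000)), rank = 4, trait = "cri")
  # training-set predictions reproduce the stored fitted values
  pr <- predict(m, s[m$training_ids])
  expect_lt(max(abs(unname(pr) - m$pls$fitted)), 1e-10)
  # invariant to an extra unused wavenumber column
  g2 <- c(s$grid, 12004)
  s2 <- spectrum_set(g2, cbind(s$absorbance, 1), s$ids, s$meta)
  expect_equal(unname(predict(m, s2)), unname(predict(m, s)), tolerance = 1e-10)
  # grid missing model wavenumbers is rejected
  s3 <- spectrum_set(s$grid[-500], s$absorbance[, -500], s$ids, s$meta)
  expect_error(predict(m, s3), "missing model wavenumbers")
})
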
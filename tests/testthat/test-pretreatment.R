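# Algebraic behaviour of the ten pretreatments and region selection.

test_that("COE shifts the minimum to exactly zero and is idempotent", {
  expect_equal(coe(c(3, 4, 5)), c(0, 1, 2))
  expect_equal(coe(c(2, 2, 2)), c(0, 0, 0))
  r <- random_rows(5, 40, 1)
  expect_equal(coe(coe(r)), coe(r))
  expect_equal(unname(apply(coe(r), 1, min)), rep(0, 5))
})

test_that("SSL removes exactly the affine trend", {
  grid <- seq(4000, 4396, 4)
  lin <- 2 + 0.003 * grid
  expect_lt(max(abs(ssl(lin, grid))), 1e-10)
  # projection property: adding a + b*nu to any row leaves output unchanged
  r <- random_rows(6, length(grid), 2)
  shifted <- r + matrix(rep(5 - 0.01 * grid, 6), 6, byrow = TRUE)
  expect_equal(ssl(shifted, grid), ssl(r, grid), tolerance = 1e-8)
  # output orthogonal to {1, grid}
  out <- ssl(r, grid)
  expect_lt(max(abs(rowSums(out))), 1e-7)
  expect_lt(max(abs(out %*% (grid - mean(grid)))) / max(abs(grid)), 1e-7)
  # quadratic on a symmetric grid keeps mean zero
  g2 <- seq(-10, 10, 1)
  expect_lt(abs(mean(ssl(g2^2, g2))), 1e-10)
  expect_error(ssl(c(1, 2, 3), c(5, 5, 5)), "degenerate")
})

test_that("SNV standardises rows and is invariant to positive affine maps", {
  expect_equal(snv(c(1, 2, 3)), c(-1, 0, 1))
  r <- random_rows(100, 50, 3)
  z <- snv(r)
  expect_lt(max(abs(rowMeans(z))), 1e-12)
  expect_equal(unname(apply(z, 1, sd)), rep(1, 100))
  a <- runif(100, 0.5, 3); b <- rnorm(100)
  expect_lt(max(abs(snv(r * a + b) - z)), 1e-8)
  expect_equal(snv(-2 * c(1, 2, 3) + 1), c(1, 0, -1))
  expect_error(snv(c(2, 2, 2)), "constant")
})

test_that("MMN rescales to [0, 2] and is affine invariant", {
  expect_equal(mmn(c(2, 4, 6)), c(0, 1, 2))
  r <- random_rows(100, 50, 4)
  z <- mmn(r)
  expect_equal(unname(apply(z, 1, min)), rep(0, 100))
  expect_equal(unname(apply(z, 1, max)), rep(2, 100))
  a <- runif(100, 0.5, 3); b <- rnorm(100)
  expect_lt(max(abs(mmn(r * a + b) - z)), 1e-8)
  expect_equal(mmn(z), z, tolerance = 1e-12)
  expect_error(mmn(rep(1, 5)), "constant")
})

test_that("MSC removes offset and gain relative to the reference", {
  ref <- 0.5 + 0.2 * sin(seq(0, 3, length.out = 80))
  x <- 2 * ref + 1
  expect_equal(as.numeric(msc(x, ref)), ref, tolerance = 1e-10)
  expect_equal(as.numeric(msc(ref, ref)), ref, tolerance = 1e-12)
  # projection: corrected rows regress on the reference with a=0, b=1
  r <- random_rows(20, 80, 5) + matrix(rep(ref, 20), 20, byrow = TRUE)
  out <- msc(r, ref)
  for (i in c(1, 7, 20)) {
    fit <- lm(out[i, ] ~ ref)
    expect_lt(abs(coef(fit)[1]), 1e-8)
    expect_equal(unname(coef(fit)[2]), 1, tolerance = 1e-8)
  }
})

test_that("Savitzky-Golay derivatives have correct units and edge cropping", {
  grid <- seq(4000, 4796, 4)
  b <- 0.003
  fd <- sg_derivative(2 + b * grid, grid, order = 1)
  expect_lt(max(abs(fd - b)), 1e-8)
  expect_equal(length(attr(fd, "grid")), length(grid) - 16)
  sed <- sg_derivative((grid - 4400)^2, grid, order = 2)
  expect_lt(max(abs(sed - 2)), 1e-6)
  expect_lt(max(abs(sg_derivative(rep(1, length(grid)), grid, order = 1))), 1e-12)
  expect_error(sg_derivative(1:10, c(1:9, 11), order = 1, window = 5),
               "non-uniform")
  expect_error(sg_derivative(1:20, 1:20, order = 1, window = 6), "odd")
})

test_that("apply_pretreatment composes, fits, and never mutates its input", {
  s <- tiny_set()
  orig <- s$absorbance
  out_none <- apply_pretreatment(pretreatment_spec("NONE"), s)
  expect_equal(out_none$absorbance, s$absorbance)
  out <- apply_pretreatment(pretreatment_spec("FD+SNV"), s)
  d <- sg_derivative(s$absorbance, s$grid, order = 1)
  manual <- snv(as.matrix(d))
  expect_equal(unname(out$absorbance), unname(manual), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(out$grid, attr(d, "grid"))
  expect_identical(s$absorbance, orig)
  # calibration fit then apply-only on the same data is identical (MSC)
  spec <- pretreatment_spec("FD+MSC")
  cal <- apply_pretreatment(spec, s, mode = "calibration")
  fitted_spec <- attr(cal, "pretreatment")
  expect_false(is.null(fitted_spec$msc_reference))
  rep2 <- apply_pretreatment(fitted_spec, s, mode = "apply-only")
  expect_equal(rep2$absorbance, cal$absorbance, tolerance = 1e-12)
  expect_error(apply_pretreatment(pretreatment_spec("MSC"), s, "apply-only"),
               "calibration set")
})

test_that("region selection retains exactly the in-interval columns", {
  grid <- seq(4000, 12000, 4)
  s <- spectrum_set(grid, matrix(seq_along(grid), 1), "a")
  full <- select_regions(s, region_set(c(4000, 12000)))
  expect_equal(full$grid, grid)
  # table-style region string: counting oracle on the default grid
  r <- parse_regions("11,964.8 - 11,178; 8825.1 - 7243.7; 6464.5 - 4104")
  sel <- select_regions(s, r)
  expected <- sum(grid >= 11178 & grid <= 11964.8) +
    sum(grid >= 7243.7 & grid <= 8825.1) + sum(grid >= 4104 & grid <= 6464.5)
  expect_equal(length(sel$grid), expected)
  # disjoint blocks concatenate without duplicates
  r2 <- region_set(c(4000, 5000), c(7000, 8000))
  sel2 <- select_regions(s, r2)
  expect_false(anyDuplicated(sel2$grid) > 0)
  expect_true(all(diff(sel2$grid) > 0))
  expect_error(select_regions(s, region_set(c(1000, 2000))), "no grid points")
})

test_that("interval blocks tile the grid span", {
  grid <- seq(4000, 12000, 4)
  one <- make_intervals(grid, 1)
  expect_equal(one[[1]], c(4000, 12000))
  ten <- make_intervals(grid, 10)
  expect_equal(vapply(ten, diff, numeric(1)), rep(800, 10))
  expect_equal(ten[[1]][1], 4000)
  expect_equal(ten[[10]][2], 12000)
  # consecutive blocks share endpoints: union covers the span
  expect_equal(vapply(ten[-1], `[`, numeric(1), 1),
               vapply(ten[-10], `[`, numeric(1), 2))
  expect_error(make_intervals(1:5, 6), "more intervals")
  # candidate enumeration: all subsets of 4 blocks is 15
  cand <- region_candidates(make_intervals(grid, 4), cap = 15)
  expect_length(cand, 15)
  expect_equal(format_regions(cand[[15]]), "12000 - 4000")
})

test_that("region parsing tolerates table formatting", {
  r <- parse_regions("11,964.8 - 11,178")
  expect_equal(unclass(r)[1, ], c(lo = 11178, hi = 11964.8))
  expect_error(parse_regions("4000 -"), "two endpoints")
  # overlapping intervals merge
  rr <- region_set(c(4000, 6000), c(5000, 7000))
  expect_equal(nrow(rr), 1)
  expect_equal(unclass(rr)[1, ], c(lo = 4000, hi = 7000))
})
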
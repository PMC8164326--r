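# Spectra / reference IO, replicate averaging, model serialization.

test_that("wide CSV spectra roundtrip exactly and canonicalise the grid", {
  s <- tiny_set()
  f <- withr::local_tempfile(fileext = ".csv")
  write_spectra(s, f, "wide_csv")
  s2 <- read_spectra(f, "wide_csv")
  expect_equal(s2$grid, s$grid)
  expect_equal(unname(s2$absorbance), unname(s$absorbance), tolerance = 1e-14)
  expect_equal(s2$ids, s$ids)
  # descending grid on disk comes back ascending with values permuted
  lines <- readLines(f)
  header <- strsplit(lines[1], ",")[[1]]
  rev_lines <- vapply(lines, function(l) {
    v <- strsplit(l, ",")[[1]]
    paste(c(v[1], rev(v[-1])), collapse = ",")
  }, character(1))
  writeLines(rev_lines, f)
  s3 <- read_spectra(f, "wide_csv")
  expect_equal(s3$grid, s$grid)
  expect_equal(unname(s3$absorbance), unname(s$absorbance), tolerance = 1e-14)
})

test_that("malformed wide CSVs are rejected with the offending location", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,4000,4004,4000", "a,1,2,3"), f)
  expect_error(read_spectra(f, "wide_csv"), "duplicated wavenumber.*4000")
  writeLines(c("id,4000,4004", "a,1,2", "b,1"), f)
  expect_error(read_spectra(f, "wide_csv"), "ragged row 3")
  writeLines(c("id,4000,4004", "a,1,oops"), f)
  expect_error(read_spectra(f, "wide_csv"), "non-numeric cell at row 2, column 3")
})

test_that("per-sample XY dialect roundtrips and ignores ## headers", {
  s <- tiny_set(n = 3)
  d <- withr::local_tempdir()
  write_spectra(s, d, "per_sample_xy")
  s2 <- read_spectra(d, "per_sample_xy")
  expect_equal(s2$grid, s$grid)
  expect_equal(unname(s2$absorbance), unname(s$absorbance), tolerance = 1e-14)
  expect_setequal(s2$ids, s$ids)
})

test_that("replicate averaging is the pointwise mean on absorbance", {
  grid <- seq(4000, 4040, 4)
  m <- rbind(rep(0, 11), rep(2, 11), rep(1, 11))
  s <- spectrum_set(grid, m, c("x", "x", "y"),
                    meta = data.frame(replicate = c(1L, 2L, 1L)))
  avg <- average_replicates(s, groups = c("x", "x", "y"))
  expect_equal(nrow(avg$absorbance), 2)
  expect_equal(unname(avg$absorbance[1, ]), rep(1, 11))
  expect_equal(avg$meta$n_averaged, c(2L, 1L))
  # the replicate index is no longer meaningful after averaging
  expect_true(all(avg$meta$replicate == 1L))
  # three identical spectra average to themselves
  s3 <- spectrum_set(grid, rbind(m[3, ], m[3, ], m[3, ]), c("a", "a", "a"),
                     meta = data.frame(replicate = 1:3))
  expect_equal(unname(average_replicates(s3)$absorbance[1, ]), unname(m[3, ]))
})

test_that("reflectance converts to log10(1/R) absorbance", {
  expect_equal(reflectance_to_absorbance(0.1), 1.0)
  expect_equal(reflectance_to_absorbance(1.0), 0.0)
  expect_equal(reflectance_to_absorbance(0.01), 2.0)
  expect_error(reflectance_to_absorbance(c(0.5, 0)), "positive")
})

test_that("model serialization roundtrips to identical predictions", {
  refs <- generate_reference_traits(40, seed = 31)
  s <- generate_nir_spectra(refs, spectra_config(seed = 32))
  reg <- region_set(c(4000, 6000), c(7000, 9000), c(10000, 12000))
  m <- fit_calibration(s, refs$cri, pretreatment_spec("FD+MSC"), reg,
                       rank = 3, trait = "cri")
  f <- withr::local_tempfile(fileext = ".json")
  save_model(m, f)
  m2 <- load_model(f)
  expect_lt(max(abs(predict(m, s) - predict(m2, s))), 1e-12)
  expect_equal(unclass(m2$regions), unclass(m$regions), ignore_attr = TRUE)
  expect_equal(m2$pretreatment$msc_reference, m$pretreatment$msc_reference,
               tolerance = 1e-15)
  # truncated file: error, not a partial model
  txt <- readLines(f)
  writeLines(substr(paste(txt, collapse = ""), 1, 200), f)
  expect_error(load_model(f), "truncated|parse")
  # foreign format version
  writeLines(jsonlite::toJSON(list(format = "other/9"), auto_unbox = TRUE), f)
  expect_error(load_model(f), "version mismatch")
})

test_that("reference tables validate their arithmetic on read", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,asl_dm,ail_dm,total_dm", "a,1.5,14.0,15.5", "b,2.0,10.0,12.0"), f)
  refs <- read_reference_table(f)
  expect_equal(nrow(refs), 2)
  writeLines(c("id,asl_dm,ail_dm,total_dm", "a,1.5,14.0,17.5"), f)
  expect_error(read_reference_table(f), "total lignin")
  writeLines(c("id,asl_dm", "a,-1"), f)
  expect_error(read_reference_table(f), "negative")
})

test_that("generator configs roundtrip through YAML", {
  d <- withr::local_tempdir()
  for (cfg in list(trait_config(), spectra_config(seed = 5), xrd_config(),
                   pipeline_config())) {
    f <- file.path(d, "cfg.yaml")
    write_config(cfg, f)
    cfg2 <- read_config(f)
    expect_equal(class(cfg2), class(cfg))
    if (inherits(cfg, "trait_config")) {
      expect_equal(cfg2$traits, cfg$traits)
      expect_equal(unname(cfg2$correlation), unname(cfg$correlation))
    } else {
      expect_equal(unclass(cfg2), unclass(cfg))
    }
  }
})
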
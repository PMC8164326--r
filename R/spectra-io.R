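# Reading and writing spectra, reference tables, fitted models and
# generator configurations.

#' Read spectra from disk
#'
#' Two dialects:
#' * `wide_csv`: one CSV file; first column `id`, remaining column
#'   headers are numeric wavenumbers, one row per spectrum.
#' * `per_sample_xy`: a directory of two-column text files (wavenumber,
#'   absorbance; comma- or whitespace-separated), one per sample, the
#'   file stem being the sample id. Header/comment lines prefixed `##`
#'   (JCAMP-DX style) are ignored.
#'
#' The grid is sorted ascending regardless of input order, with the
#' values permuted consistently. Ragged rows, duplicated wavenumbers and
#' non-numeric cells are rejected with the offending location.
#'
#' @param path File (wide_csv) or directory (per_sample_xy).
#' @param dialect `"wide_csv"` or `"per_sample_xy"`.
#' @return A [spectrum_set()].
#' @export
read_spectra <- function(path, dialect = c("wide_csv", "per_sample_xy")) {
  dialect <- match.arg(dialect)
  if (dialect == "wide_csv") read_spectra_wide(path) else read_spectra_xy(path)
}

read_spectra_wide <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (length(lines) < 2) stop("wide CSV needs a header and at least one spectrum")
  cells <- strsplit(lines, ",", fixed = TRUE)
  header <- cells[[1]]
  p <- length(header) - 1
  wn <- suppressWarnings(as.numeric(header[-1]))
  if (anyNA(wn))
    stop("non-numeric wavenumber header in column(s): ",
         paste(which(is.na(wn)) + 1, collapse = ", "))
  dup <- wn[duplicated(wn)]
  if (length(dup) > 0)
    stop("duplicated wavenumber column(s): ", paste(unique(dup), collapse = ", "))
  n <- length(lines) - 1
  m <- matrix(NA_real_, n, p)
  ids <- character(n)
  for (i in seq_len(n)) {
    row <- cells[[i + 1]]
    if (length(row) != p + 1)
      stop("ragged row ", i + 1, ": expected ", p + 1, " cells, found ", length(row))
    ids[i] <- row[1]
    v <- suppressWarnings(as.numeric(row[-1]))
    if (anyNA(v))
      stop("non-numeric cell at row ", i + 1, ", column ",
           which(is.na(v))[1] + 1)
    m[i, ] <- v
  }
  spectrum_set(wn, m, ids)
}

read_spectra_xy <- function(path) {
  if (!dir.exists(path)) stop("directory not found: ", path)
  files <- sort(list.files(path, full.names = TRUE))
  files <- files[!dir.exists(files)]
  if (length(files) == 0) stop("no spectra files in ", path)
  one <- function(f) {
    lines <- readLines(f)
    lines <- lines[!startsWith(lines, "##")]
    lines <- lines[nzchar(trimws(lines))]
    parts <- strsplit(trimws(lines), "[,[:space:]]+")
    bad <- which(lengths(parts) != 2)
    if (length(bad) > 0)
      stop("file ", basename(f), ": expected two columns at data line ", bad[1])
    v <- suppressWarnings(vapply(parts, as.numeric, numeric(2)))
    if (anyNA(v))
      stop("file ", basename(f), ": non-numeric value at data line ",
           which(apply(is.na(v), 2, any))[1])
    list(wn = v[1, ], val = v[2, ])
  }
  first <- one(files[1])
  o <- order(first$wn)
  wn <- first$wn[o]
  if (anyDuplicated(wn))
    stop("file ", basename(files[1]), ": duplicated wavenumber ",
         wn[duplicated(wn)][1])
  m <- matrix(NA_real_, length(files), length(wn))
  m[1, ] <- first$val[o]
  if (length(files) > 1) for (i in 2:length(files)) {
    xi <- one(files[i])
    oi <- order(xi$wn)
    if (length(xi$wn) != length(wn) || max(abs(xi$wn[oi] - wn)) > 1e-9)
      stop("file ", basename(files[i]), ": grid differs from ", basename(files[1]))
    m[i, ] <- xi$val[oi]
  }
  ids <- sub("\\.[^.]*$", "", basename(files))
  spectrum_set(wn, m, ids)
}

#' Write spectra to disk
#'
#' @param s A [spectrum_set()].
#' @param path Output file (wide_csv) or directory (per_sample_xy).
#' @param dialect `"wide_csv"` or `"per_sample_xy"`.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(s, path, dialect = c("wide_csv", "per_sample_xy")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(s, "spectrum_set"))
  if (dialect == "wide_csv") {
    header <- paste(c("id", format(s$grid, trim = TRUE, digits = 15)),
                    collapse = ",")
    rows <- vapply(seq_along(s$ids), function(i)
      paste(c(s$ids[i], format(s$absorbance[i, ], trim = TRUE, digits = 17)),
            collapse = ","), character(1))
    writeLines(c(header, rows), path)
  } else {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    for (i in seq_along(s$ids)) {
      f <- file.path(path, paste0(s$ids[i], ".xy"))
      writeLines(c("## TITLE= simulated NIR spectrum",
                   paste0("## SAMPLE= ", s$ids[i]),
                   paste(format(s$grid, trim = TRUE, digits = 15),
                         format(s$absorbance[i, ], trim = TRUE, digits = 17))),
                 f)
    }
  }
  invisible(path)
}

#' Read / write a reference trait table CSV
#'
#' Fixed column names: `id` plus any of `cri`, `asl_dm`, `ail_dm`,
#' `total_dm`, `asl_cw`, `ail_cw`, `total_cw` (additional columns such
#' as `true_*` pass through). The table is validated on read.
#'
#' @param path CSV path.
#' @return A reference table data.frame.
#' @export
read_reference_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  refs <- utils::read.csv(path, stringsAsFactors = FALSE)
  refs$id <- as.character(refs$id)
  validate_reference_table(refs)
  refs
}

#' @rdname read_reference_table
#' @param refs Reference table to write.
#' @export
write_reference_table <- function(refs, path) {
  validate_reference_table(refs)
  utils::write.csv(refs, path, row.names = FALSE)
  invisible(path)
}

#' Average replicate spectra
#'
#' Pointwise arithmetic mean of the recorded absorbance (log 1/R) over
#' each replicate group, matching the manual averaging of the three
#' offline replicate scans. All replicates must share one grid (they do
#' within a `spectrum_set`). The replicate index is dropped; the number
#' of averaged spectra is recorded in `meta$n_averaged`.
#'
#' @param s A [spectrum_set()].
#' @param groups Grouping: a vector with one label per spectrum, the
#'   name of a `meta` column, or `NULL` to group by sample id.
#' @return A `spectrum_set` with one spectrum per group.
#' @export
average_replicates <- function(s, groups = NULL) {
  stopifnot(inherits(s, "spectrum_set"))
  if (is.null(groups)) groups <- s$ids
  else if (length(groups) == 1 && is.character(groups) &&
           groups %in% names(s$meta)) groups <- s$meta[[groups]]
  if (length(groups) != length(s$ids))
    stop("groups length does not match number of spectra")
  groups <- as.character(groups)
  u <- unique(groups)
  m <- matrix(NA_real_, length(u), length(s$grid))
  counts <- integer(length(u))
  for (i in seq_along(u)) {
    idx <- which(groups == u[i])
    counts[i] <- length(idx)
    m[i, ] <- colMeans(s$absorbance[idx, , drop = FALSE])
  }
  first <- match(u, groups)
  meta <- s$meta[first, setdiff(names(s$meta), "replicate"), drop = FALSE]
  meta$n_averaged <- counts
  rownames(meta) <- NULL
  spectrum_set(s$grid, m, u, meta)
}

#' Convert reflectance to absorbance
#'
#' NIR absorbance is recorded as `log10(1/R)` where `R` is the sample
#' reflectance, `0 < R <= 1`.
#'
#' @param R Reflectance vector or matrix.
#' @return `log10(1/R)`, same shape.
#' @export
reflectance_to_absorbance <- function(R) {
  if (any(R <= 0)) stop("reflectance must be positive")
  if (any(R > 1)) warning("reflectance values > 1 give negative absorbance")
  log10(1 / R)
}

# ---- model serialization ---------------------------------------------

MODEL_FORMAT <- "nirscane_model/1"

#' Save / load a fitted calibration model
#'
#' Self-describing JSON text container with an explicit format version.
#' A reloaded model predicts identically to the original (full-precision
#' serialization); truncated or foreign files raise an error rather than
#' yielding a partial model.
#'
#' @param m A `calibration_model` from [fit_calibration()].
#' @param path Output path.
#' @return `save_model`: `path`, invisibly. `load_model`: the model.
#' @export
save_model <- function(m, path) {
  stopifnot(inherits(m, "calibration_model"))
  payload <- list(
    format = MODEL_FORMAT,
    trait = m$trait,
    gh_threshold = m$gh_threshold,
    pretreatment = list(method = m$pretreatment$method,
                        sg_window = m$pretreatment$sg_window,
                        sg_polyorder = m$pretreatment$sg_polyorder,
                        msc_reference = m$pretreatment$msc_reference,
                        msc_grid = m$pretreatment$msc_grid),
    regions = if (is.null(m$regions)) NULL else unclass(m$regions)[, , drop = FALSE],
    input_grid = m$input_grid,
    grid = m$grid,
    training_ids = m$training_ids,
    y_train = m$y_train,
    pls = list(rank = m$pls$rank, x_mean = m$pls$x_mean, y_mean = m$pls$y_mean,
               W = m$pls$W, P = m$pls$P, q = m$pls$q,
               coef = m$pls$coef, intercept = m$pls$intercept,
               fitted = m$pls$fitted))
  writeLines(jsonlite::toJSON(payload, digits = I(17), auto_unbox = TRUE,
                              null = "null"), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  payload <- tryCatch(jsonlite::fromJSON(readLines(path, warn = FALSE)),
                      error = function(e)
                        stop("cannot parse model file (truncated or not a model): ",
                             conditionMessage(e)))
  if (!identical(payload$format, MODEL_FORMAT))
    stop("model format version mismatch: found '", payload$format,
         "', expected '", MODEL_FORMAT, "'")
  spec <- pretreatment_spec(payload$pretreatment$method,
                            payload$pretreatment$sg_window,
                            payload$pretreatment$sg_polyorder)
  spec$msc_reference <- payload$pretreatment$msc_reference
  spec$msc_grid <- payload$pretreatment$msc_grid
  pls <- payload$pls
  structure(list(trait = payload$trait,
                 pretreatment = spec,
                 regions = if (is.null(payload$regions)) NULL else
                   region_set(matrix(payload$regions, ncol = 2)),
                 input_grid = payload$input_grid,
                 grid = payload$grid,
                 pls = structure(list(rank = pls$rank, x_mean = pls$x_mean,
                                      y_mean = pls$y_mean,
                                      W = matrix(pls$W, ncol = pls$rank),
                                      P = matrix(pls$P, ncol = pls$rank),
                                      q = pls$q, coef = pls$coef,
                                      intercept = pls$intercept,
                                      fitted = pls$fitted),
                                 class = "pls_fit"),
                 gh_threshold = payload$gh_threshold,
                 training_ids = payload$training_ids,
                 elimination = NULL,
                 y_train = payload$y_train),
            class = "calibration_model")
}

# ---- generator / pipeline configuration files ------------------------

#' Write / read a configuration as a flat YAML file
#'
#' Serialises [trait_config()], [spectra_config()], [xrd_config()] and
#' [pipeline_config()] objects (data-frame fields are stored as parallel
#' column vectors).
#'
#' @param cfg A configuration object.
#' @param path YAML path.
#' @return `write_config`: `path`, invisibly. `read_config`: the
#'   reconstructed configuration object.
#' @export
write_config <- function(cfg, path) {
  type <- class(cfg)[1]
  flat <- lapply(unclass(cfg), function(v)
    if (is.data.frame(v)) lapply(as.list(v), I) else v)
  yaml::write_yaml(c(list(config_type = type), flat), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- yaml::read_yaml(path)
  type <- raw$config_type
  raw$config_type <- NULL
  rebuild_df <- function(x) as.data.frame(lapply(x, unlist),
                                          stringsAsFactors = FALSE)
  switch(type,
    trait_config = trait_config(
      traits = rebuild_df(raw$traits),
      correlation = matrix(unlist(raw$correlation),
                           nrow = length(raw$traits$trait))),
    spectra_config = do.call(spectra_config,
                             c(raw[setdiff(names(raw), "bands")],
                               list(bands = rebuild_df(raw$bands)))),
    xrd_config = do.call(xrd_config, raw),
    pipeline_config = do.call(pipeline_config, raw),
    stop("unknown config_type '", type, "'"))
}
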
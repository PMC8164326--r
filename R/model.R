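# Full calibration "equation": fitted pretreatment + region set + PLS core.

#' Fit a complete calibration equation
#'
#' Runs the full single-candidate pipeline on a calibration set:
#' pretreatment (fitting any data-dependent parameters such as the MSC
#' reference), wavelength-region selection, one-pass GH outlier
#' elimination, and a NIPALS PLS fit at the given rank.
#'
#' @param s Calibration [spectrum_set()].
#' @param y Reference values aligned with `s` (one per sample).
#' @param pretreatment A [pretreatment_spec()].
#' @param regions A [region_set()], or `NULL` for the full grid.
#' @param rank Number of PLS latent variables.
#' @param gh_threshold GH outlier cutoff (default 3; `Inf` disables).
#' @param trait Optional trait name recorded in the model.
#' @return An object of class `calibration_model`.
#' @export
fit_calibration <- function(s, y, pretreatment = pretreatment_spec("NONE"),
                            regions = NULL, rank, gh_threshold = 3.0,
                            trait = NA_character_) {
  stopifnot(inherits(s, "spectrum_set"))
  y <- as.numeric(y)
  if (length(y) != length(s$ids)) stop("y length does not match sample count")
  pre <- apply_pretreatment(pretreatment, s, mode = "calibration")
  fitted_spec <- attr(pre, "pretreatment")
  sel <- if (is.null(regions)) pre else select_regions(pre, regions)
  elim <- eliminate_outliers(sel, threshold = gh_threshold)
  keep <- match(elim$set$ids, s$ids)
  yk <- y[keep]
  pls <- fit_pls(elim$set$absorbance, yk, rank)
  structure(list(trait = trait,
                 pretreatment = fitted_spec,
                 regions = regions,
                 input_grid = s$grid,
                 grid = elim$set$grid,
                 pls = pls,
                 gh_threshold = gh_threshold,
                 training_ids = elim$set$ids,
                 elimination = elim$report,
                 y_train = yk),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat("<calibration_model> trait ", x$trait, ", SCM ",
      format_scm(x$pretreatment$method), ", rank ", x$pls$rank,
      ", N ", length(x$training_ids),
      if (!is.null(x$regions)) paste0(", regions ", format_regions(x$regions)),
      "\n", sep = "")
  invisible(x)
}

#' Predict trait values from spectra with a fitted calibration equation
#'
#' Applies the model's stored pretreatment (apply-only: the MSC
#' reference fitted on the calibration set is reused) and region
#' selection, then the collapsed PLS coefficients. The new spectra may be
#' on a larger grid: any grid containing the model's wavenumbers works;
#' extra columns are ignored.
#'
#' @param object A `calibration_model`.
#' @param newdata A [spectrum_set()].
#' @param ... Ignored.
#' @return Numeric vector of predictions, named by sample id.
#' @export
predict.calibration_model <- function(object, newdata, ...) {
  stopifnot(inherits(newdata, "spectrum_set"))
  # restrict to the calibration input grid first: row-wise transforms
  # (SNV, MMN, ...) must see exactly the columns they were fitted over
  gidx <- match(round(object$input_grid, 6), round(newdata$grid, 6))
  if (anyNA(gidx))
    stop("spectra grid is missing model wavenumbers: ",
         paste(utils::head(object$input_grid[is.na(gidx)], 5), collapse = ", "),
         if (sum(is.na(gidx)) > 5) " ...")
  newdata <- spectrum_set(object$input_grid,
                          newdata$absorbance[, gidx, drop = FALSE],
                          newdata$ids, newdata$meta)
  pre <- apply_pretreatment(object$pretreatment, newdata, mode = "apply-only")
  sel <- if (is.null(object$regions)) pre else select_regions(pre, object$regions)
  idx <- match(round(object$grid, 6), round(sel$grid, 6))
  if (anyNA(idx))
    stop("spectra grid is missing model wavenumbers: ",
         paste(utils::head(object$grid[is.na(idx)], 5), collapse = ", "),
         if (sum(is.na(idx)) > 5) " ...")
  X <- sel$absorbance[, idx, drop = FALSE]
  stats::setNames(predict(object$pls, X), newdata$ids)
}
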
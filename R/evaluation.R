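# Calibration / cross-validation / external-validation statistics,
# exhaustive model search, and model-comparison tests.

#' Cross-validation specification
#'
#' @param k Fold count (default 10).
#' @param seed Shuffle seed for the fold assignment.
#' @return An object of class `cv_spec`.
#' @export
cv_spec <- function(k = 10, seed = 1) {
  if (k < 2) stop("fold count k must be >= 2")
  structure(list(k = as.integer(k), seed = as.integer(seed)), class = "cv_spec")
}

#' Calibration fit statistics
#'
#' `R^2 = 1 - SSE/SST` and `RMSE = sqrt(SSE/n)` between reference values
#' and fitted/predicted values.
#'
#' @param y Reference values.
#' @param y_hat Fitted or predicted values.
#' @return List with `r2` and `rmse`.
#' @export
calib_stats <- function(y, y_hat) {
  y <- as.numeric(y); y_hat <- as.numeric(y_hat)
  if (length(y) != length(y_hat)) stop("y and y_hat lengths differ")
  if (length(y) < 3) stop("need at least 3 observations")
  sst <- sum((y - mean(y))^2)
  if (sst == 0) stop("zero variance in reference values")
  sse <- sum((y - y_hat)^2)
  list(r2 = 1 - sse / sst, rmse = sqrt(sse / length(y)))
}

#' Split sample ids into calibration and external-validation sets
#'
#' Uniform random, seeded, disjoint and exhaustive.
#'
#' @param ids Vector of sample ids.
#' @param n_val Number of validation samples (`0 < n_val < length(ids)`).
#' @param seed Integer seed.
#' @return List with `cal` and `val` id vectors.
#' @export
split_calibration_validation <- function(ids, n_val, seed) {
  n <- length(ids)
  if (n_val <= 0) stop("n_val must be positive")
  if (n_val >= n) stop("n_val must be smaller than the number of samples")
  perm <- sample_with_seed(n, seed)
  val <- sort(perm[seq_len(n_val)])
  list(cal = ids[-val], val = ids[val])
}

#' Cross-validate a calibration candidate
#'
#' Full-pipeline internal cross-validation: the samples are partitioned
#' into seeded folds and, inside each training fold, the pretreatment is
#' refit (including the MSC reference), regions are selected and the PLS
#' model is fit; held-out samples are predicted with that fold's
#' pipeline. Out-of-fold predictions are assembled once per sample and
#' the statistics computed on the assembled vector.
#' `RPD = SD(y) / RMSECV`.
#'
#' Samples should already have passed GH screening (elimination is
#' applied once per candidate, before the folds).
#'
#' @param s A [spectrum_set()] (raw spectra).
#' @param y Reference values aligned with `s`.
#' @param pretreatment A [pretreatment_spec()].
#' @param regions A [region_set()] or `NULL`.
#' @param rank Rank at which to report statistics; if `NULL`, the rank
#'   minimising RMSECV (up to `rank_max`) is chosen (ties toward the
#'   smaller rank).
#' @param rank_max Maximum rank swept when `rank` is `NULL`.
#' @param cv A [cv_spec()].
#' @param pre_sel Optional precomputed pretreated and region-selected
#'   [spectrum_set()] for `s` (an optimisation for sample-wise
#'   pretreatments, where per-fold refitting is an identity; ignored for
#'   MSC-containing specs, which are always refit per fold).
#' @return List with `r2cv`, `rmsecv`, `rpd`, `rank`, `rmsecv_path`
#'   (per-rank RMSECV) and `preds` (assembled out-of-fold predictions).
#' @export
cross_validate <- function(s, y, pretreatment = pretreatment_spec("NONE"),
                           regions = NULL, rank = NULL, rank_max = 10,
                           cv = cv_spec(), pre_sel = NULL) {
  stopifnot(inherits(s, "spectrum_set"))
  y <- as.numeric(y)
  n <- length(s$ids)
  if (length(y) != n) stop("y length does not match sample count")
  folds <- cv_folds(n, cv)
  sweep_to <- if (is.null(rank)) rank_max else rank
  if (min(n - lengths(folds)) < sweep_to + 1)
    stop("a fold leaves fewer than rank + 1 training samples")
  uses_msc <- grepl("MSC", pretreatment$method, fixed = TRUE)
  if (!uses_msc) {
    # every non-MSC pretreatment is a per-spectrum transform with no
    # fitted parameters, so refitting it inside each training fold is
    # an identity: pretreat once and cross-validate the plain matrix
    if (is.null(pre_sel)) {
      pre_sel <- apply_pretreatment(pretreatment, s, mode = "calibration")
      if (!is.null(regions)) pre_sel <- select_regions(pre_sel, regions)
    }
    sw <- cv_rank_sweep(pre_sel$absorbance, y, sweep_to, cv)
    preds <- sw$preds
  } else {
    preds <- matrix(NA_real_, n, sweep_to)
    for (f in folds) {
      tr <- setdiff(seq_len(n), f)
      pre_tr <- apply_pretreatment(pretreatment, s[tr], mode = "calibration")
      spec_f <- attr(pre_tr, "pretreatment")
      sel_tr <- if (is.null(regions)) pre_tr else select_regions(pre_tr, regions)
      r_f <- min(sweep_to, length(tr) - 1, ncol(sel_tr$absorbance))
      m <- fit_pls(sel_tr$absorbance, y[tr], r_f)
      path <- pls_coef_path(m)
      pre_te <- apply_pretreatment(spec_f, s[f], mode = "apply-only")
      sel_te <- if (is.null(regions)) pre_te else select_regions(pre_te, regions)
      pf <- sweep(sel_te$absorbance %*% path$coef, 2, path$intercept, "+")
      if (m$rank < sweep_to)
        pf <- cbind(pf, matrix(pf[, m$rank], length(f), sweep_to - m$rank))
      preds[f, ] <- pf
    }
  }
  rmsecv_path <- sqrt(colMeans((preds - y)^2))
  chosen <- if (is.null(rank)) which.min(round(rmsecv_path, 12)) else rank
  st <- calib_stats(y, preds[, chosen])
  list(r2cv = st$r2, rmsecv = st$rmse, rpd = stats::sd(y) / st$rmse,
       rank = as.integer(chosen), rmsecv_path = rmsecv_path,
       preds = preds[, chosen])
}

#' External validation of a fitted calibration equation
#'
#' Predicts an independent validation set and reports `R^2ev`, `RMSEP`
#' and `RPD = SD(y_val)/RMSEP`. Validation ids must be disjoint from the
#' model's training ids.
#'
#' @param m A `calibration_model`.
#' @param s_val Validation [spectrum_set()].
#' @param y_val Reference values aligned with `s_val`.
#' @return List with `r2ev`, `rmsep`, `rpd`, `n` and `preds`.
#' @export
external_validate <- function(m, s_val, y_val) {
  stopifnot(inherits(m, "calibration_model"), inherits(s_val, "spectrum_set"))
  overlap <- intersect(s_val$ids, m$training_ids)
  if (length(overlap) > 0)
    stop("validation ids overlap the training set: ",
         paste(utils::head(overlap, 5), collapse = ", "))
  y_val <- as.numeric(y_val)
  preds <- predict(m, s_val)
  st <- calib_stats(y_val, preds)
  if (st$rmse == 0) stop("RMSEP is zero; RPD undefined")
  list(r2ev = st$r2, rmsep = st$rmse, rpd = stats::sd(y_val) / st$rmse,
       n = length(y_val), preds = preds)
}

#' Evaluate one (pretreatment x region) calibration candidate
#'
#' The per-candidate pipeline of the model search: pretreat and
#' region-select the calibration spectra, screen GH outliers once, sweep
#' the PLS rank by internal cross-validation, pick the RMSECV-minimising
#' rank, and compute calibration statistics of the final fit on the
#' retained samples.
#'
#' @inheritParams cross_validate
#' @param trait Trait name recorded in the output row.
#' @param gh_threshold GH outlier cutoff (default 3).
#' @param pre_full Optional precomputed `apply_pretreatment(pretreatment,
#'   s, "calibration")` result, shared across region candidates by
#'   [search_models()].
#' @return A one-row data.frame (an "equation record") with columns
#'   `trait`, `scm`, `regions`, `rank`, `n`, `mean`, `sd`, `r2`, `rmsec`,
#'   `r2cv`, `rmsecv`, `rpd`, plus the number of eliminated outliers
#'   `n_outliers`.
#' @export
evaluate_candidate <- function(s, y, pretreatment, regions = NULL,
                               rank_max = 10, cv = cv_spec(),
                               gh_threshold = 3.0, trait = NA_character_,
                               pre_full = NULL) {
  y <- as.numeric(y)
  pre <- if (is.null(pre_full)) {
    apply_pretreatment(pretreatment, s, mode = "calibration")
  } else pre_full
  sel <- if (is.null(regions)) pre else select_regions(pre, regions)
  elim <- eliminate_outliers(sel, threshold = gh_threshold)
  keep <- match(elim$set$ids, s$ids)
  s_keep <- s[keep]; y_keep <- y[keep]
  rank_max <- min(rank_max, length(keep) - ceiling(length(keep) / cv$k) - 1,
                  ncol(sel$absorbance))
  cvres <- cross_validate(s_keep, y_keep, pretreatment, regions,
                          rank = NULL, rank_max = rank_max, cv = cv,
                          pre_sel = elim$set)
  final <- fit_pls(elim$set$absorbance[, , drop = FALSE], y_keep, cvres$rank)
  cal <- calib_stats(y_keep, final$fitted)
  data.frame(trait = trait,
             scm = format_scm(pretreatment$method),
             regions = if (is.null(regions)) "full" else format_regions(regions),
             rank = cvres$rank,
             n = length(keep),
             n_outliers = sum(elim$report$removed),
             mean = mean(y_keep),
             sd = stats::sd(y_keep),
             r2 = cal$r2, rmsec = cal$rmse,
             r2cv = cvres$r2cv, rmsecv = cvres$rmsecv, rpd = cvres$rpd,
             stringsAsFactors = FALSE)
}

#' Exhaustive pretreatment-by-region model search
#'
#' Evaluates every combination of the given pretreatments and region
#' candidates with its own GH outlier elimination and cross-validated
#' rank selection, and ranks the resulting equation records by RMSECV
#' ascending (ties by higher R^2cv, then smaller rank). The head of the
#' table is the best equation.
#'
#' @param s Calibration [spectrum_set()].
#' @param refs Reference table containing the trait column.
#' @param trait Trait column name in `refs`.
#' @param pretreatments Character vector of SCM names (default all ten)
#'   or a list of [pretreatment_spec()] objects.
#' @param region_sets List of [region_set()] candidates (e.g. from
#'   [region_candidates()]); `NULL` entries mean the full grid. Default:
#'   all unions of 4 equal-width interval blocks (15 candidates).
#' @param rank_max,cv,gh_threshold Passed to [evaluate_candidate()].
#' @param verbose Emit a progress message per candidate.
#' @return A data.frame of ranked equation records (best first).
#' @export
search_models <- function(s, refs, trait,
                          pretreatments = setdiff(scm_methods, "NONE"),
                          region_sets = NULL,
                          rank_max = 10, cv = cv_spec(), gh_threshold = 3.0,
                          verbose = FALSE) {
  al <- align_ids(s, refs)
  if (!trait %in% names(al$refs)) stop("trait column '", trait, "' not in reference table")
  keep <- !is.na(al$refs[[trait]])
  s2 <- al$set[which(keep)]; y <- al$refs[[trait]][keep]
  if (is.character(pretreatments))
    pretreatments <- lapply(pretreatments, pretreatment_spec)
  if (is.null(region_sets))
    region_sets <- region_candidates(make_intervals(s2$grid, 4), cap = 15)
  if (length(pretreatments) == 0 || length(region_sets) == 0)
    stop("no candidates: empty pretreatment or region list")
  records <- vector("list", length(pretreatments) * length(region_sets))
  i <- 0
  for (p in pretreatments) {
    pre_full <- if (grepl("MSC", p$method, fixed = TRUE)) NULL else
      apply_pretreatment(p, s2, mode = "calibration")
    for (r in region_sets) {
    i <- i + 1
    rec <- evaluate_candidate(s2, y, p, r, rank_max = rank_max, cv = cv,
                              gh_threshold = gh_threshold, trait = trait,
                              pre_full = pre_full)
    if (verbose)
      message(sprintf("[%d/%d] %s | %s | rank %d | RMSECV %.4g",
                      i, length(records), rec$scm, rec$regions, rec$rank,
                      rec$rmsecv))
    records[[i]] <- rec
  }
  }
  out <- do.call(rbind, records)
  out <- out[order(out$rmsecv, -out$r2cv, out$rank), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Refit the winning equation on calibration + validation merged
#'
#' After external validation, the validation samples are folded back
#' into a global calibration set and the winning candidate (pretreatment
#' and regions) is re-run end to end: GH elimination, rank selection and
#' internal cross-validation on the merged set.
#'
#' @param record A one-row equation record (e.g. head of
#'   [search_models()] output) carrying `scm` and `regions`.
#' @param s_merged Merged [spectrum_set()] (calibration + validation).
#' @param refs Reference table.
#' @param trait Trait column name.
#' @param rank_max,cv,gh_threshold Passed to [evaluate_candidate()].
#' @return A one-row equation record for the merged calibration.
#' @export
merge_validation_and_refit <- function(record, s_merged, refs, trait,
                                       rank_max = 10, cv = cv_spec(),
                                       gh_threshold = 3.0) {
  al <- align_ids(s_merged, refs)
  keep <- !is.na(al$refs[[trait]])
  s2 <- al$set[which(keep)]; y <- al$refs[[trait]][keep]
  pre <- pretreatment_spec(record$scm)
  reg <- if (identical(record$regions, "full")) NULL else parse_regions(record$regions)
  evaluate_candidate(s2, y, pre, reg, rank_max = rank_max, cv = cv,
                     gh_threshold = gh_threshold, trait = trait)
}

# ---- model comparison statistics -------------------------------------

signif_stars <- function(p) ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", ""))

#' F-test comparison of two RMSE values
#'
#' `F = (max(rmse1, rmse2) / min(rmse1, rmse2))^2` with `(n - 1, n - 1)`
#' degrees of freedom ordered to match the numerator/denominator;
#' two-sided p-value from the F distribution. Used to compare the
#' RMSEC/RMSECV of two calibrations (e.g. online vs offline).
#'
#' @param rmse1,n1 RMSE and sample count of the first calibration.
#' @param rmse2,n2 RMSE and sample count of the second calibration.
#' @return List with `f`, `df1`, `df2`, `p`, `stars`.
#' @export
compare_rmse <- function(rmse1, n1, rmse2, n2) {
  if (n1 < 2 || n2 < 2) stop("need n >= 2 in both groups")
  if (rmse1 <= 0 || rmse2 <= 0) stop("RMSE must be positive")
  if (rmse1 >= rmse2) { f <- (rmse1 / rmse2)^2; df1 <- n1 - 1; df2 <- n2 - 1
  } else { f <- (rmse2 / rmse1)^2; df1 <- n2 - 1; df2 <- n1 - 1 }
  pf_hi <- stats::pf(f, df1, df2, lower.tail = FALSE)
  p <- min(1, 2 * pf_hi)
  if (rmse1 == rmse2) p <- 1
  list(f = f, df1 = df1, df2 = df2, p = p, stars = signif_stars(p))
}

#' Fisher-z comparison of two coefficients of determination
#'
#' Converts each R^2 to a correlation `r = sqrt(R^2)`, applies the
#' Fisher z-transformation `z = atanh(r)`, and compares the two
#' calibrations with the two-sample statistic
#' `(z1 - z2) / sqrt(1/(n1-3) + 1/(n2-3))`, referred to the standard
#' normal (the large-sample form of the Student comparison of
#' transformed correlations). Two-sided p-value.
#'
#' @param r2_1,n1 R^2 and sample count of the first calibration.
#' @param r2_2,n2 R^2 and sample count of the second calibration.
#' @return List with `z1`, `z2`, `statistic`, `p`, `stars`.
#' @export
compare_r2 <- function(r2_1, n1, r2_2, n2) {
  for (r2 in c(r2_1, r2_2))
    if (r2 < 0 || r2 >= 1) stop("R^2 must lie in [0, 1): Fisher z is infinite at 1")
  if (n1 <= 3 || n2 <= 3) stop("need n > 3 in both groups")
  z1 <- atanh(sqrt(r2_1)); z2 <- atanh(sqrt(r2_2))
  se <- sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  stat <- (z1 - z2) / se
  p <- 2 * stats::pnorm(-abs(stat))
  list(z1 = z1, z2 = z2, statistic = stat, p = p, stars = signif_stars(p))
}

#' Write equation records as a study-table style CSV
#'
#' Column order mirrors the calibration tables: Rank, N, SCM, Spectrum
#' range, Mean, SD, R^2, RMSEC, R^2cv, RMSECV, RPD.
#'
#' @param records Equation-record data.frame from [search_models()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_equation_records <- function(records, path) {
  out <- data.frame(Trait = records$trait,
                    Rank = records$rank,
                    N = records$n,
                    SCM = records$scm,
                    `Spectrum range (cm-1)` = records$regions,
                    Mean = records$mean, SD = records$sd,
                    R2 = records$r2, RMSEC = records$rmsec,
                    R2cv = records$r2cv, RMSECV = records$rmsecv,
                    RPD = records$rpd,
                    check.names = FALSE)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
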
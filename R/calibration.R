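# PCA-based global-H outlier screening and NIPALS PLS calibration.

#' Principal component analysis of a spectral population
#'
#' Centered (unscaled) PCA used to characterise the spectral population
#' before outlier screening. The number of retained components is the
#' smallest count whose cumulative explained-variance fraction reaches
#' `var_threshold`, capped at `k_max` and at the matrix rank.
#'
#' @param X Samples-by-points numeric matrix.
#' @param var_threshold Cumulative explained-variance target (default 0.99).
#' @param k_max Maximum component count (default 20).
#' @return An object of class `pca_result`: list with `k`, `scores`
#'   (n x k), `var_frac` (all components), `score_sd` (first k), `center`.
#' @export
fit_pca <- function(X, var_threshold = 0.99, k_max = 20) {
  X <- as.matrix(X)
  if (nrow(X) < 3) stop("PCA needs at least 3 samples")
  pr <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  ev <- pr$sdev^2
  rank <- sum(pr$sdev > max(pr$sdev) * 1e-9)
  var_frac <- ev / sum(ev)
  k <- which(cumsum(var_frac) >= var_threshold)[1]
  if (is.na(k)) k <- rank
  k <- max(1L, min(k, k_max, rank))
  structure(list(k = k,
                 scores = pr$x[, seq_len(k), drop = FALSE],
                 var_frac = var_frac,
                 score_sd = pr$sdev[seq_len(k)],
                 center = pr$center),
            class = "pca_result")
}

#' Global-H (GH) spectral outlier score
#'
#' GH is the squared Mahalanobis distance of a sample in PCA score space
#' divided by the number of components:
#' `GH_i = (1/k) * sum_j (t_ij / s_j)^2`, where `s_j` is the score
#' standard deviation of component `j`. Over the fitting set the mean GH
#' is `(n-1)/n`. Samples with GH > 3 are conventionally treated as
#' spectral outliers.
#'
#' @param p A [fit_pca()] result.
#' @return Numeric vector of per-sample GH scores.
#' @export
gh_distances <- function(p) {
  stopifnot(inherits(p, "pca_result"))
  if (any(p$score_sd <= 0))
    stop("zero score standard deviation on a retained component")
  z <- sweep(p$scores, 2, p$score_sd, "/")
  rowMeans(z^2)
}

#' Eliminate GH spectral outliers
#'
#' Fits a PCA on the (pretreated, region-selected) spectra, computes the
#' GH score of each sample, and removes samples with GH above the
#' threshold from both the spectrum set and the reference table. The
#' screening is applied once (no iterative re-elimination).
#'
#' @param s A [spectrum_set()], already pretreated and region-selected as
#'   for the model being built.
#' @param refs Matching reference table (same ids), or `NULL`.
#' @param threshold GH cutoff (default 3.0); `Inf` disables elimination.
#' @param var_threshold,k_max Passed to [fit_pca()].
#' @return List with `set`, `refs` (filtered) and `report`, a data.frame
#'   with columns `id`, `gh`, `removed`.
#' @export
eliminate_outliers <- function(s, refs = NULL, threshold = 3.0,
                               var_threshold = 0.99, k_max = 20) {
  stopifnot(inherits(s, "spectrum_set"))
  p <- fit_pca(s$absorbance, var_threshold, k_max)
  gh <- gh_distances(p)
  removed <- gh > threshold
  if (all(removed)) stop("GH screening removed every sample; threshold too low")
  report <- data.frame(id = s$ids, gh = unname(gh), removed = removed,
                       stringsAsFactors = FALSE)
  keep <- which(!removed)
  out_refs <- refs
  if (!is.null(refs)) {
    out_refs <- refs[match(s$ids[keep], refs$id), , drop = FALSE]
    rownames(out_refs) <- NULL
  }
  list(set = s[keep], refs = out_refs, report = report)
}

# ---- NIPALS PLS -------------------------------------------------------

#' Fit a PLS calibration by NIPALS
#'
#' Single-response partial least squares by the NIPALS algorithm:
#' components are extracted sequentially, deflating `X` only. `X` and `y`
#' are centered internally. The latent-variable model is collapsed into a
#' coefficient vector and intercept, so prediction is
#' `yhat = intercept + x %*% coef`.
#'
#' @param X Samples-by-variables matrix.
#' @param y Numeric response vector.
#' @param rank Number of latent variables (`rank <= min(n-1, p)`).
#' @return An object of class `pls_fit`: list with `rank`, `x_mean`,
#'   `y_mean`, `W` (weights), `P` (x-loadings), `q` (y-loadings),
#'   `coef`, `intercept`, `fitted`.
#' @export
fit_pls <- function(X, y, rank) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("X row count and y length differ")
  if (stats::sd(y) == 0) stop("zero-variance response")
  if (rank < 1) stop("rank must be >= 1")
  if (rank > min(n - 1, p))
    stop("rank ", rank, " exceeds min(n-1, p) = ", min(n - 1, p))
  x_mean <- colMeans(X); y_mean <- mean(y)
  Xc <- sweep(X, 2, x_mean)
  yc <- y - y_mean
  W <- matrix(0, p, rank); P <- matrix(0, p, rank); q <- numeric(rank)
  Xd <- Xc
  A <- rank
  for (h in seq_len(rank)) {
    w <- crossprod(Xd, yc)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12 * max(1, sqrt(sum(Xc^2)))) {
      warning("negligible weight norm at component ", h,
              "; rank truncated to ", h - 1L)
      A <- h - 1L
      break
    }
    w <- w / nw
    t_h <- as.numeric(Xd %*% w)
    tt <- sum(t_h^2)
    p_h <- as.numeric(crossprod(Xd, t_h)) / tt
    q[h] <- sum(yc * t_h) / tt
    Xd <- Xd - tcrossprod(t_h, p_h)
    W[, h] <- w; P[, h] <- p_h
  }
  if (A == 0) stop("no usable PLS component (X carries no covariance with y)")
  W <- W[, seq_len(A), drop = FALSE]
  P <- P[, seq_len(A), drop = FALSE]
  q <- q[seq_len(A)]
  coef <- as.numeric(W %*% solve(crossprod(P, W), q))
  intercept <- y_mean - sum(x_mean * coef)
  fitted <- as.numeric(intercept + X %*% coef)
  structure(list(rank = A, x_mean = x_mean, y_mean = y_mean,
                 W = W, P = P, q = q, coef = coef, intercept = intercept,
                 fitted = fitted),
            class = "pls_fit")
}

#' Collapsed coefficient vectors for every nested rank
#'
#' NIPALS models are nested: the first `a` components of a rank-`A` fit
#' are the rank-`a` fit. Returns the p-by-A matrix whose column `a` is
#' the collapsed coefficient vector of the rank-`a` model (used for
#' efficient per-rank cross-validation).
#'
#' @param m A [fit_pls()] object.
#' @return List with `coef` (p x A matrix) and `intercept` (length A).
#' @export
pls_coef_path <- function(m) {
  stopifnot(inherits(m, "pls_fit"))
  A <- m$rank
  coef <- matrix(0, length(m$x_mean), A)
  intercept <- numeric(A)
  for (a in seq_len(A)) {
    Wa <- m$W[, seq_len(a), drop = FALSE]
    Pa <- m$P[, seq_len(a), drop = FALSE]
    coef[, a] <- as.numeric(Wa %*% solve(crossprod(Pa, Wa), m$q[seq_len(a)]))
    intercept[a] <- m$y_mean - sum(m$x_mean * coef[, a])
  }
  list(coef = coef, intercept = intercept)
}

#' @export
predict.pls_fit <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (ncol(X) != length(object$x_mean)) stop("variable count mismatch")
  as.numeric(object$intercept + X %*% object$coef)
}

#' Select the PLS rank by internal cross-validation
#'
#' Computes the k-fold cross-validated RMSECV for every rank up to
#' `rank_max` and returns the minimiser; ties are broken toward the
#' smaller rank (parsimony).
#'
#' @param X Samples-by-variables matrix.
#' @param y Response vector.
#' @param rank_max Maximum rank considered (default 25).
#' @param cv A [cv_spec()].
#' @return The chosen rank (integer), with the per-rank RMSECV vector as
#'   attribute `"rmsecv"`.
#' @export
select_rank <- function(X, y, rank_max = 25, cv = cv_spec()) {
  if (rank_max < 1) stop("rank_max must be >= 1")
  rm <- cv_rank_sweep(as.matrix(X), as.numeric(y), rank_max, cv)
  rank <- which.min(round(rm$rmsecv, 12))    # ties -> smaller rank
  structure(as.integer(rank), rmsecv = rm$rmsecv)
}

# k-fold CV of plain (X, y) over all ranks 1..rank_max (internal engine).
# Returns per-rank RMSECV and the n x rank_max out-of-fold prediction matrix.
cv_rank_sweep <- function(X, y, rank_max, cv) {
  n <- nrow(X)
  folds <- cv_folds(n, cv)
  rank_max <- min(rank_max, ncol(X))
  preds <- matrix(NA_real_, n, rank_max)
  for (f in folds) {
    tr <- setdiff(seq_len(n), f)
    r_f <- min(rank_max, length(tr) - 1)
    if (r_f < 1) stop("fold leaves fewer than 2 training samples")
    m <- fit_pls(X[tr, , drop = FALSE], y[tr], r_f)
    path <- pls_coef_path(m)
    pf <- sweep(X[f, , drop = FALSE] %*% path$coef, 2, path$intercept, "+")
    if (m$rank < rank_max)                    # truncated: pad with last column
      pf <- cbind(pf, matrix(pf[, m$rank], length(f), rank_max - m$rank))
    preds[f, ] <- pf
  }
  rmsecv <- sqrt(colMeans((preds - y)^2))
  list(rmsecv = rmsecv, preds = preds)
}

# fold index list; deterministic given cv$seed
cv_folds <- function(n, cv) {
  k <- cv$k
  if (k < 2 || k > n) stop("fold count k must satisfy 2 <= k <= n")
  perm <- sample_with_seed(n, cv$seed)
  split(perm, rep(seq_len(k), length.out = n))
}

sample_with_seed <- function(n, seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
            suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  sample.int(n)
}
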
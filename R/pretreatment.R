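# Row-wise spectral pretreatments (scatter-correction methods, SCM).
# All low-level operations accept a numeric vector or a samples-x-points
# matrix and return the same shape. Grid-changing operations (derivatives)
# return the cropped grid as an attribute; apply_pretreatment() does the
# spectrum_set bookkeeping.

scm_methods <- c("NONE", "COE", "SSL", "SNV", "MMN", "MSC",
                 "FD", "SED", "FD+SSL", "FD+SNV", "FD+MSC")

as_row_matrix <- function(x) {
  if (is.null(dim(x))) matrix(as.numeric(x), nrow = 1) else as.matrix(x)
}

restore_shape <- function(out, x) {
  if (is.null(dim(x))) drop(out) else out
}

#' Constant offset elimination (COE)
#'
#' Subtracts each spectrum's minimum so the new minimum is exactly 0.
#'
#' @param x Numeric vector (one spectrum) or samples-by-points matrix.
#' @return Same shape as `x`.
#' @export
coe <- function(x) {
  m <- as_row_matrix(x)
  if (ncol(m) == 0) stop("empty spectrum")
  out <- m - apply(m, 1, min)
  restore_shape(out, x)
}

#' Straight-line subtraction (SSL)
#'
#' Subtracts the per-spectrum least-squares straight line over the
#' wavenumber grid (detrending). The result is orthogonal to both the
#' constant and the linear trend.
#'
#' @param x Numeric vector or matrix of spectra.
#' @param grid Wavenumber grid matching the columns of `x`.
#' @return Same shape as `x`.
#' @export
ssl <- function(x, grid) {
  m <- as_row_matrix(x)
  grid <- as.numeric(grid)
  if (ncol(m) != length(grid)) stop("grid length does not match spectrum length")
  if (ncol(m) < 3) stop("straight-line subtraction needs at least 3 points")
  if (stats::sd(grid) == 0) stop("degenerate grid: zero spread")
  H <- cbind(1, grid - mean(grid))           # orthogonal-ish basis
  # rowwise OLS coefficients: B = M H (H'H)^-1  (n x 2)
  B <- m %*% H %*% solve(crossprod(H))
  out <- m - tcrossprod(B, H)
  restore_shape(out, x)
}

#' Standard normal variate (SNV)
#'
#' Centers and scales each spectrum to mean 0, sd 1 (sample sd, n-1
#' denominator).
#'
#' @param x Numeric vector or matrix of spectra.
#' @return Same shape as `x`.
#' @export
snv <- function(x) {
  m <- as_row_matrix(x)
  mu <- rowMeans(m)
  s <- apply(m, 1, stats::sd)
  if (any(s == 0)) stop("SNV undefined for constant spectrum (sd = 0), row(s): ",
                        paste(which(s == 0), collapse = ", "))
  restore_shape((m - mu) / s, x)
}

#' Min-max normalization (MMN)
#'
#' Rescales each spectrum to the range `[0, 2]` (the vector-normalization
#' convention of commercial NIRS software): `(x - min)/(max - min) * 2`.
#'
#' @param x Numeric vector or matrix of spectra.
#' @return Same shape as `x`.
#' @export
mmn <- function(x) {
  m <- as_row_matrix(x)
  lo <- apply(m, 1, min); hi <- apply(m, 1, max)
  if (any(hi == lo)) stop("MMN undefined for constant spectrum, row(s): ",
                          paste(which(hi == lo), collapse = ", "))
  restore_shape((m - lo) / (hi - lo) * 2, x)
}

#' Multiplicative scatter correction (MSC)
#'
#' Regresses each spectrum on a reference spectrum (`x = a + b * ref`)
#' and returns `(x - a)/b`, removing additive offset and multiplicative
#' gain relative to the reference. In a calibration the reference is the
#' mean calibration spectrum, stored in the fitted pretreatment spec so
#' that validation spectra are corrected against the same reference.
#'
#' @param x Numeric vector or matrix of spectra.
#' @param reference Reference spectrum (defaults to the column mean of `x`).
#' @return Same shape as `x`, with the reference attached as attribute
#'   `"reference"`.
#' @export
msc <- function(x, reference = NULL) {
  m <- as_row_matrix(x)
  if (is.null(reference)) reference <- colMeans(m)
  reference <- as.numeric(reference)
  if (length(reference) != ncol(m)) stop("MSC reference length mismatch")
  vr <- stats::var(reference)
  if (vr == 0) stop("MSC reference has zero variance")
  rc <- reference - mean(reference)
  b <- as.numeric(m %*% rc) / sum(rc^2)     # slope of x on ref, rowwise
  if (any(abs(b) < 1e-12))
    stop("MSC slope ~ 0 for row(s): ", paste(which(abs(b) < 1e-12), collapse = ", "))
  a <- rowMeans(m) - b * mean(reference)
  out <- (m - a) / b
  out <- restore_shape(out, x)
  attr(out, "reference") <- reference
  out
}

#' Savitzky-Golay derivative (FD / SED)
#'
#' First or second derivative with respect to wavenumber, computed by
#' Savitzky-Golay local polynomial filtering on a uniform grid. Edges are
#' handled by cropping half a window on each side rather than polynomial
#' extrapolation; the cropped grid is returned as attribute `"grid"`.
#'
#' @param x Numeric vector or matrix of spectra.
#' @param grid Uniform wavenumber grid (cm^-1).
#' @param order Derivative order, 1 (FD) or 2 (SED).
#' @param window Odd filter window length in points (default 17).
#' @param polyorder Local polynomial order (default 2).
#' @return Matrix (or vector) of derivative spectra in units per cm^-1
#'   (per cm^-2 for order 2), `window - 1` points shorter than the input,
#'   with the cropped grid as attribute `"grid"`.
#' @export
sg_derivative <- function(x, grid, order = 1, window = 17, polyorder = 2) {
  m <- as_row_matrix(x)
  grid <- as.numeric(grid)
  if (ncol(m) != length(grid)) stop("grid length does not match spectrum length")
  if (!order %in% c(1, 2)) stop("derivative order must be 1 or 2")
  if (window %% 2 != 1) stop("Savitzky-Golay window must be odd")
  if (window < polyorder + 2) stop("window must be >= polyorder + 2")
  if (polyorder < order) stop("polyorder must be >= derivative order")
  if (ncol(m) < window) stop("spectrum shorter than the filter window")
  h <- diff(grid)
  if (max(abs(h - h[1])) > 1e-6 * abs(h[1]))
    stop("non-uniform wavenumber grid; resample before taking derivatives")
  F <- signal::sgolay(p = polyorder, n = window, m = order, ts = h[1])
  k <- as.numeric(F[(window + 1) / 2, ])     # interior derivative kernel
  half <- (window - 1) / 2
  p_out <- ncol(m) - 2 * half
  out <- matrix(0, nrow(m), p_out)
  for (j in seq_len(window))                 # shift-and-add convolution
    out <- out + k[j] * m[, j:(j + p_out - 1), drop = FALSE]
  out <- restore_shape(out, x)
  attr(out, "grid") <- grid[(half + 1):(length(grid) - half)]
  out
}

# ---- pretreatment specs ----------------------------------------------

#' Pretreatment (scatter-correction method) specification
#'
#' @param method One of `"NONE"`, `"COE"`, `"SSL"`, `"SNV"`, `"MMN"`,
#'   `"MSC"`, `"FD"`, `"SED"`, `"FD+SSL"`, `"FD+SNV"`, `"FD+MSC"`
#'   (spaces around `+` tolerated). Combinations apply the first
#'   derivative first, then the scatter correction.
#' @param sg_window Savitzky-Golay window (odd, default 17).
#' @param sg_polyorder Savitzky-Golay polynomial order (default 2).
#' @return An object of class `pretreatment_spec`.
#' @export
pretreatment_spec <- function(method = "NONE", sg_window = 17, sg_polyorder = 2) {
  method <- toupper(gsub("[[:space:]]", "", method))
  if (!method %in% scm_methods)
    stop("unknown pretreatment method '", method, "'; must be one of: ",
         paste(scm_methods, collapse = ", "))
  if (sg_window %% 2 != 1 || sg_window < sg_polyorder + 2)
    stop("sg_window must be odd and >= sg_polyorder + 2")
  structure(list(method = method, sg_window = sg_window,
                 sg_polyorder = sg_polyorder, msc_reference = NULL,
                 msc_grid = NULL),
            class = "pretreatment_spec")
}

#' @export
print.pretreatment_spec <- function(x, ...) {
  cat("<pretreatment_spec> ", format_scm(x$method),
      if (grepl("FD|SED", x$method))
        paste0(" (window ", x$sg_window, ", polyorder ", x$sg_polyorder, ")"),
      if (!is.null(x$msc_reference)) " [fitted]", "\n", sep = "")
  invisible(x)
}

#' Format a method label the way the study tables print it
#' @param method Method string, e.g. `"FD+SNV"`.
#' @return e.g. `"FD + SNV"`.
#' @export
format_scm <- function(method) gsub("+", " + ", method, fixed = TRUE)

#' Apply a pretreatment to a spectrum set
#'
#' Applies the spectral pretreatment named in `spec` to every spectrum.
#' Combination methods (`FD+SSL`, `FD+SNV`, `FD+MSC`) take the first
#' derivative first and then apply the scatter correction. In
#' `"calibration"` mode MSC-containing specs compute and store the mean
#' (derivative) calibration spectrum as the correction reference; in
#' `"apply-only"` mode the stored reference is reused, so validation and
#' prediction spectra are corrected exactly as the calibration was.
#'
#' @param spec A [pretreatment_spec()].
#' @param s A [spectrum_set()].
#' @param mode `"calibration"` (fit any data-dependent parameters on `s`)
#'   or `"apply-only"` (reuse stored parameters).
#' @return The transformed `spectrum_set` (the input is never modified).
#'   The fitted spec is attached as attribute `"pretreatment"`.
#' @export
apply_pretreatment <- function(spec, s, mode = c("calibration", "apply-only")) {
  mode <- match.arg(mode)
  stopifnot(inherits(spec, "pretreatment_spec"), inherits(s, "spectrum_set"))
  m <- s$absorbance
  grid <- s$grid
  parts <- strsplit(spec$method, "+", fixed = TRUE)[[1]]
  if (identical(parts, "NONE")) parts <- character(0)
  if (identical(parts, "SED")) parts <- "SED"
  for (part in parts) {
    if (part == "FD" || part == "SED") {
      d <- sg_derivative(m, grid, order = if (part == "SED") 2 else 1,
                         window = spec$sg_window, polyorder = spec$sg_polyorder)
      grid <- attr(d, "grid")
      m <- as_row_matrix(d)
      attr(m, "grid") <- NULL
    } else if (part == "COE") {
      m <- coe(m)
    } else if (part == "SSL") {
      m <- ssl(m, grid)
    } else if (part == "SNV") {
      m <- snv(m)
    } else if (part == "MMN") {
      m <- mmn(m)
    } else if (part == "MSC") {
      if (mode == "calibration") {
        out <- msc(m)
        spec$msc_reference <- attr(out, "reference")
        spec$msc_grid <- grid
        m <- out
      } else {
        if (is.null(spec$msc_reference))
          stop("apply-only MSC requires a spec fitted on a calibration set")
        idx <- match(round(spec$msc_grid, 6), round(grid, 6))
        if (anyNA(idx))
          stop("data grid is missing wavenumbers of the stored MSC reference")
        m <- m[, idx, drop = FALSE]
        grid <- grid[idx]
        m <- msc(m, reference = spec$msc_reference)
      }
      attr(m, "reference") <- NULL
    }
  }
  out <- spectrum_set(grid, m, s$ids, s$meta)
  attr(out, "pretreatment") <- spec
  out
}

# ---- wavelength regions ----------------------------------------------

#' Wavelength region set
#'
#' A set of closed wavenumber intervals `[lo, hi]` (cm^-1) used to select
#' spectral variables before calibration. Intervals are normalised to
#' ascending order and overlapping/touching intervals are merged, so the
#' stored intervals are pairwise disjoint.
#'
#' @param ... Numeric length-2 vectors `c(lo, hi)` (either order), or a
#'   single 2-column matrix / list of such vectors.
#' @return An object of class `region_set`: a 2-column matrix with
#'   columns `lo`, `hi`.
#' @export
region_set <- function(...) {
  args <- list(...)
  if (length(args) == 1 && is.matrix(args[[1]])) {
    ivs <- args[[1]]
  } else if (length(args) == 1 && is.list(args[[1]]) && !is.data.frame(args[[1]])) {
    ivs <- do.call(rbind, args[[1]])
  } else {
    ivs <- do.call(rbind, args)
  }
  ivs <- matrix(as.numeric(ivs), ncol = 2)
  ivs <- t(apply(ivs, 1, sort))              # tolerate hi-first table order
  if (any(ivs[, 1] == ivs[, 2])) stop("degenerate interval with lo == hi")
  ivs <- ivs[order(ivs[, 1]), , drop = FALSE]
  # merge overlaps
  merged <- ivs[1, , drop = FALSE]
  if (nrow(ivs) > 1) for (i in 2:nrow(ivs)) {
    last <- nrow(merged)
    if (ivs[i, 1] <= merged[last, 2]) {
      merged[last, 2] <- max(merged[last, 2], ivs[i, 2])
    } else merged <- rbind(merged, ivs[i, ])
  }
  colnames(merged) <- c("lo", "hi")
  structure(merged, class = c("region_set", "matrix"))
}

#' Parse a region string in study-table format
#'
#' Accepts strings like `"11,964.8 - 11,178; 8825.1 - 7243.7"`:
#' semicolon-separated intervals, endpoints separated by a hyphen or
#' en-dash, comma thousands separators tolerated, high endpoint first as
#' the tables print it.
#'
#' @param text Region string.
#' @return A [region_set()].
#' @export
parse_regions <- function(text) {
  pieces <- strsplit(text, ";")[[1]]
  ivs <- lapply(pieces, function(p) {
    p <- gsub(",", "", p)
    ends <- regmatches(p, gregexpr("[0-9]+\\.?[0-9]*", p))[[1]]
    if (length(ends) != 2)
      stop("cannot parse interval '", trimws(p), "': expected two endpoints")
    as.numeric(ends)
  })
  region_set(ivs)
}

#' Format a region set the way the study tables print it
#'
#' @param r A [region_set()].
#' @return A string `"hi - lo; hi - lo"` with intervals in descending
#'   wavenumber order.
#' @export
format_regions <- function(r) {
  ivs <- unclass(r)[order(-unclass(r)[, 1]), , drop = FALSE]
  paste(apply(ivs, 1, function(v) paste0(v[2], " - ", v[1])), collapse = "; ")
}

#' @export
print.region_set <- function(x, ...) {
  cat("<region_set> ", format_regions(x), "\n", sep = "")
  invisible(x)
}

#' Select the spectral variables inside a region set
#'
#' Retains the columns whose wavenumber lies inside any interval of `r`
#' (closed, inclusive endpoints), preserving column order.
#'
#' @param s A [spectrum_set()].
#' @param r A [region_set()].
#' @return A `spectrum_set` restricted to the selected columns.
#' @export
select_regions <- function(s, r) {
  stopifnot(inherits(s, "spectrum_set"), inherits(r, "region_set"))
  keep <- rep(FALSE, length(s$grid))
  for (i in seq_len(nrow(r)))
    keep <- keep | (s$grid >= r[i, 1] & s$grid <= r[i, 2])
  if (!any(keep)) stop("no grid points fall inside the region set")
  spectrum_set(s$grid[keep], s$absorbance[, keep, drop = FALSE], s$ids, s$meta)
}

#' Divide a grid span into contiguous equal-width interval blocks
#'
#' Building blocks for the interval-division / reassembly region search:
#' the grid span is tiled by `n_intervals` contiguous equal-width
#' intervals; region candidates are unions of these blocks.
#'
#' @param grid Wavenumber grid.
#' @param n_intervals Number of blocks (>= 1, at most the point count).
#' @return A list of length-2 vectors `c(lo, hi)`.
#' @export
make_intervals <- function(grid, n_intervals) {
  if (n_intervals < 1) stop("n_intervals must be >= 1")
  if (n_intervals > length(grid)) stop("more intervals than grid points")
  span <- range(grid)
  edges <- seq(span[1], span[2], length.out = n_intervals + 1)
  lapply(seq_len(n_intervals), function(i) c(edges[i], edges[i + 1]))
}

#' Enumerate region-set candidates from interval blocks
#'
#' All non-empty unions of up to `max_blocks` blocks, ordered by block
#' count then lexicographically, truncated to `cap` candidates.
#'
#' @param blocks List of interval blocks from [make_intervals()].
#' @param max_blocks Maximum number of blocks per candidate (default all).
#' @param cap Maximum number of candidates returned (default 15).
#' @return A list of [region_set()] objects.
#' @export
region_candidates <- function(blocks, max_blocks = length(blocks), cap = 15) {
  nb <- length(blocks)
  combos <- list()
  for (k in seq_len(min(max_blocks, nb))) {
    cmb <- utils::combn(nb, k, simplify = FALSE)
    combos <- c(combos, cmb)
    if (length(combos) >= cap) break
  }
  combos <- combos[seq_len(min(cap, length(combos)))]
  lapply(combos, function(idx) region_set(blocks[idx]))
}
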
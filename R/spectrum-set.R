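#' Spectrum set container
#'
#' A `spectrum_set` holds a wavenumber grid together with an
#' absorbance matrix (log 1/R) and per-sample metadata. It is the object
#' every pretreatment, region selection and calibration step operates on.
#'
#' @param grid Numeric vector of wavenumbers (cm^-1), strictly monotone.
#'   Stored in ascending order; the matrix columns are permuted to match.
#' @param absorbance Numeric matrix, one row per sample, one column per
#'   grid point. All values must be finite.
#' @param ids Character vector of unique sample identifiers (defaults to
#'   the matrix rownames).
#' @param meta Optional `data.frame` of per-sample metadata. Recognised
#'   columns: `batch`, `date`, `mode` (`"online"` or `"offline"`),
#'   `replicate`. Missing columns are filled with defaults.
#' @return An object of class `spectrum_set`: a list with elements
#'   `grid`, `absorbance`, `ids`, `meta`.
#' @export
spectrum_set <- function(grid, absorbance, ids = rownames(absorbance),
                         meta = NULL) {
  grid <- as.numeric(grid)
  if (is.null(dim(absorbance))) absorbance <- matrix(absorbance, nrow = 1)
  absorbance <- as.matrix(absorbance)
  storage.mode(absorbance) <- "double"
  if (length(grid) != ncol(absorbance))
    stop("grid length (", length(grid), ") does not match matrix column count (",
         ncol(absorbance), ")")
  if (length(grid) >= 2) {
    d <- diff(grid)
    if (any(d == 0)) stop("duplicated wavenumbers in grid: ",
                          paste(unique(grid[which(d == 0)]), collapse = ", "))
    if (all(d < 0)) { # descending input: canonicalise
      grid <- rev(grid)
      absorbance <- absorbance[, rev(seq_len(ncol(absorbance))), drop = FALSE]
    } else if (any(d < 0)) {
      o <- order(grid)
      if (anyDuplicated(grid)) stop("duplicated wavenumbers in grid")
      grid <- grid[o]
      absorbance <- absorbance[, o, drop = FALSE]
    }
  }
  if (any(!is.finite(absorbance)))
    stop("non-finite absorbance values at ",
         sum(!is.finite(absorbance)), " positions")
  if (is.null(ids)) ids <- paste0("S", seq_len(nrow(absorbance)))
  ids <- as.character(ids)
  if (length(ids) != nrow(absorbance))
    stop("ids length does not match number of spectra")
  n <- nrow(absorbance)
  if (is.null(meta)) meta <- data.frame(row.names = seq_len(n))
  meta <- as.data.frame(meta)
  if (nrow(meta) == 0 && n > 0) meta <- data.frame(row.names = seq_len(n))
  if (nrow(meta) != n) stop("meta row count does not match number of spectra")
  if (is.null(meta$batch)) meta$batch <- rep("B1", n)
  if (is.null(meta$mode)) meta$mode <- rep("online", n)
  if (is.null(meta$replicate)) meta$replicate <- rep(1L, n)
  if (anyDuplicated(paste(ids, meta$replicate)))
    stop("duplicated (id, replicate) pairs")
  rownames(absorbance) <- ids
  structure(list(grid = grid, absorbance = absorbance, ids = ids, meta = meta),
            class = "spectrum_set")
}

#' @export
print.spectrum_set <- function(x, ...) {
  cat("<spectrum_set> ", nrow(x$absorbance), " spectra x ",
      length(x$grid), " points, ",
      min(x$grid), "-", max(x$grid), " cm^-1\n", sep = "")
  invisible(x)
}

#' @export
dim.spectrum_set <- function(x) dim(x$absorbance)

#' Subset a spectrum set by sample
#'
#' @param x A `spectrum_set`.
#' @param i Row (sample) index: integer, logical, or sample ids.
#' @param ... Ignored.
#' @return A `spectrum_set` with the selected samples.
#' @export
`[.spectrum_set` <- function(x, i, ...) {
  if (is.character(i)) i <- match(i, x$ids)
  spectrum_set(x$grid, x$absorbance[i, , drop = FALSE], x$ids[i],
               x$meta[i, , drop = FALSE])
}

#' Replace the absorbance matrix of a spectrum set
#'
#' Internal helper: build a new set sharing ids/meta with `x` but with a
#' different matrix (and optionally grid).
#' @noRd
set_matrix <- function(x, m, grid = x$grid) {
  spectrum_set(grid, m, x$ids, x$meta)
}

# ---- reference table --------------------------------------------------

trait_columns <- c("cri", "asl_dm", "ail_dm", "total_dm",
                   "asl_cw", "ail_cw", "total_cw")

#' Validate a reference trait table
#'
#' A reference table is a plain `data.frame` with an `id` column and any
#' of the trait columns `cri`, `asl_dm`, `ail_dm`, `total_dm`, `asl_cw`,
#' `ail_cw`, `total_cw` (lignin values in % dry mass / % cell wall, CrI
#' in %). Missing values are permitted per trait. Checks:
#' all present values are non-negative; where the soluble, insoluble and
#' total lignin are all present, `|total - (asl + ail)| <= 0.1`
#' (rounding tolerance); proportions are >= the matching contents
#' (the cell wall is at most the dry mass).
#'
#' @param refs A data.frame.
#' @return `refs`, invisibly, if valid; otherwise an error.
#' @export
validate_reference_table <- function(refs) {
  if (!is.data.frame(refs)) stop("reference table must be a data.frame")
  if (is.null(refs$id)) stop("reference table must have an 'id' column")
  if (anyDuplicated(refs$id)) stop("duplicated sample ids in reference table")
  present <- intersect(trait_columns, names(refs))
  for (cn in present) {
    v <- refs[[cn]]
    if (any(v < 0, na.rm = TRUE))
      stop("negative values in reference column '", cn, "'")
  }
  chk_sum <- function(a, b, tot, label) {
    if (all(c(a, b, tot) %in% names(refs))) {
      ok <- stats::complete.cases(refs[, c(a, b, tot)])
      bad <- abs(refs[[tot]][ok] - (refs[[a]][ok] + refs[[b]][ok])) > 0.1
      if (any(bad))
        stop("total lignin != ASL + AIL beyond 0.1 tolerance (", label,
             ") for ids: ", paste(refs$id[ok][bad], collapse = ", "))
    }
  }
  chk_sum("asl_dm", "ail_dm", "total_dm", "% dry mass")
  chk_sum("asl_cw", "ail_cw", "total_cw", "% cell wall")
  for (p in c("asl", "ail", "total")) {
    dm <- paste0(p, "_dm"); cw <- paste0(p, "_cw")
    if (all(c(dm, cw) %in% names(refs))) {
      ok <- stats::complete.cases(refs[, c(dm, cw)])
      if (any(refs[[cw]][ok] < refs[[dm]][ok] - 1e-8))
        stop("proportion (% cell wall) below content (% dry mass) for '", p, "'")
    }
  }
  invisible(refs)
}

#' Align a spectrum set and reference table on shared ids
#'
#' @param s A `spectrum_set`.
#' @param refs A reference table with an `id` column.
#' @return A list with elements `set` and `refs`, row-aligned, restricted
#'   to the shared ids (order of `s`).
#' @export
align_ids <- function(s, refs) {
  common <- intersect(s$ids, refs$id)
  if (length(common) == 0) stop("no overlapping ids between spectra and reference table")
  s2 <- s[common]
  refs2 <- refs[match(common, refs$id), , drop = FALSE]
  rownames(refs2) <- NULL
  list(set = s2, refs = refs2)
}
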
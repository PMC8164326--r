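# Laboratory reference computations: Segal crystallinity index from
# X-ray diffractograms and the two-step acid-hydrolysis lignin arithmetic.

#' Diffractogram container
#'
#' @param two_theta Scattering angles 2-theta in degrees, ascending,
#'   within `[10, 45]`.
#' @param intensity Non-negative intensities (counts), same length.
#' @param id Optional sample id.
#' @return An object of class `diffractogram`.
#' @export
diffractogram <- function(two_theta, intensity, id = NA_character_) {
  two_theta <- as.numeric(two_theta); intensity <- as.numeric(intensity)
  if (length(two_theta) != length(intensity))
    stop("two_theta and intensity lengths differ")
  if (is.unsorted(two_theta, strictly = TRUE))
    stop("two_theta must be strictly ascending")
  if (min(two_theta) < 10 - 1e-9 || max(two_theta) > 45 + 1e-9)
    stop("two_theta outside the 10-45 degree scan range")
  if (any(intensity < 0)) stop("negative intensities")
  structure(list(two_theta = two_theta, intensity = intensity, id = id),
            class = "diffractogram")
}

#' Segal crystallinity index from an X-ray diffractogram
#'
#' `CrI = 100 * (I200 - Iam) / I200`, where `I200` is the maximum
#' intensity of the 200 reflection (crystalline plus amorphous, near
#' 2-theta = 22.5 deg) and `Iam` the minimum intensity between the 200
#' and 110 peaks (amorphous only, near 18.5 deg). Both extrema are
#' located by windowed search around the nominal angles rather than
#' fixed-angle lookup. No baseline is subtracted (the original Segal
#' convention); `subtract_background` optionally removes a linear
#' baseline fitted to the scan endpoints first.
#'
#' @param d A [diffractogram()].
#' @param i200_window Search window for the 200 peak maximum (degrees).
#' @param iam_window Search window for the amorphous minimum (degrees).
#' @param subtract_background If `TRUE`, subtract the straight line
#'   through the first and last scan points before the computation
#'   (off by default).
#' @return List with `cri` (%), `i200`, `iam`, `angle_200`, `angle_am`.
#' @export
compute_cri <- function(d, i200_window = c(21, 24), iam_window = c(17, 20),
                        subtract_background = FALSE) {
  stopifnot(inherits(d, "diffractogram"))
  tt <- d$two_theta; I <- d$intensity
  if (subtract_background) {
    ends <- c(1, length(tt))
    slope <- diff(I[ends]) / diff(tt[ends])
    I <- I - (I[1] + slope * (tt - tt[1]))
  }
  in200 <- tt >= i200_window[1] & tt <= i200_window[2]
  inam <- tt >= iam_window[1] & tt <= iam_window[2]
  if (!any(in200) || !any(inam))
    stop("extremum search window does not overlap the scan grid")
  i200_idx <- which(in200)[which.max(I[in200])]
  iam_idx <- which(inam)[which.min(I[inam])]
  i200 <- I[i200_idx]; iam <- I[iam_idx]
  if (i200 <= 0) stop("I200 <= 0: no crystalline peak intensity")
  if (iam > i200)
    stop("I_am (", signif(iam, 4), ") exceeds I200 (", signif(i200, 4),
         "): diffractogram lacks the expected peak/valley structure")
  list(cri = 100 * (i200 - iam) / i200, i200 = i200, iam = iam,
       angle_200 = tt[i200_idx], angle_am = tt[iam_idx])
}

#' Wet-chemistry protocol constants
#'
#' Defaults follow the two-step acid hydrolysis protocol: 0.5 g sample,
#' hydrolysate fixed to 250 mL and read at 205 nm through a 1 cm cell,
#' ASL absorptivity 110 L g^-1 cm^-1 (the standard 205 nm value of the
#' NREL laboratory analytical procedure); 0.10 g subsample for the
#' soluble-sugar extraction that defines the cell-wall fraction.
#'
#' @param sample_mass Hydrolysis sample mass (g).
#' @param filtrate_volume Hydrolysate volume (L).
#' @param dilution UV dilution factor.
#' @param path UV path length (cm).
#' @param absorptivity ASL absorptivity at 205 nm (L g^-1 cm^-1).
#' @param dry_mass Dry mass of the sugar-extraction subsample (g).
#' @param ash_mass Typical crucible ash mass (g), used by the generator.
#' @return A list of protocol constants.
#' @export
wetchem_protocol <- function(sample_mass = 0.5, filtrate_volume = 0.25,
                             dilution = 10, path = 1, absorptivity = 110,
                             dry_mass = 0.10, ash_mass = 0.005) {
  list(sample_mass = sample_mass, filtrate_volume = filtrate_volume,
       dilution = dilution, path = path, absorptivity = absorptivity,
       dry_mass = dry_mass, ash_mass = ash_mass)
}

#' Acid-soluble lignin content from UV absorbance
#'
#' `ASL (% dry mass) = 100 * A205 * V * DF / (eps * l * m)` with
#' absorbance `A205`, filtrate volume `V` (L), dilution factor `DF`,
#' absorptivity `eps` (L g^-1 cm^-1), path length `l` (cm) and sample
#' mass `m` (g).
#'
#' @param r A wet-chemistry record: list/one-row data.frame with fields
#'   `a205`, `filtrate_volume`, `dilution`, `path`, `sample_mass`.
#' @param absorptivity Absorptivity (default 110 L g^-1 cm^-1).
#' @return ASL content in % dry mass.
#' @export
asl_content <- function(r, absorptivity = 110) {
  if (r$sample_mass <= 0) stop("sample mass must be positive")
  100 * r$a205 * r$filtrate_volume * r$dilution /
    (absorptivity * r$path * r$sample_mass)
}

#' Acid-insoluble lignin content from residue and ash masses
#'
#' `AIL (% dry mass) = 100 * (residue - ash) / sample_mass`.
#'
#' @param r Wet-chemistry record with `residue_mass`, `ash_mass`,
#'   `sample_mass` (g).
#' @return AIL content in % dry mass.
#' @export
ail_content <- function(r) {
  if (r$sample_mass <= 0) stop("sample mass must be positive")
  if (r$ash_mass > r$residue_mass) stop("ash mass exceeds residue mass")
  100 * (r$residue_mass - r$ash_mass) / r$sample_mass
}

#' Cell-wall fraction of dry biomass
#'
#' The residue after soluble-sugar extraction is taken as cell wall:
#' `(dry_mass - soluble_sugar) / dry_mass`.
#'
#' @param r Wet-chemistry record with `dry_mass`, `soluble_sugar` (g).
#' @return Cell-wall fraction in `(0, 1]`.
#' @export
cell_wall_fraction <- function(r) {
  if (r$dry_mass <= 0) stop("dry mass must be positive")
  if (r$soluble_sugar >= r$dry_mass)
    stop("soluble sugar mass must be smaller than dry mass")
  (r$dry_mass - r$soluble_sugar) / r$dry_mass
}

#' Lignin proportion in the cell wall
#'
#' Converts a lignin content (% dry mass) into a proportion of the cell
#' wall by dividing by the cell-wall fraction.
#'
#' @param content_dm Lignin content in % dry mass.
#' @param cw Cell-wall fraction of dry mass, in `(0, 1]`.
#' @return Lignin proportion in % cell wall.
#' @export
lignin_proportion <- function(content_dm, cw) {
  if (any(cw <= 0)) stop("cell-wall fraction must be positive")
  if (any(cw > 1)) stop("cell-wall fraction cannot exceed 1")
  content_dm / cw
}

#' Compute a reference table from wet-chemistry records and diffractograms
#'
#' Applies [asl_content()], [ail_content()], [cell_wall_fraction()] and
#' [lignin_proportion()] to each wet-chemistry record, and [compute_cri()]
#' to each diffractogram, merging on id.
#'
#' @param wetchem Data.frame of wet-chemistry records (one row per
#'   sample, columns as in [asl_content()] etc. plus `id`).
#' @param diffractograms Optional named list of [diffractogram()]
#'   objects (names = ids).
#' @return A reference table data.frame.
#' @export
assay_reference_table <- function(wetchem, diffractograms = NULL) {
  n <- nrow(wetchem)
  asl <- ail <- cw <- numeric(n)
  for (i in seq_len(n)) {
    r <- as.list(wetchem[i, ])
    asl[i] <- asl_content(r)
    ail[i] <- ail_content(r)
    cw[i] <- cell_wall_fraction(r)
  }
  refs <- data.frame(id = wetchem$id,
                     asl_dm = asl, ail_dm = ail, total_dm = asl + ail,
                     asl_cw = lignin_proportion(asl, cw),
                     ail_cw = lignin_proportion(ail, cw),
                     total_cw = lignin_proportion(asl + ail, cw),
                     cw_frac = cw,
                     stringsAsFactors = FALSE)
  if (!is.null(diffractograms)) {
    cri <- vapply(diffractograms, function(d) compute_cri(d)$cri, numeric(1))
    refs$cri <- cri[match(refs$id, names(diffractograms))]
  }
  validate_reference_table(refs)
  refs
}
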
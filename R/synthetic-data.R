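# Synthetic-data generators: reference traits with known latent values,
# NIR spectra with controlled artifact structure, X-ray diffractograms
# built to close under the Segal computation, and wet-chemistry raw
# records that invert the lignin arithmetic exactly at zero noise.

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
            suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  expr
}

# ---- truncated-normal machinery --------------------------------------

# mean and sd of N(mu, sig) truncated to [a, b]
tnorm_moments <- function(mu, sig, a, b) {
  al <- (a - mu) / sig; be <- (b - mu) / sig
  Z <- stats::pnorm(be) - stats::pnorm(al)
  dphi <- stats::dnorm(al) - stats::dnorm(be)
  m <- mu + sig * dphi / Z
  v <- sig^2 * (1 + (al * stats::dnorm(al) - be * stats::dnorm(be)) / Z -
                  (dphi / Z)^2)
  c(mean = m, sd = sqrt(max(v, 0)))
}

# latent (mu, sig) such that the [a, b]-truncated normal has the target
# mean and sd (moment matching, so configured moments are reproduced
# exactly despite truncation)
tnorm_match <- function(mean, sd, a, b) {
  obj <- function(th) {
    mo <- tnorm_moments(th[1], exp(th[2]), a, b)
    (mo["mean"] - mean)^2 / sd^2 + (mo["sd"] - sd)^2 / sd^2
  }
  fit <- stats::optim(c(mean, log(sd)), obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 2000))
  if (fit$value > 1e-6)
    stop("cannot moment-match a truncated normal with mean ", mean,
         ", sd ", sd, " on [", a, ", ", b, "]")
  c(mu = fit$par[1], sig = exp(fit$par[2]))
}

# truncated-normal quantile transform of standard-normal draws
tnorm_from_z <- function(z, mu, sig, a, b) {
  pa <- stats::pnorm(a, mu, sig); pb <- stats::pnorm(b, mu, sig)
  stats::qnorm(pa + stats::pnorm(z) * (pb - pa), mu, sig)
}

# ---- trait configuration ---------------------------------------------

#' Default inter-trait correlation matrix
#'
#' Latent correlations among (CrI, ASL, AIL, cell-wall fraction):
#' the two lignin fractions are moderately positively correlated; more
#' lignified walls carry somewhat lower soluble-sugar (higher cell wall)
#' and crystallinity varies largely independently. Values are a modeling
#' choice for the simulator, not measured quantities.
#'
#' @return A 4x4 correlation matrix.
#' @export
default_trait_correlation <- function() {
  R <- matrix(c(1.00, 0.10, -0.20, 0.15,
                0.10, 1.00, 0.35, -0.10,
                -0.20, 0.35, 1.00, -0.30,
                0.15, -0.10, -0.30, 1.00), 4, 4)
  dimnames(R) <- list(c("cri", "asl_dm", "ail_dm", "cw_frac"),
                      c("cri", "asl_dm", "ail_dm", "cw_frac"))
  R
}

#' Trait distribution configuration
#'
#' Truncated-normal parameters per base trait plus an inter-trait
#' correlation matrix and per-trait reference measurement noise.
#' Defaults reproduce the printed population statistics of the sugarcane
#' study: CrI mean 42.8 / sd 3.85 ranging 21.6-55.6 %, ASL 1.2-2.6 and
#' AIL 9.2-25.3 % dry mass (total lignin 10.9-27.0 % dry mass, total
#' proportion 24.3-56.2 % cell wall). The cell-wall fraction links
#' content to proportion.
#'
#' @param traits Data.frame with columns `trait`, `mean`, `sd`, `min`,
#'   `max`, `noise_sd` for the four base traits `cri`, `asl_dm`,
#'   `ail_dm`, `cw_frac`.
#' @param correlation Symmetric positive-semidefinite correlation matrix
#'   with unit diagonal, in the row order of `traits`.
#' @return An object of class `trait_config`.
#' @export
trait_config <- function(traits = NULL, correlation = default_trait_correlation()) {
  if (is.null(traits))
    traits <- data.frame(
      trait = c("cri", "asl_dm", "ail_dm", "cw_frac"),
      mean = c(42.8, 1.73, 14.8, 0.46),
      sd = c(3.85, 0.23, 2.95, 0.05),
      min = c(21.6, 1.2, 9.2, 0.30),
      max = c(55.6, 2.6, 25.3, 0.65),
      noise_sd = c(1.2, 0.07, 0.9, 0.015),
      stringsAsFactors = FALSE)
  stopifnot(is.data.frame(traits),
            all(c("trait", "mean", "sd", "min", "max", "noise_sd") %in% names(traits)))
  if (any(traits$min >= traits$max)) stop("trait min must be < max")
  if (any(traits$sd <= 0)) stop("trait sd must be > 0")
  if (any(traits$noise_sd < 0)) stop("reference noise sd must be >= 0")
  correlation <- as.matrix(correlation)
  k <- nrow(traits)
  if (!all(dim(correlation) == k)) stop("correlation matrix dimension mismatch")
  if (max(abs(correlation - t(correlation))) > 1e-10)
    stop("correlation matrix must be symmetric")
  if (max(abs(diag(correlation) - 1)) > 1e-10)
    stop("correlation matrix must have unit diagonal")
  ev <- eigen(correlation, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("correlation matrix is not positive semidefinite (min eigenvalue ",
         signif(min(ev), 3), ")")
  structure(list(traits = traits, correlation = correlation),
            class = "trait_config")
}

#' Generate a reference trait table with known latent values
#'
#' Samples the base traits (CrI, ASL, AIL, cell-wall fraction) from
#' moment-matched truncated normals joined by a Gaussian copula with the
#' configured correlation matrix, so the marginal means and sds equal
#' the configured values exactly despite the range truncation. Derived
#' traits follow by arithmetic: `total = ASL + AIL` exactly, proportions
#' = content / cell-wall fraction. Observed columns add Gaussian
#' measurement noise (truncated back to the configured range); the
#' noiseless truth is kept in `true_*` columns.
#'
#' @param n Number of samples (>= 2).
#' @param cfg A [trait_config()].
#' @param seed Integer seed (bit-identical output for identical inputs).
#' @return A reference table data.frame with observed columns `cri`,
#'   `asl_dm`, `ail_dm`, `total_dm`, `asl_cw`, `ail_cw`, `total_cw`,
#'   `cw_frac` and matching `true_*` columns.
#' @export
generate_reference_traits <- function(n, cfg = trait_config(), seed = 1) {
  stopifnot(inherits(cfg, "trait_config"))
  if (n < 2) stop("n must be >= 2")
  tr <- cfg$traits
  k <- nrow(tr)
  latent <- t(vapply(seq_len(k), function(i)
    tnorm_match(tr$mean[i], tr$sd[i], tr$min[i], tr$max[i]), numeric(2)))
  with_seed(seed, {
    L <- chol_psd(cfg$correlation)
    Z <- matrix(stats::rnorm(n * k), n, k) %*% L
    X <- vapply(seq_len(k), function(i)
      tnorm_from_z(Z[, i], latent[i, 1], latent[i, 2], tr$min[i], tr$max[i]),
      numeric(n))
    colnames(X) <- tr$trait
    E <- vapply(seq_len(k), function(i) stats::rnorm(n, 0, tr$noise_sd[i]),
                numeric(n))
    obs <- X + E
    for (i in seq_len(k)) obs[, i] <- pmin(pmax(obs[, i], tr$min[i]), tr$max[i])
    refs <- data.frame(id = sprintf("S%04d", seq_len(n)),
                       stringsAsFactors = FALSE)
    refs$true_cri <- X[, "cri"]
    refs$true_asl_dm <- X[, "asl_dm"]
    refs$true_ail_dm <- X[, "ail_dm"]
    refs$true_cw_frac <- X[, "cw_frac"]
    refs$true_total_dm <- refs$true_asl_dm + refs$true_ail_dm
    refs$true_asl_cw <- refs$true_asl_dm / refs$true_cw_frac
    refs$true_ail_cw <- refs$true_ail_dm / refs$true_cw_frac
    refs$true_total_cw <- refs$true_total_dm / refs$true_cw_frac
    refs$cri <- obs[, "cri"]
    refs$asl_dm <- obs[, "asl_dm"]
    refs$ail_dm <- obs[, "ail_dm"]
    refs$cw_frac <- obs[, "cw_frac"]
    refs$total_dm <- refs$asl_dm + refs$ail_dm
    refs$asl_cw <- refs$asl_dm / refs$cw_frac
    refs$ail_cw <- refs$ail_dm / refs$cw_frac
    refs$total_cw <- refs$total_dm / refs$cw_frac
    refs
  })
}

# upper-triangular factor tolerant of semidefinite matrices
chol_psd <- function(R) {
  e <- eigen(R, symmetric = TRUE)
  v <- pmax(e$values, 0)
  t(e$vectors %*% (t(e$vectors) * sqrt(v)))
}

# ---- spectra configuration -------------------------------------------

#' Default trait absorption-band table
#'
#' Gaussian signature bands (center, width in cm^-1; amplitude in
#' absorbance per trait unit) placed so each trait contributes signal in
#' several distinct wavelength blocks. Band placement is a free modeling
#' choice of the simulator, not a claim about lignin/cellulose band
#' assignments.
#'
#' @return Data.frame with columns `trait`, `center`, `width`, `amplitude`.
#' @export
default_band_table <- function() {
  data.frame(
    trait = c("cri", "cri", "cri",
              "asl_dm", "asl_dm",
              "ail_dm", "ail_dm", "ail_dm",
              "cw_frac", "cw_frac"),
    center = c(5100, 8400, 11400,
               4300, 6900,
               5600, 9100, 10600,
               4700, 7600),
    width = c(150, 200, 250,
              80, 120,
              100, 180, 220,
              90, 150),
    amplitude = c(0.0015, 0.0012, 0.0010,
                  0.030, 0.025,
                  0.0028, 0.0022, 0.0018,
                  0.18, 0.15),
    stringsAsFactors = FALSE)
}

#' Background (matrix) absorbance shape
#'
#' The broad trait-independent absorbance of the sample matrix: every
#' real NIR spectrum is dominated by a large smooth background on which
#' the analyte bands ride, and it is this common component that lets
#' scatter corrections (SNV/MSC) estimate the per-sample gain. Returned
#' at unit amplitude; scaled by the `background_amplitude` config field.
#'
#' @param grid Wavenumber grid (cm^-1).
#' @return Numeric vector, one value per grid point.
#' @export
background_spectrum <- function(grid) {
  g <- function(c0, w) exp(-0.5 * ((grid - c0) / w)^2)
  0.35 + 0.25 * g(5200, 700) + 0.35 * g(7000, 900) +
    0.30 * g(9800, 1200) + 0.15 * g(11500, 800)
}

#' Spectral artifact configuration
#'
#' Defines the simulated measurement process: absorbance of sample i at
#' wavenumber v is
#' `offset_i + slope_i * (v - mean(v))
#'  + m_i * (bg * B(v) + sum_t x_it * S_t(v)) + batch_shift + noise`,
#' with log-normal multiplicative gain `m_i = exp(N(0, scatter_log_sd))`,
#' a fixed broad matrix background `B` ([background_spectrum()], scaled
#' by `bg = background_amplitude`) and Gaussian trait signature bands
#' `S_t`. This is exactly the artifact family (additive offset, linear
#' tilt, multiplicative scatter) that COE/SSL/SNV/MSC are designed to
#' remove; the common background inside the gain is what makes the
#' per-sample gain estimable, as in real spectra.
#'
#' @param wn_lo,wn_hi Grid limits (cm^-1; default 4000-12000).
#' @param step Grid step (cm^-1, default 4).
#' @param bands Band table as in [default_band_table()].
#' @param offset_sd Additive offset sd (absorbance units).
#' @param slope_sd Baseline tilt sd (absorbance per cm^-1).
#' @param scatter_log_sd Log-sd of the multiplicative gain.
#' @param noise_sd Additive noise sd per channel.
#' @param noise_hetero Heteroscedasticity factor: the noise sd at a
#'   channel is `noise_sd * (1 + noise_hetero * |clean absorbance|)`.
#' @param background_amplitude Scale of the matrix background (default
#'   1; 0 removes the background so spectra are purely trait-driven).
#' @param n_batches Number of collection batches (default 6, as in the
#'   study's six sample lots).
#' @param batch_shift_sd Sd of the per-batch constant offset.
#' @param seed Integer seed.
#' @return An object of class `spectra_config`.
#' @export
spectra_config <- function(wn_lo = 4000, wn_hi = 12000, step = 4,
                           bands = default_band_table(),
                           offset_sd = 0.05, slope_sd = 1e-5,
                           scatter_log_sd = 0.1,
                           noise_sd = 0.002, noise_hetero = 0.5,
                           background_amplitude = 1,
                           n_batches = 6, batch_shift_sd = 0.02,
                           seed = 1) {
  if (wn_lo >= wn_hi) stop("wn_lo must be < wn_hi")
  if (step <= 0) stop("step must be positive")
  if (any(bands$width <= 0)) stop("band widths must be positive")
  for (s in c(offset_sd, slope_sd, scatter_log_sd, noise_sd, batch_shift_sd))
    if (s < 0) stop("artifact sds must be >= 0")
  structure(list(wn_lo = wn_lo, wn_hi = wn_hi, step = step, bands = bands,
                 offset_sd = offset_sd, slope_sd = slope_sd,
                 scatter_log_sd = scatter_log_sd, noise_sd = noise_sd,
                 noise_hetero = noise_hetero,
                 background_amplitude = background_amplitude,
                 n_batches = n_batches,
                 batch_shift_sd = batch_shift_sd, seed = as.integer(seed)),
            class = "spectra_config")
}

#' Generate NIR spectra from reference traits
#'
#' Builds log(1/R) absorbance spectra on the configured grid from the
#' `true_*` trait columns of a reference table, applying the artifact
#' model of [spectra_config()]. Batches are assigned as contiguous
#' sample blocks.
#'
#' @param refs Reference table from [generate_reference_traits()] (must
#'   carry a `true_<trait>` column for every trait in the band table).
#' @param cfg A [spectra_config()].
#' @return A [spectrum_set()].
#' @export
generate_nir_spectra <- function(refs, cfg = spectra_config()) {
  stopifnot(inherits(cfg, "spectra_config"))
  grid <- seq(cfg$wn_lo, cfg$wn_hi, by = cfg$step)
  bands <- cfg$bands
  if (any(bands$center < cfg$wn_lo | bands$center > cfg$wn_hi))
    stop("band center(s) outside the wavenumber grid: ",
         paste(bands$center[bands$center < cfg$wn_lo | bands$center > cfg$wn_hi],
               collapse = ", "))
  traits <- unique(bands$trait)
  miss <- setdiff(paste0("true_", traits), names(refs))
  if (length(miss) > 0)
    stop("reference table lacks columns: ", paste(miss, collapse = ", "))
  n <- nrow(refs); p <- length(grid)
  # trait signature matrix S: traits x points
  S <- t(vapply(traits, function(tn) {
    b <- bands[bands$trait == tn, , drop = FALSE]
    colSums(t(vapply(seq_len(nrow(b)), function(i)
      b$amplitude[i] * exp(-0.5 * ((grid - b$center[i]) / b$width[i])^2),
      numeric(p))))
  }, numeric(p)))
  X <- as.matrix(refs[, paste0("true_", traits), drop = FALSE])
  clean <- X %*% S
  clean <- sweep(clean, 2, cfg$background_amplitude * background_spectrum(grid), "+")
  with_seed(cfg$seed, {
    offset <- stats::rnorm(n, 0, cfg$offset_sd)
    slope <- stats::rnorm(n, 0, cfg$slope_sd)
    gain <- exp(stats::rnorm(n, 0, cfg$scatter_log_sd))
    shifts <- stats::rnorm(cfg$n_batches, 0, cfg$batch_shift_sd)
    batch <- sort(rep_len(seq_len(cfg$n_batches), n))
    noise_sd <- cfg$noise_sd * (1 + cfg$noise_hetero * abs(clean))
    noise <- matrix(stats::rnorm(n * p), n, p) * noise_sd
    m <- offset + outer(slope, grid - mean(grid)) + gain * clean +
      shifts[batch] + noise
    spectrum_set(grid, m, refs$id,
                 meta = data.frame(batch = paste0("B", batch),
                                   mode = "online", replicate = 1L))
  })
}

# ---- X-ray diffractograms --------------------------------------------

#' X-ray diffractogram simulation configuration
#'
#' The simulated curve is a constant background plus two crystalline
#' Gaussian peaks (the 200 reflection near 22.5 deg and the 110
#' reflection near 15.5 deg, at a fixed amplitude ratio) and one broad
#' amorphous component. The components are placed so the curve's
#' maximum falls on the 200 peak and its minimum between the 110 and
#' 200 peaks near 18.5 deg, as the Segal convention requires.
#'
#' @param tt_lo,tt_hi Scan limits in degrees 2-theta (defaults 10/45).
#' @param step Scan step (degrees, default 0.05).
#' @param peak_center,peak_width 200-peak center/width (deg).
#' @param p110_center,p110_width,p110_ratio Secondary 110 peak.
#' @param halo_center,halo_width Broad amorphous component.
#' @param crystalline_amplitude Amplitude of the 200 peak (counts).
#' @param background Constant background (counts).
#' @param noise_sd Additive noise sd (counts).
#' @param seed Integer seed.
#' @return An object of class `xrd_config`.
#' @export
xrd_config <- function(tt_lo = 10, tt_hi = 45, step = 0.05,
                       peak_center = 22.5, peak_width = 0.9,
                       p110_center = 15.5, p110_width = 1.1, p110_ratio = 0.55,
                       halo_center = 21.0, halo_width = 8,
                       crystalline_amplitude = 1000, background = 50,
                       noise_sd = 5, seed = 1) {
  if (tt_lo >= tt_hi) stop("tt_lo must be < tt_hi")
  if (peak_width <= 0 || halo_width <= 0 || p110_width <= 0)
    stop("widths must be positive")
  structure(list(tt_lo = tt_lo, tt_hi = tt_hi, step = step,
                 peak_center = peak_center, peak_width = peak_width,
                 p110_center = p110_center, p110_width = p110_width,
                 p110_ratio = p110_ratio,
                 halo_center = halo_center, halo_width = halo_width,
                 crystalline_amplitude = crystalline_amplitude,
                 background = background, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "xrd_config")
}

xrd_curve <- function(cfg, amorphous_amplitude) {
  tt <- seq(cfg$tt_lo, cfg$tt_hi, by = cfg$step)
  g <- function(c0, w) exp(-0.5 * ((tt - c0) / w)^2)
  I <- cfg$background +
    cfg$crystalline_amplitude * (g(cfg$peak_center, cfg$peak_width) +
                                   cfg$p110_ratio * g(cfg$p110_center, cfg$p110_width)) +
    amorphous_amplitude * g(cfg$halo_center, cfg$halo_width)
  list(two_theta = tt, intensity = I)
}

#' Generate a diffractogram with a prescribed Segal crystallinity
#'
#' Solves for the amorphous-component amplitude such that applying
#' [compute_cri()] to the noiseless curve returns `cri_true` (within
#' 0.1), then adds measurement noise.
#'
#' @param cri_true Target crystallinity index in (0, 100).
#' @param cfg An [xrd_config()].
#' @param id Sample id.
#' @return A [diffractogram()].
#' @export
generate_xrd <- function(cri_true, cfg = xrd_config(), id = NA_character_) {
  if (cri_true <= 0 || cri_true >= 100)
    stop("cri_true must lie strictly between 0 and 100")
  cri_of <- function(a) {
    cur <- xrd_curve(cfg, a)
    compute_cri(diffractogram(cur$two_theta, cur$intensity))$cri
  }
  upper <- cfg$crystalline_amplitude * 50
  f <- function(a) cri_of(a) - cri_true
  if (f(0) < 0)
    stop("target CrI ", cri_true, " exceeds the maximum achievable ",
         signif(cri_of(0), 4), " for this configuration")
  if (f(upper) > 0)
    stop("target CrI ", cri_true, " below the achievable range")
  a_star <- stats::uniroot(f, c(0, upper), tol = 1e-9)$root
  cur <- xrd_curve(cfg, a_star)
  I <- with_seed(cfg$seed,
                 cur$intensity + stats::rnorm(length(cur$intensity), 0, cfg$noise_sd))
  diffractogram(cur$two_theta, pmax(I, 0), id = id)
}

# ---- wet-chemistry raw records ---------------------------------------

#' Generate raw wet-chemistry records from reference traits
#'
#' Inverts the lignin arithmetic: builds (A205, volumes, masses) records
#' such that [asl_content()], [ail_content()], [cell_wall_fraction()]
#' and [lignin_proportion()] recover the `true_*` trait values exactly
#' when the noise sds are zero. Noise is mean-zero Gaussian on the UV
#' absorbance (relative) and on the weighed masses (absolute, g).
#'
#' @param refs Reference table with `true_asl_dm`, `true_ail_dm`,
#'   `true_cw_frac`.
#' @param protocol Constants from [wetchem_protocol()].
#' @param seed Integer seed.
#' @param a205_rel_sd Relative noise sd on A205 (default 0.01).
#' @param mass_sd Absolute noise sd on weighed masses in g (default 2e-4).
#' @return Data.frame of wet-chemistry records, one row per sample.
#' @export
generate_wetchem_raw <- function(refs, protocol = wetchem_protocol(), seed = 1,
                                 a205_rel_sd = 0.01, mass_sd = 2e-4) {
  need <- c("true_asl_dm", "true_ail_dm", "true_cw_frac")
  miss <- setdiff(need, names(refs))
  if (length(miss) > 0) stop("reference table lacks columns: ",
                             paste(miss, collapse = ", "))
  n <- nrow(refs); pr <- protocol
  a205 <- refs$true_asl_dm * pr$absorptivity * pr$path * pr$sample_mass /
    (100 * pr$filtrate_volume * pr$dilution)
  residue <- pr$ash_mass + refs$true_ail_dm * pr$sample_mass / 100
  sugar <- (1 - refs$true_cw_frac) * pr$dry_mass
  with_seed(seed, {
    a205_obs <- a205 * (1 + stats::rnorm(n, 0, a205_rel_sd))
    residue_obs <- residue + stats::rnorm(n, 0, mass_sd)
    sugar_obs <- sugar + stats::rnorm(n, 0, mass_sd)
    data.frame(id = refs$id,
               a205 = a205_obs,
               filtrate_volume = pr$filtrate_volume,
               dilution = pr$dilution,
               path = pr$path,
               sample_mass = pr$sample_mass,
               residue_mass = pmax(residue_obs, pr$ash_mass),
               ash_mass = pr$ash_mass,
               dry_mass = pr$dry_mass,
               soluble_sugar = pmin(pmax(sugar_obs, 0), pr$dry_mass * 0.999),
               stringsAsFactors = FALSE)
  })
}
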
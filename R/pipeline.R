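# End-to-end study orchestration: simulate -> calibrate (search) ->
# validate -> merge-refit -> compare, with manifests and CSV reports.

#' Collection-batch bookkeeping of the study design
#'
#' The sugarcane population was collected in six batches: 164, 162, 184,
#' 70 and 48 samples monthly from November 2018 to March 2019, plus 210
#' samples in December 2019. The first five collections (628 samples)
#' were also scanned offline after drying and grinding.
#'
#' @return Data.frame with columns `batch`, `month`, `n`, `offline`.
#' @export
collection_batches <- function() {
  data.frame(batch = paste0("B", 1:6),
             month = c("2018-11", "2018-12", "2019-01", "2019-02",
                       "2019-03", "2019-12"),
             n = c(164L, 162L, 184L, 70L, 48L, 210L),
             offline = c(rep(TRUE, 5), FALSE),
             stringsAsFactors = FALSE)
}

#' Pipeline configuration
#'
#' @param n_samples Number of simulated samples (default 300).
#' @param traits Trait columns to calibrate (default CrI and total
#'   lignin content, % dry mass).
#' @param pretreatments SCM names searched (default all ten).
#' @param n_intervals Interval blocks for the region search (default 4).
#' @param max_subsets Cap on region-subset candidates (default 15).
#' @param rank_max Maximum PLS rank swept (default 10).
#' @param gh_threshold GH outlier cutoff (default 3).
#' @param cv_k Internal cross-validation fold count (default 10).
#' @param n_validation External validation set size (default 60).
#' @param n_xrd Number of diffractogram fixtures written by
#'   [run_simulate()] (default 12).
#' @param seed Master seed; every generator and split derives its own
#'   substream from it.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(n_samples = 300,
                            traits = c("cri", "total_dm"),
                            pretreatments = setdiff(scm_methods, "NONE"),
                            n_intervals = 4, max_subsets = 15,
                            rank_max = 10, gh_threshold = 3.0,
                            cv_k = 10, n_validation = 60, n_xrd = 12,
                            seed = 42) {
  if (n_validation >= n_samples) stop("n_validation must be < n_samples")
  structure(list(n_samples = as.integer(n_samples), traits = traits,
                 pretreatments = pretreatments,
                 n_intervals = as.integer(n_intervals),
                 max_subsets = as.integer(max_subsets),
                 rank_max = as.integer(rank_max),
                 gh_threshold = gh_threshold, cv_k = as.integer(cv_k),
                 n_validation = as.integer(n_validation),
                 n_xrd = as.integer(n_xrd), seed = as.integer(seed)),
            class = "pipeline_config")
}

# derived substream seeds (kept far apart and below 2^31)
substream <- function(seed, k) (as.integer(seed) * 101L + k * 7919L) %% 2000000011L

write_manifest <- function(out_dir, command, config, seeds, files) {
  manifest <- list(command = command, created = format(Sys.time(), tz = "UTC"),
                   seeds = seeds, files = files,
                   config = unclass_config(config))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = I(17),
                              pretty = TRUE, null = "null"),
             file.path(out_dir, paste0(command, "_manifest.json")))
}

unclass_config <- function(cfg) {
  x <- unclass(cfg)
  lapply(x, function(v) if (is.data.frame(v) || is.matrix(v)) as.list(as.data.frame(v)) else v)
}

#' Simulate the study inputs and write them to disk
#'
#' Generates the reference traits, NIR spectra, diffractogram fixtures
#' and wet-chemistry records, writing `reference.csv`, `spectra.csv`
#' (wide CSV), `wetchem.csv`, per-sample `xrd/<id>.csv` files and a
#' manifest of seeds and configuration.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory.
#' @param force Overwrite existing outputs (default `FALSE`).
#' @param trait_cfg,spec_cfg Optional [trait_config()] / [spectra_config()]
#'   overrides (seed fields are replaced by the pipeline substreams).
#' @return Invisibly, a list with `refs`, `set`, `wetchem` and the file
#'   paths written.
#' @export
run_simulate <- function(config = pipeline_config(), out_dir, force = FALSE,
                         trait_cfg = trait_config(), spec_cfg = spectra_config()) {
  paths <- list(reference = file.path(out_dir, "reference.csv"),
                spectra = file.path(out_dir, "spectra.csv"),
                wetchem = file.path(out_dir, "wetchem.csv"),
                xrd = file.path(out_dir, "xrd"))
  if (!force && any(file.exists(unlist(paths[1:3]))))
    stop("outputs already exist in ", out_dir, "; use force = TRUE to overwrite")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- list(traits = substream(config$seed, 1L),
                spectra = substream(config$seed, 2L),
                wetchem = substream(config$seed, 3L),
                xrd = substream(config$seed, 4L))
  refs <- generate_reference_traits(config$n_samples, trait_cfg,
                                    seed = seeds$traits)
  spec_cfg$seed <- seeds$spectra
  set <- generate_nir_spectra(refs, spec_cfg)
  wet <- generate_wetchem_raw(refs, seed = seeds$wetchem)
  write_reference_table(refs, paths$reference)
  write_spectra(set, paths$spectra, "wide_csv")
  utils::write.csv(wet, paths$wetchem, row.names = FALSE)
  dir.create(paths$xrd, showWarnings = FALSE)
  n_xrd <- min(config$n_xrd, nrow(refs))
  for (i in seq_len(n_xrd)) {
    xc <- xrd_config(seed = substream(seeds$xrd, i))
    d <- generate_xrd(refs$true_cri[i], xc, id = refs$id[i])
    utils::write.csv(data.frame(two_theta = d$two_theta,
                                intensity = d$intensity),
                     file.path(paths$xrd, paste0(refs$id[i], ".csv")),
                     row.names = FALSE)
  }
  write_manifest(out_dir, "simulate", config, seeds,
                 lapply(paths, as.character))
  message("simulate: wrote ", nrow(refs), " samples x ", length(set$grid),
          " wavenumbers to ", out_dir)
  invisible(list(refs = refs, set = set, wetchem = wet, paths = paths))
}

#' Run the calibration model search
#'
#' Splits the samples into calibration and external-validation sets,
#' runs the exhaustive pretreatment-by-region search per trait on the
#' calibration set, writes the ranked equation records (winner first),
#' the winner's GH elimination report and the serialized winning models.
#'
#' @param set A [spectrum_set()] or path to a wide CSV.
#' @param refs Reference table (or CSV path).
#' @param config A [pipeline_config()].
#' @param out_dir Output directory.
#' @param verbose Progress messages per candidate.
#' @return Invisibly, a list with per-trait `records`, `model`,
#'   `split`, and the validation spectra/references for [run_validate()].
#' @export
run_calibrate <- function(set, refs, config = pipeline_config(), out_dir,
                          verbose = FALSE) {
  if (is.character(set)) set <- read_spectra(set, "wide_csv")
  if (is.character(refs)) refs <- read_reference_table(refs)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  al <- align_ids(set, refs)
  split <- split_calibration_validation(al$set$ids, config$n_validation,
                                        seed = substream(config$seed, 5L))
  s_cal <- al$set[split$cal]; s_val <- al$set[split$val]
  message("calibrate: ", length(split$cal), " calibration / ",
          length(split$val), " validation samples")
  cv <- cv_spec(config$cv_k, seed = substream(config$seed, 6L))
  blocks <- make_intervals(s_cal$grid, config$n_intervals)
  regions <- region_candidates(blocks, cap = config$max_subsets)
  results <- list()
  all_records <- list()
  for (trait in config$traits) {
    records <- search_models(s_cal, refs, trait,
                             pretreatments = config$pretreatments,
                             region_sets = regions,
                             rank_max = config$rank_max, cv = cv,
                             gh_threshold = config$gh_threshold,
                             verbose = verbose)
    best <- records[1, ]
    message("calibrate [", trait, "]: best ", best$scm, " | rank ",
            best$rank, " | R2cv ", signif(best$r2cv, 3), " | RPD ",
            signif(best$rpd, 3), " (", best$n_outliers, " GH outliers removed)")
    al_cal <- align_ids(s_cal, refs)
    keep <- !is.na(al_cal$refs[[trait]])
    model <- fit_calibration(al_cal$set[which(keep)],
                             al_cal$refs[[trait]][keep],
                             pretreatment_spec(best$scm),
                             if (identical(best$regions, "full")) NULL else
                               parse_regions(best$regions),
                             rank = best$rank,
                             gh_threshold = config$gh_threshold,
                             trait = trait)
    save_model(model, file.path(out_dir, paste0("model_", trait, ".json")))
    utils::write.csv(model$elimination,
                     file.path(out_dir, paste0("elimination_", trait, ".csv")),
                     row.names = FALSE)
    all_records[[trait]] <- records
    results[[trait]] <- list(records = records, model = model)
  }
  write_equation_records(do.call(rbind, all_records),
                         file.path(out_dir, "equation_records.csv"))
  write_manifest(out_dir, "calibrate", config,
                 list(split = substream(config$seed, 5L),
                      cv = substream(config$seed, 6L)),
                 list(records = "equation_records.csv"))
  invisible(list(results = results, split = split,
                 s_val = s_val, refs = refs))
}

#' Externally validate fitted models
#'
#' @param models Named list of `calibration_model`s (or paths to model
#'   JSON files), one per trait.
#' @param set Validation [spectrum_set()] (ids must be disjoint from
#'   each model's training set).
#' @param refs Reference table.
#' @param out_dir Output directory for `external_validation.csv`.
#' @return Invisibly, the validation report data.frame with columns
#'   `trait`, `n_ev`, `r2ev`, `rmsep`, `rpd_ev`.
#' @export
run_validate <- function(models, set, refs, out_dir = NULL) {
  if (length(set$ids) == 0) stop("empty validation set")
  rows <- lapply(names(models), function(trait) {
    m <- models[[trait]]
    if (is.character(m)) m <- load_model(m)
    al <- align_ids(set, refs)
    keep <- !is.na(al$refs[[trait]])
    ev <- external_validate(m, al$set[which(keep)], al$refs[[trait]][keep])
    message("validate [", trait, "]: R2ev ", signif(ev$r2ev, 3),
            " | RMSEP ", signif(ev$rmsep, 3), " | RPD ", signif(ev$rpd, 3))
    data.frame(trait = trait, n_ev = ev$n, r2ev = ev$r2ev,
               rmsep = ev$rmsep, rpd_ev = ev$rpd, stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(report, file.path(out_dir, "external_validation.csv"),
                     row.names = FALSE)
  }
  invisible(report)
}

#' Merge the validation set back and refit the winning equations
#'
#' @param calibrate_result Result of [run_calibrate()].
#' @param set Full [spectrum_set()] (calibration + validation samples).
#' @param refs Reference table.
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory for `merged_records.csv`.
#' @return Invisibly, the merged equation records (one row per trait).
#' @export
run_merge_refit <- function(calibrate_result, set, refs,
                            config = pipeline_config(), out_dir = NULL) {
  cv <- cv_spec(config$cv_k, seed = substream(config$seed, 7L))
  rows <- lapply(names(calibrate_result$results), function(trait) {
    best <- calibrate_result$results[[trait]]$records[1, ]
    rec <- merge_validation_and_refit(best, set, refs, trait,
                                      rank_max = config$rank_max, cv = cv,
                                      gh_threshold = config$gh_threshold)
    message("merge-refit [", trait, "]: N ", rec$n, " | R2cv ",
            signif(rec$r2cv, 3), " | RPD ", signif(rec$rpd, 3))
    rec
  })
  merged <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_equation_records(merged, file.path(out_dir, "merged_records.csv"))
  }
  invisible(merged)
}

#' Compare two calibration reports (e.g. online vs offline)
#'
#' Per shared trait: F-test on RMSEC and RMSECV, Fisher-z test on R^2
#' and R^2cv, starred at p < 0.05 (`*`) and p < 0.01 (`**`).
#'
#' @param report_a,report_b Equation-record data.frames (one row per
#'   trait, as returned by [run_merge_refit()] or the head rows of
#'   [search_models()] output), or paths to `equation_records.csv`
#'   style files.
#' @param out_dir Optional output directory for `comparison.csv`.
#' @return Invisibly, the comparison table: one row per trait and
#'   statistic with columns `trait`, `statistic`, `value_a`, `value_b`,
#'   `test`, `stat`, `p`, `stars`.
#' @export
run_compare <- function(report_a, report_b, out_dir = NULL) {
  norm <- function(r) {
    if (is.character(r)) {
      r <- utils::read.csv(r, check.names = FALSE, stringsAsFactors = FALSE)
      names(r) <- tolower(sub("^R2", "r2", names(r)))
      names(r)[names(r) == "n"] <- "n"
    }
    r
  }
  a <- norm(report_a); b <- norm(report_b)
  shared <- intersect(a$trait, b$trait)
  if (length(shared) == 0) stop("the two reports share no traits")
  rows <- list()
  for (tr in shared) {
    ra <- a[a$trait == tr, ][1, ]; rb <- b[b$trait == tr, ][1, ]
    for (st in c("rmsec", "rmsecv")) {
      cmp <- compare_rmse(ra[[st]], ra$n, rb[[st]], rb$n)
      rows[[length(rows) + 1]] <-
        data.frame(trait = tr, statistic = toupper(st),
                   value_a = ra[[st]], value_b = rb[[st]],
                   test = "F", stat = cmp$f, p = cmp$p, stars = cmp$stars,
                   stringsAsFactors = FALSE)
    }
    for (st in c("r2", "r2cv")) {
      cmp <- compare_r2(ra[[st]], ra$n, rb[[st]], rb$n)
      rows[[length(rows) + 1]] <-
        data.frame(trait = tr, statistic = toupper(st),
                   value_a = ra[[st]], value_b = rb[[st]],
                   test = "Fisher-z", stat = cmp$statistic, p = cmp$p,
                   stars = cmp$stars, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(out, file.path(out_dir, "comparison.csv"),
                     row.names = FALSE)
  }
  invisible(out)
}
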
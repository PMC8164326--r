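# Shared fixtures, all built in code.

# small deterministic spectrum set: smooth curves + per-sample structure
tiny_set <- function(n = 8, p = 60, seed = 123) {
  grid <- seq(4000, 4000 + 4 * (p - 1), by = 4)
  set.seed(seed)
  m <- t(vapply(seq_len(n), function(i)
    0.4 + 0.002 * i + 0.1 * exp(-0.5 * ((grid - 4100) / 30)^2) * i / n +
      rnorm(p, 0, 0.001), numeric(p)))
  spectrum_set(grid, m, sprintf("T%02d", seq_len(n)),
               meta = data.frame(batch = rep("B1", n), mode = "online",
                                 replicate = 1L))
}

# random spectra rows for algebraic property checks
random_rows <- function(n, p, seed) {
  set.seed(seed)
  matrix(rnorm(n * p, mean = 0.5, sd = 0.3), n, p)
}

# memoised end-to-end study run under default conditions, shared by the
# recovery and consistency tests so the expensive search runs once
.e2e_cache <- new.env(parent = emptyenv())
e2e_run <- function() {
  if (!is.null(.e2e_cache$res)) return(.e2e_cache$res)
  cfg <- pipeline_config(seed = 42)
  dir <- file.path(tempdir(), "nirscane-e2e")
  sim <- run_simulate(cfg, out_dir = dir, force = TRUE)
  cal <- suppressMessages(run_calibrate(sim$set, sim$refs, cfg,
                                        out_dir = file.path(dir, "cal")))
  models <- lapply(cal$results, `[[`, "model")
  val <- suppressMessages(run_validate(models, cal$s_val, sim$refs))
  .e2e_cache$res <- list(cfg = cfg, sim = sim, cal = cal, val = val, dir = dir)
  .e2e_cache$res
}
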
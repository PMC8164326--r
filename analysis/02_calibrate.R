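#!/usr/bin/env Rscript
# Step 2 — calibration model search.
#
# Splits the simulated population into calibration (240) and external
# validation (60) sets, then searches all 10 pretreatments x 15
# wavelength-region subsets per trait: each candidate gets its own GH
# outlier screening and cross-validated PLS rank selection, and records
# are ranked by RMSECV. Writes the ranked equation table and the
# serialized winning models.

library(nirscane)

cfg <- pipeline_config(seed = 42)
set <- read_spectra("scratch/sim/spectra.csv", "wide_csv")
refs <- read_reference_table("scratch/sim/reference.csv")

cal <- run_calibrate(set, refs, cfg, out_dir = "scratch/cal")

dir.create("results", showWarnings = FALSE)
top <- do.call(rbind, lapply(cfg$traits, function(tr)
  head(cal$results[[tr]]$records, 5)))
write_equation_records(top, "results/02_top_equations.csv")

cat("\nTop calibration equations per trait (of",
    nrow(cal$results[[1]]$records), "candidates each):\n")
print(top[, c("trait", "scm", "regions", "rank", "n", "r2", "r2cv", "rpd")],
      digits = 3, row.names = FALSE)
saveRDS(cal, "scratch/cal/cal_state.rds")   # working state for steps 3-5
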
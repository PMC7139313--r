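#!/usr/bin/env Rscript

# Simulate one example patient per archetype with the default study
# conditions (five q21d doses, weekly draws, lognormal noise CV 0.15) and
# write their lab series plus the ground-truth event days. These files feed
# 03_detect_events.R.

suppressPackageStartupMessages(library(tolbreak))

SEED <- 20260101L
archetypes <- c("responder", "non_responder", "paradox",
                "autocrine_progressor", "irae_coupled")

out_dir <- "results/simulated"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

panel <- simulator_marker_panel()
ground_truth <- list()
all_labs <- list()
for (i in seq_along(archetypes)) {
  arch <- archetypes[i]
  sim <- generate_patient(scenario_config(arch, seed = SEED + i),
                          patient_id = arch, include_dense = FALSE)
  all_labs[[arch]] <- sim$patient$labs
  ground_truth[[arch]] <- sim$ground_truth
  cat(sprintf("%-22s kill days: %-8s irAE days: %s\n", arch,
              paste(round(sim$ground_truth$kill_days, 1), collapse = ","),
              paste(round(sim$ground_truth$irae_days, 1), collapse = ",")))
}

write_labs_csv(dplyr::bind_rows(all_labs), file.path(out_dir, "labs.csv"),
               panel = panel)
readr::write_csv(panel, file.path(out_dir, "markers.csv"))
jsonlite::write_json(ground_truth, file.path(out_dir, "ground_truth.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
cat("\nWrote", file.path(out_dir, c("labs.csv", "markers.csv",
                                    "ground_truth.json")), "\n")
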
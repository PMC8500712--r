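#!/usr/bin/env Rscript
# Calibrate the nearby-interaction cutoffs on the social cohort: compare its
# pairwise-distance histogram and sub-cutoff run durations against a
# random-regrouping null ensemble (fish that never swam together), with
# Holm-corrected per-bin tests, then pick conservative cutoffs one bin
# inside each significant band.

suppressPackageStartupMessages(library(shoalbout))

arena <- arena_spec()
seed <- 20260927
paths <- Sys.glob("results/cohorts/social_sim_*.csv")
stopifnot(length(paths) >= 4)
cohort <- lapply(paths, function(p) fill_gaps(read_group(p, arena)))

ne <- build_null_groups(cohort, n = 200, seed = seed)
cat(sprintf("null ensemble: %d members from %d source groups\n",
            length(ne$members), length(cohort)))

dcal <- distance_calibration(cohort, ne)
utils::write.csv(calibration_table(dcal),
                 "results/distance_calibration.csv", row.names = FALSE)
cat("distance: significant bins (cm):",
    paste(dcal$significant, collapse = " "), "\n")

dist_cutoff <- if (length(dcal$significant)) dcal$selected_cutoff else 5
ucal <- duration_calibration(cohort, ne, dist_cutoff = dist_cutoff)
utils::write.csv(calibration_table(ucal),
                 "results/duration_calibration.csv", row.names = FALSE)
cat("duration: significant bins (s):",
    paste(ucal$significant, collapse = " "), "\n")
dur_cutoff <- if (length(ucal$significant)) ucal$selected_cutoff else 4

jsonlite::write_json(list(dist_cutoff_cm = dist_cutoff,
                          dur_cutoff_s = dur_cutoff,
                          n_null = length(ne$members), seed = seed),
                     "results/cutoffs.json", auto_unbox = TRUE,
                     pretty = TRUE)
cat(sprintf("selected cutoffs: %.1f cm, %.1f s -> results/cutoffs.json\n",
            dist_cutoff, dur_cutoff))
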
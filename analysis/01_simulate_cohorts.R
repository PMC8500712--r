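#!/usr/bin/env Rscript
# Build the two synthetic study cohorts that the downstream analyses use:
#  - "social": groups whose fish engage nearby neighbours, hold a preferred
#    separation and slow down while engaged (surface-fish-like behaviour);
#  - "circler": asocial groups with a strong one-way turning bias
#    (cavefish-like behaviour).
# Each group is a 300-s, 20-fps, four-fish recording in a 50.8 x 25.4 cm
# arena, written in the standard trajectory CSV format with a params sidecar.

suppressPackageStartupMessages(library(shoalbout))

out_dir <- "results/cohorts"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
seed <- 20260927
n_groups <- 8

social_params <- sim_params(attraction_strength = 0.05,
                            deceleration_factor = 0.6, turn_bias = 0.5)
circler_params <- sim_params(turn_bias = 0.8)

write_cohort <- function(params, name, seed) {
  cohort <- simulate_cohort(params, n_groups = n_groups, seed = seed)
  for (rec in cohort) {
    write_group(rec, file.path(out_dir, paste0(name, "_", rec$group_id,
                                               ".csv")))
  }
  p <- unclass(params)
  p$arena <- p$arena[c("width", "height", "frame_rate")]
  jsonlite::write_json(c(p, list(n_groups = n_groups, master_seed = seed)),
                       file.path(out_dir, paste0(name, "_params.json")),
                       auto_unbox = TRUE, pretty = TRUE)
  cohort
}

social <- write_cohort(social_params, "social", seed)
circler <- write_cohort(circler_params, "circler", seed + 1)

v_soc <- mean(sapply(social, group_mean_speed))
v_cir <- mean(sapply(circler, group_mean_speed))
cat(sprintf("wrote %d social + %d circler groups to %s\n",
            n_groups, n_groups, out_dir))
cat(sprintf("mean group speed: social %.2f cm/s, circler %.2f cm/s\n",
            v_soc, v_cir))
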
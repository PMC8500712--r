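#!/usr/bin/env Rscript
# Downstream statistics on the per-fish table: AIC-selected factorial GLM of
# adjusted interaction time against cohort and sex-free nuisance factors,
# the logarithmic-curve correlation between turning bias and interaction
# time, and Holm-adjusted two-sample tests.

suppressPackageStartupMessages(library(shoalbout))

fish <- utils::read.csv("results/fish_metrics.csv")
fish$arena_half <- ifelse(fish$position_index >= stats::median(
  fish$position_index), "centre", "edge")

# Factorial comparison: adjusted interaction time ~ cohort x location habit
res <- compare_factorial(fish, "total_adjusted_s",
                         c("cohort", "arena_half"))
cat("chosen model:", res$chosen, "\n")
print(res$candidates)

# Log-curve correlation of turning bias with interaction time, pooled
lcf <- log_curve_fit(fish$turning_bias_index, fish$total_adjusted_s)
cat(sprintf("log-curve fit: adj R^2 = %.3f, F = %.2f, p = %.3g, slope = %.2f\n",
            lcf$adj_r2, lcf$f, lcf$p, lcf$coefficients[2]))

# Two-sample contrasts as one Holm family
soc <- fish[fish$cohort == "social", ]
cir <- fish[fish$cohort == "circler", ]
fam <- paired_and_rank_tests(list(
  list(x = soc$total_adjusted_s, y = cir$total_adjusted_s,
       name = "adjusted_duration"),
  list(x = soc$bout_count, y = cir$bout_count, name = "bout_count"),
  list(x = soc$turning_bias_index, y = cir$turning_bias_index,
       name = "turning_bias")), test = "wilcoxon")
print(fam$contrasts)

jsonlite::write_json(list(
  chosen_model = res$chosen,
  aic = stats::setNames(as.list(res$candidates$aic), res$candidates$formula),
  log_curve = list(adj_r2 = lcf$adj_r2, p = lcf$p,
                   slope = unname(lcf$coefficients[2])),
  contrasts = fam$contrasts),
  "results/group_statistics.json", auto_unbox = TRUE, pretty = TRUE)
cat("wrote results/group_statistics.json\n")
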
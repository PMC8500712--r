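# shoalbout

Trajectory-based quantification of **social-like nearby interactions** and
**repetitive turning bias** in four-fish group recordings.

Frame-averaged shoaling statistics (inter-individual distance, IID;
nearest-neighbour distance, NND) can be blind to weak, episodic sociality,
especially in the dark where fish track each other by flow sensing rather
than vision. `shoalbout` implements an event-level measure instead: a
*nearby-interaction bout* is a maximal run of frames in which a pair of
fish stays within a distance cutoff (default 5 cm) for at least a duration
cutoff (default 4 s). Each bout is corrected for chance proximity by
subtracting the *passing-by duration*

    PbDur = E(|L|) / E(|Vr|) = (4R/π) / (4V/π) = R / V,

the expected transit time of one fish crossing the R-cm disc around
another when both swim independently at the group mean speed V (mean chord
2R·sin ω, mean relative speed 2V·sin(θ/2), ω and θ uniform on (0, π)).
Cutoffs are not taken on faith: they are calibrated by comparing the actual
recordings against a **random-regrouping null ensemble** — virtual groups
of four fish that never swam together — with Holm-corrected per-bin tests,
then choosing the second most extreme significant bin.

Repetitive turning is scored from signed turning angles at 0.25-s steps,
θ = atan2(v1 × v2, v1 · v2), summarised by the turning-bias index
|log2(N1/N2)| over clockwise (N1) and anticlockwise (N2) step counts.

The package also ships a first-class agent-based simulator of four-fish
groups (correlated random walk with tunable attraction, deceleration on
approach, turn-direction bias, and tracker-like identity gaps), so every
pipeline stage is testable without raw videos, plus downstream statistics:
AIC-selected factorial GLMs with Holm post hoc contrasts, logarithmic-curve
fits, intraclass-correlation repeatability, and paired/rank tests.

## Worked example

```r
library(shoalbout)

# a social group: fish engage neighbours, slow down while engaged
p <- sim_params(seed = 7, attraction_strength = 0.05,
                deceleration_factor = 0.6)
rec <- simulate_group(p)
rec
#> <group_recording> sim1 (synthetic): 4 fish x 6000 frames @ 20 fps, arena 50.8 x 25.4 cm
#>   fish: fish1, fish2, fish3, fish4 | missing%: 1.1, 1.1, 1.0, 1.0

V <- group_mean_speed(rec)
pbm <- passing_by_duration(V, cutoff = 5)
cat(sprintf("V = %.2f cm/s, PbDur = %.2f s\n", V, pbm$pbdur))
#> V = 1.91 cm/s, PbDur = 2.62 s

bouts <- detect_group_bouts(rec, dist_cutoff = 5, dur_cutoff = 4)
summ <- adjust_and_summarize(bouts, pbm, names(rec$trajectories))
summ$per_fish
#>   fish_id total_adjusted_s bout_count
#> 1   fish1         357.7351          3
#> 2   fish2         339.7635          4
#> 3   fish3         344.0135          4
#> 4   fish4         208.5284          1

ts <- turning_angles(rec$trajectories$fish1)
cat(sprintf("fish1 turning bias = %.2f (N1 = %d, N2 = %d)\n",
            turning_bias_index(ts), ts$n_cw, ts$n_ccw))
#> fish1 turning bias = 1.01 (N1 = 398, N2 = 800)

speed_profile(rec, "fish1", bouts)[c("during", "out")]
#> $during 1.79   $out 3.09        # cm/s: engaged fish slow down
```

The four fish here accumulate 209–358 s of PbDur-adjusted interaction time
out of 300 s (overlapping partners are counted per bout), their speed drops
from 3.1 to 1.8 cm/s during bouts — the planted deceleration — and fish1's
bias index of ~1 reflects the one-way orbiting that station-keeping around
a partner induces even with balanced turn kicks.

## The analysis workflow

Numbered drivers under `analysis/` run the full study on synthetic cohorts
and write tidy tables under `results/`:

| script | what it does |
|---|---|
| `01_simulate_cohorts.R` | simulate a social and a biased-circler cohort, write trajectory CSVs |
| `02_calibrate_cutoffs.R` | null ensemble + distance/duration calibration, select cutoffs |
| `03_detect_interactions.R` | bouts, PbDur adjustment, per-fish metrics, speed profiles |
| `04_turning_bias.R` | turning-bias indices and across-session ICC repeatability |
| `05_group_statistics.R` | AIC-selected GLM, log-curve correlation, Holm-adjusted rank tests |

Run them in order from the repository root, e.g.
`Rscript analysis/01_simulate_cohorts.R`.

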
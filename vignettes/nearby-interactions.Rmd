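---
title: "Quantifying nearby interactions and turning bias in four-fish groups"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying nearby interactions and turning bias in four-fish groups}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shoalbout)
```

## The problem

Classic shoaling statistics — the inter-individual distance (IID, the mean
of all pairwise distances in a group) and the nearest-neighbour distance
(NND) — average over a whole recording and can miss weak, episodic
sociality. In the dark, where fish cannot see each other, groups of four
fish may drift close together by chance, follow one another briefly, or
ignore each other entirely; a frame-averaged distance does not separate
these. This package implements an event-level alternative: the **nearby
interaction**, a pairwise proximity bout in which two fish stay within a
distance cutoff for at least a duration cutoff, corrected for the time two
independently swimming fish would spend that close purely in passing.

The unit of analysis is a `group_recording`: four equal-length trajectories
(x, y in cm per frame) in a known arena, by default 50.8 × 25.4 cm at 20
frames per second for 300 s. Upstream tracking (video, identity assignment)
is out of scope; the input is the tracker's per-frame coordinate table.

## The pipeline

1. **Ingest and repair** (`read_group`, `trim_lead_in`, `fill_gaps`). The
   first minute of a raw recording is discarded (the release of the fish
   agitates the water). Frames where the tracker lost an identity are
   filled by constant-velocity straight-line interpolation between the
   flanking observations — the unique path with constant speed and heading,
   which is what averaging velocity and direction across a gap means. Gaps
   touching the recording edge have only one flank; these hold the nearest
   observed position constant. That edge rule is this package's choice (the
   published procedure needs both flanks and does not define the edge
   case); edge gaps are rare (< 1% of frames at realistic loss rates) and
   the held position contributes zero speed, which slightly biases speeds
   downward at the margins.

2. **Bout detection** (`detect_bouts`). For each of the 6 pairs, maximal
   runs of frames with distance ≤ 5 cm lasting ≥ 4 s become bouts. Frames
   are 0-based and bout spans half-open `[start, end)`; a 4-s bout at 20
   fps is exactly 80 frames, and a 79-frame run is rejected.

3. **Passing-by correction** (`passing_by_duration`,
   `adjust_and_summarize`). Two fish swimming independently at the group
   mean speed V with a uniform heading difference θ have mean relative
   speed E(|Vr|) = 4V/π (from |Vr| = 2V·sin(θ/2)); a straight crossing of a
   5-cm disc at a uniform chord angle ω covers E(|L|) = 4·5/π cm (from
   |L| = 2·5·sin ω). Their ratio, PbDur = 5 cm / V, is the expected
   by-chance transit time, computed once per group from the full analysis
   window and subtracted from every bout (floored at zero). A group
   swimming 1 cm/s has PbDur = 5 s; one at 2.5 cm/s has 2 s.
   `pbdur_mc_oracle` verifies both expectations by Monte Carlo.

   Per-fish totals sum each pairwise bout the fish participates in, without
   deduplicating simultaneous bouts with different partners: simple,
   monotone in the cutoffs, and consistent with subtracting PbDur from each
   bout. A fish interacting with two partners at once genuinely
   accumulates two bouts' worth of time under this convention.

4. **Cutoff calibration** (`build_null_groups`, `distance_calibration`,
   `duration_calibration`, `select_cutoff`). The chance baseline is a
   random-regrouping null: virtual groups assembled from four fish that
   never swam together (four distinct source groups, one fish each,
   time-aligned by frame). Per 1-cm distance bin (and per 1-s duration on
   an inverse-cumulative run-count curve), actual groups are compared with
   null members by t-tests with Holm step-down correction across the
   candidate window (1–10 cm, 1–15 s by default; testing every bin of the
   full 0–56 cm range would dilute power). A bin counts as significant
   separation only when the actual data *exceed* the null — cutoffs are
   calibrated on an excess of nearby events, and a deficit carries no
   evidence of interaction. The selected cutoff is the second most extreme
   significant bin (second-longest distance, second-shortest duration), a
   deliberately conservative choice one bin inside each band.

   **Variance model.** Null members reuse the same fish, so they are
   positively correlated and treating 200 members as independent
   observations understates the variance of the null mean. The calibration
   therefore estimates that variance with a delete-one-source-group
   jackknife (leave out all members touching one source group, recompute
   the mean, take the scaled spread of the leave-one-out means), and uses
   n_groups − 1 degrees of freedom. With this variance model, cohorts of
   independent random walkers pass both calibrations clean in ≥ 95% of
   seeded repeats; with the naive member-wise variance they do not.

5. **Speed profiles** (`speed_profile`). Mean speed during bouts, in the
   4-s windows before and after each bout, and outside all of these.
   Flanking windows truncate at recording edges; frames inside any bout
   always count as `during`, and the `after` of one bout wins over the
   `before` of the next. Speeds are central finite differences of position
   (second-order accurate, no phase lag), with one-sided differences at the
   two ends and no smoothing.

6. **Turning bias** (`turning_angles`, `turning_bias_index`). Positions are
   sampled every 5 frames (0.25 s); for consecutive displacement vectors v1
   and v2 the signed turning angle is θ = atan2(v1 × v2, v1 · v2). The
   two-argument arctangent is used deliberately: the single-argument
   arctangent of the cross/dot quotient loses the quadrant and the sign.
   N1 counts clockwise (negative) steps, N2 anticlockwise; the bias index
   is |log2((N1 + ½)/(N2 + ½))|. The Haldane–Anscombe ½ keeps a
   perfect circler finite (a fish that never turns one way scores
   log2((N + ½)/½) ≈ 10 for N ≈ 500 rather than infinity). Steps whose
   displacement is below 1e-6 cm (a stationary fish) are excluded from both
   counts rather than scored as zero-angle turns. The index is invariant
   under rotation, translation and reflection of the coordinates, so the
   y-axis convention (image vs mathematical) affects only the sign of
   displayed θ, never the index.

7. **Downstream statistics** (`compare_factorial`, `log_curve_fit`,
   `icc_repeatability`, `paired_and_rank_tests`). Factorial comparisons fit
   the additive and interaction (generalized) linear models, select by AIC,
   and report Holm-adjusted pairwise cell contrasts. Gaussian is the
   default family (configurable); the published analyses do not state
   links. The turning-bias/interaction relationship is fit as y on log(x),
   adding 0.01 to x only when zeros are present (balanced turners have
   index exactly 0). Repeatability across sessions is ICC(A,1) — two-way,
   absolute agreement, single measures — computed from hand-derived mean
   squares with an F = MSR/MSE significance test; the consistency variant
   ICC(C,1) is exposed because the published "interclass kappa" does not
   pin the variant down.

## The synthetic generator

`simulate_group` is a first-class module, not a fixture: a correlated
random walk whose dials map one-to-one onto the phenotypes the pipeline
measures.

* **Turning**: per frame the heading receives a kick of half-normal
  magnitude with scale (1 − persistence)·π/2 and a sign that is
  anticlockwise with probability `turn_bias`. At the defaults (persistence
  0.9, 20 fps) a balanced fish wanders; `turn_bias` 0.8–0.9 produces the
  tight repetitive circling seen in strongly lateralized fish.
* **Sociality**: when the nearest neighbour comes within `sensing_radius`
  (5 cm — a plausible lateral-line range and the bout cutoff), the fish
  engages for at least `min_dwell_s` (5 s), steering toward its partner
  with weight `attraction_strength` and multiplying its speed by
  `deceleration_factor`. Engaged fish hold a `preferred_distance` (2 cm,
  about a body length): they steer toward the partner when farther, away
  when closer. Without the preferred separation, attracted agents collapse
  onto coincident points, which no real fish pair does.
* **Environment**: specular wall reflection plus a 1-cm steering margin
  keeps positions in the arena; per-frame speeds are Gaussian around
  `base_speed` (3 cm/s, a realistic cruising speed for a 4-cm fish),
  clamped at base + 5 sd. Identity gaps are injected at `gap_rate` (1% per
  frame, matching ≥ 97% tracking success) and either left as NA or filled
  immediately.

Defaults (300 s, 20 fps, four fish, 50.8 × 25.4 cm) reproduce the recording
conditions of the group assay; cohorts default to 18 groups. What the
generator does **not** emulate: hydrodynamic coupling, body posture,
burst-and-glide gaits, wall thigmotaxis gradients, learning, or any
calibration to real fish. Passing tests therefore demonstrate that the
pipeline's estimators recover planted behavioural structure and stay
calibrated under its null — not that real fish behave like the agents.

## Numerical choices and degenerate inputs

* Bout length comparisons use a 1e-9 guard so a run of exactly
  `dur_cutoff × frame_rate` frames qualifies despite floating-point noise.
* A stationary group (V = 0) has no defined PbDur and is an error, not a
  silent zero.
* Histogram bins are 1 cm wide, labelled by their upper edge, with the last
  bin absorbing the arena diagonal (≈ 56.8 cm); the duration grid is 1 s.
  Both are configurable; whole-cm and whole-s bands are what the selection
  rules quote.
* With only one Holm-significant bin the selector returns it with a
  warning; with none it fails loudly ("calibration failed") rather than
  guessing.
* Teleport-like jumps (> 20 cm/frame) in input tables trigger warnings, not
  repairs — identity switches are an upstream correction problem.
* `classify_pair_motion` thresholds (δ = 0.5 cm per 1-s window, alignment
  cos 60°) are free parameters exposed as arguments; the five category
  names come from the assay, the criteria are this package's.

## Problem sizes

The bundled analyses and tests run cohorts of 8–18 groups of 300-s
recordings, null ensembles of 100–200 members, 20-seed calibration repeats,
and 10^5-draw Monte-Carlo checks; a full run of the numbered analysis
scripts takes well under a minute on one core, and the complete test suite
a few minutes.

## Known limitations

* Per-fish totals double-count simultaneous bouts with different partners
  (documented convention; the published method does not specify overlap
  handling).
* The passing-by model assumes straight crossings at the group mean speed;
  strongly speed-heterogeneous groups get a single group-level PbDur.
* Calibration power at very small cohort sizes (< 8 groups) is limited;
  the selector then falls back to the conventional 5 cm / 4 s cutoffs in
  `run_study`.
* The five-way pair-motion classification is heuristic and intended for
  descriptive summaries, not inference.
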
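# Run code with a temporary RNG state when a seed is supplied.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}

#' Build the random-regrouping null ensemble
#'
#' Assembles virtual four-fish groups by sampling, for each member, four
#' distinct source groups and one fish from each, so that no two fish in a
#' member ever physically swam together. Trajectories are copied unmodified
#' and time-aligned by frame index (all recordings truncated to the shortest
#' length). Compositions may repeat across members; within-member
#' distinctness of source groups is the only hard constraint.
#'
#' @param recordings List of at least 4 gap-filled [group_recording()]s with
#'   a common arena and frame rate.
#' @param n Number of null members. Default 1280.
#' @param seed Integer seed for reproducible sampling.
#' @return An object of class `null_ensemble`: list with `members` (list of
#'   [group_recording()]s labelled `null_<i>`), `provenance` (data.frame
#'   member, slot, source_group, source_fish), `seed`.
#' @export
build_null_groups <- function(recordings, n = 1280, seed = NULL) {
  if (length(recordings) < 4L) {
    stop("need at least 4 source groups, got ", length(recordings))
  }
  nf <- min(vapply(recordings, n_frames, integer(1)))
  arena <- recordings[[1]]$arena
  prov <- with_seed(seed, {
    do.call(rbind, lapply(seq_len(n), function(m) {
      gs <- sample.int(length(recordings), 4L, replace = FALSE)
      fs <- vapply(gs, function(g) sample.int(4L, 1L), integer(1))
      data.frame(member = m, slot = 1:4, source_group = gs, source_fish = fs)
    }))
  })
  members <- lapply(seq_len(n), function(m) {
    rows <- prov[prov$member == m, ]
    trajs <- lapply(seq_len(4L), function(k) {
      src <- recordings[[rows$source_group[k]]]$trajectories[[rows$source_fish[k]]]
      keep <- seq_len(nf)
      fish_trajectory(paste0("s", rows$source_group[k], "f",
                             rows$source_fish[k], "_", k),
                      src$x[keep], src$y[keep], src$missing[keep],
                      src$frame_rate)
    })
    group_recording(trajs, arena, group_id = paste0("null_", m),
                    population_label = "synthetic")
  })
  structure(list(members = members, provenance = prov, seed = seed),
            class = "null_ensemble")
}

#' Holm step-down adjustment
#'
#' Familywise-error control by the Holm step-down rule (via
#' [stats::p.adjust()]): sort p ascending, multiply the i-th by (m - i + 1),
#' enforce monotonicity, cap at 1, restore the input order.
#'
#' @param p Numeric vector of raw p-values.
#' @return Adjusted p-values, same length and order.
#' @export
holm_adjust <- function(p) {
  stats::p.adjust(p, method = "holm")
}

# Shared t-test + Holm machinery over a bin-by-unit frequency matrix.
#
# Null members are regroupings of the same fish, so they are positively
# correlated and s^2/n_members understates the variance of the null mean.
# When the ensemble's provenance is available, the null-mean variance is
# estimated by a delete-one-source-group jackknife instead; without
# provenance the test falls back to plain Welch across members.
calibrate_bins <- function(actual_mat, null_mat, values, test_idx, alpha,
                           rule, provenance = NULL) {
  m_act <- colMeans(actual_mat)
  m_nul <- colMeans(null_mat)
  ci <- function(mat) {
    se <- apply(mat, 2, stats::sd) / sqrt(nrow(mat))
    q <- stats::qt(0.975, df = nrow(mat) - 1)
    rbind(lower = colMeans(mat) - q * se, upper = colMeans(mat) + q * se)
  }
  jack_var <- NULL
  if (!is.null(provenance)) {
    groups <- sort(unique(provenance$source_group))
    if (length(groups) > 4) {
      # members not touching group g, per g
      omit <- lapply(groups, function(g) {
        bad <- unique(provenance$member[provenance$source_group == g])
        setdiff(seq_len(nrow(null_mat)), bad)
      })
      if (all(lengths(omit) > 0)) {
        jack_var <- vapply(seq_along(values), function(j) {
          loo <- vapply(omit, function(idx) mean(null_mat[idx, j]),
                        numeric(1))
          G <- length(loo)
          (G - 1) / G * sum((loo - mean(loo))^2)
        }, numeric(1))
      }
    }
  }
  p_raw <- rep(NA_real_, length(values))
  n_a <- nrow(actual_mat)
  for (j in test_idx) {
    a <- actual_mat[, j]; b <- null_mat[, j]
    p_raw[j] <- if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      1
    } else if (!is.null(jack_var)) {
      se2 <- stats::var(a) / n_a + jack_var[j]
      if (se2 == 0) 1 else {
        tstat <- (mean(a) - mean(b)) / sqrt(se2)
        2 * stats::pt(abs(tstat), df = n_a - 1, lower.tail = FALSE)
      }
    } else {
      tryCatch(stats::t.test(a, b)$p.value, error = function(e) 1)
    }
  }
  p_holm <- rep(NA_real_, length(values))
  p_holm[test_idx] <- holm_adjust(p_raw[test_idx])
  # a bin counts as significant separation only when the actual data exceed
  # the chance expectation: cutoffs are calibrated on an excess of nearby
  # events, not a deficit
  excess <- m_act[test_idx] > m_nul[test_idx]
  sig <- values[test_idx][which(p_holm[test_idx] < alpha & excess)]
  curve <- structure(list(values = values,
                          actual_mean = m_act, actual_ci = ci(actual_mat),
                          null_mean = m_nul, null_ci = ci(null_mat),
                          p_raw = p_raw, p_holm = p_holm,
                          significant = sig, alpha = alpha, rule = rule,
                          selected_cutoff = NA_real_),
                     class = "calibration_curve")
  if (length(sig) > 0) {
    curve$selected_cutoff <- select_cutoff(curve, rule)
  }
  curve
}

#' Calibrate the distance cutoff against the null ensemble
#'
#' Bins every pairwise distance of every frame into 1-cm classes and
#' compares, bin by bin within a candidate window, the per-group relative
#' frequencies of the actual recordings against the per-member frequencies
#' of the null ensemble (per-bin t-tests, Holm-corrected). Groups, not
#' frames, are the test unit; because null members reuse the same fish, the
#' null-mean variance is estimated by a delete-one-source-group jackknife
#' rather than by treating members as independent. The selected cutoff is the second-longest significant
#' distance -- a conservative choice one bin inside the significant band.
#'
#' @param actual List of at least 2 gap-filled [group_recording()]s.
#' @param null A `null_ensemble` from [build_null_groups()].
#' @param bin_edges Histogram edges in cm. Default 0:57 (1-cm bins covering
#'   the arena diagonal); a bin is labelled by its upper edge.
#' @param test_window Range of bin labels (cm) entering the Holm family.
#'   Default c(1, 10).
#' @param alpha Familywise significance level. Default 0.05.
#' @return A `calibration_curve` (see [select_cutoff()]); `values` are bin
#'   upper edges in cm.
#' @export
distance_calibration <- function(actual, null, bin_edges = 0:57,
                                 test_window = c(1, 10), alpha = 0.05) {
  if (length(actual) < 2L) stop("need at least 2 actual groups")
  freqs <- function(rec) {
    d <- unlist(lapply(pairwise_distances(rec), `[[`, "d"), use.names = FALSE)
    h <- graphics::hist(pmin(d, max(bin_edges) - 1e-9), breaks = bin_edges,
                        plot = FALSE)
    h$counts / length(d)
  }
  actual_mat <- do.call(rbind, lapply(actual, freqs))
  null_mat <- do.call(rbind, lapply(null$members, freqs))
  values <- bin_edges[-1]
  test_idx <- which(values >= test_window[1] & values <= test_window[2])
  calibrate_bins(actual_mat, null_mat, values, test_idx, alpha,
                 rule = "second_longest", provenance = null$provenance)
}

#' Calibrate the duration cutoff against the null ensemble
#'
#' At a fixed distance cutoff, counts for each group (and null member) the
#' sub-cutoff proximity runs lasting at least d seconds, for every candidate
#' d -- an inverse cumulative duration distribution, pooled over the six
#' pairs. Per-duration t-tests with Holm correction compare actual groups
#' against null members (null-mean variance by source-group jackknife, as in
#' [distance_calibration()]); the selected cutoff is the second-shortest
#' significant duration.
#'
#' @param actual List of gap-filled [group_recording()]s.
#' @param null A `null_ensemble`.
#' @param dist_cutoff Distance cutoff in cm. Default 5.
#' @param durations Candidate duration grid in seconds. Default 0:40.
#' @param test_window Durations (s) entering the Holm family. Default
#'   c(1, 15).
#' @param alpha Familywise level. Default 0.05.
#' @return A `calibration_curve`; `values` are durations in seconds and the
#'   means are per-group run counts (non-increasing in duration).
#' @export
duration_calibration <- function(actual, null, dist_cutoff = 5,
                                 durations = 0:40, test_window = c(1, 15),
                                 alpha = 0.05) {
  if (length(actual) < 2L) stop("need at least 2 actual groups")
  run_counts <- function(rec) {
    fr <- rec$trajectories[[1]]$frame_rate
    lens <- unlist(lapply(pairwise_distances(rec), function(p) {
      r <- rle(p$d <= dist_cutoff)
      r$lengths[r$values]
    }), use.names = FALSE) / fr
    vapply(durations, function(d) sum(lens >= d - 1e-9), numeric(1))
  }
  actual_mat <- do.call(rbind, lapply(actual, run_counts))
  null_mat <- do.call(rbind, lapply(null$members, run_counts))
  test_idx <- which(durations >= test_window[1] & durations <= test_window[2])
  calibrate_bins(actual_mat, null_mat, durations, test_idx, alpha,
                 rule = "second_shortest", provenance = null$provenance)
}

#' Select a conservative cutoff from a calibration curve
#'
#' Among the Holm-significant bins, returns the second most extreme value
#' under the given rule: `second_longest` for distances (one bin inside the
#' longest significant distance), `second_shortest` for durations, or
#' `extreme` for the most extreme significant bin. With a single significant
#' bin that bin is returned with a warning; with none, calibration has
#' failed and an error is raised.
#'
#' @param curve A `calibration_curve`.
#' @param rule One of "second_longest", "second_shortest", "extreme".
#' @return The selected cutoff (cm or s per the curve's metric).
#' @export
select_cutoff <- function(curve, rule = curve$rule) {
  rule <- match.arg(rule, c("second_longest", "second_shortest", "extreme"))
  sig <- sort(curve$significant)
  if (length(sig) == 0L) {
    stop("calibration failed: no Holm-significant bins")
  }
  if (length(sig) == 1L) {
    warning("only one significant bin; returning it")
    return(sig)
  }
  switch(rule,
         second_longest = sig[length(sig) - 1L],
         second_shortest = sig[2L],
         extreme = if (identical(curve$rule, "second_shortest")) sig[1L]
                   else sig[length(sig)])
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf(
    "<calibration_curve> %d bins, %d significant (Holm alpha = %g), cutoff = %s\n",
    length(x$values), length(x$significant), x$alpha,
    if (is.na(x$selected_cutoff)) "none" else format(x$selected_cutoff)))
  invisible(x)
}

#' Tidy per-bin table of a calibration curve
#'
#' @param curve A `calibration_curve`.
#' @return data.frame with value, actual/null means and CI bounds, raw and
#'   Holm p-values, and a significance flag.
#' @export
calibration_table <- function(curve) {
  data.frame(value = curve$values,
             actual_mean = curve$actual_mean,
             actual_lo = curve$actual_ci["lower", ],
             actual_hi = curve$actual_ci["upper", ],
             null_mean = curve$null_mean,
             null_lo = curve$null_ci["lower", ],
             null_hi = curve$null_ci["upper", ],
             p_raw = curve$p_raw, p_holm = curve$p_holm,
             significant = !is.na(curve$p_holm) &
               curve$p_holm < curve$alpha)
}
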
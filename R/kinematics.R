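#' Pairwise distance series for a four-fish group
#'
#' Euclidean distance per frame for each of the 6 unordered pairs among the
#' four fish (choose(4, 2) = 6). These are the components of the
#' inter-individual distance (IID).
#'
#' @param rec A gap-filled [group_recording()].
#' @return A list of 6 elements, each a list with `pair` (character 2-vector)
#'   and `d` (numeric per-frame distance, cm). Named `"id1-id2"`.
#' @export
pairwise_distances <- function(rec) {
  stopifnot(inherits(rec, "group_recording"))
  tr <- rec$trajectories
  ids <- names(tr)
  cmb <- utils::combn(4L, 2L)
  out <- lapply(seq_len(ncol(cmb)), function(k) {
    i <- cmb[1, k]; j <- cmb[2, k]
    list(pair = c(ids[i], ids[j]),
         d = sqrt((tr[[i]]$x - tr[[j]]$x)^2 + (tr[[i]]$y - tr[[j]]$y)^2))
  })
  names(out) <- vapply(out, function(p) paste(p$pair, collapse = "-"),
                       character(1))
  out
}

#' Per-frame inter-individual distance (IID)
#'
#' The mean of the six pairwise distances in each frame.
#'
#' @param rec A gap-filled [group_recording()].
#' @return Numeric vector, one mean distance (cm) per frame.
#' @export
iid_per_frame <- function(rec) {
  pd <- pairwise_distances(rec)
  Reduce(`+`, lapply(pd, `[[`, "d")) / length(pd)
}

#' Per-frame nearest-neighbour distance (NND)
#'
#' For each frame, each fish's distance to its closest group-mate, averaged
#' over the four fish.
#'
#' @param rec A gap-filled [group_recording()].
#' @return Numeric vector, one mean nearest-neighbour distance (cm) per frame.
#' @export
nnd_per_frame <- function(rec) {
  pd <- pairwise_distances(rec)
  n <- length(pd[[1]]$d)
  ids <- names(rec$trajectories)
  # per-fish min over its 3 pair series
  mins <- lapply(ids, function(id) {
    mine <- Filter(function(p) id %in% p$pair, pd)
    do.call(pmin, lapply(mine, `[[`, "d"))
  })
  Reduce(`+`, mins) / 4
}

#' Per-frame swimming speed
#'
#' Central finite difference of position scaled by the frame rate; the first
#' and last frames use one-sided differences. No smoothing is applied.
#'
#' @param traj A gap-filled `fish_trajectory`.
#' @param frame_rate Frames per second; defaults to the trajectory's own.
#' @return Numeric vector of speeds (cm/s), one per frame.
#' @export
speed_series <- function(traj, frame_rate = traj$frame_rate) {
  x <- traj$x; y <- traj$y
  n <- length(x)
  if (n < 2L) stop("need at least 2 frames for speed")
  i <- 2:(n - 1)
  vx <- c(x[2] - x[1], (x[i + 1] - x[i - 1]) / 2, x[n] - x[n - 1])
  vy <- c(y[2] - y[1], (y[i + 1] - y[i - 1]) / 2, y[n] - y[n - 1])
  sqrt(vx^2 + vy^2) * frame_rate
}

#' Total swimming distance
#'
#' Sum of per-frame displacement magnitudes along the path.
#'
#' @param traj A gap-filled `fish_trajectory`.
#' @return Total path length in cm.
#' @export
total_distance <- function(traj) {
  sum(sqrt(diff(traj$x)^2 + diff(traj$y)^2))
}

#' Position index: centre vs periphery occupancy
#'
#' Region 1 is the concentric rectangle similar to the arena, scaled by
#' 1/sqrt(2) along each axis so its area is exactly half the arena's; region
#' 0 is the remaining peripheral band of equal area. Returns the fraction of
#' frames spent in region 1: values near 1 mean centre preference, values
#' near 0 wall-hugging (thigmotaxis).
#'
#' @param traj A gap-filled `fish_trajectory`.
#' @param arena An [arena_spec()].
#' @return Scalar in [0, 1].
#' @export
position_index <- function(traj, arena) {
  hw <- arena$width / (2 * sqrt(2))
  hh <- arena$height / (2 * sqrt(2))
  inside <- abs(traj$x - arena$width / 2) <= hw &
    abs(traj$y - arena$height / 2) <= hh
  mean(inside)
}

#' Per-frame occupancy probability of a region
#'
#' The fraction of the four fish inside a rectangular region in each frame
#' (e.g. the lighted half in a phototaxis assay), with its mean and a
#' t-based 95% confidence interval across frames.
#'
#' @param rec A gap-filled [group_recording()].
#' @param region A region name from `rec$arena$regions`, or a list/vector
#'   with `xmin`, `xmax`, `ymin`, `ymax` in cm.
#' @return List with `per_frame` (numeric vector in [0,1]), `mean`, and
#'   `ci95` (length-2 vector).
#' @export
occupancy_probability <- function(rec, region) {
  stopifnot(inherits(rec, "group_recording"))
  if (is.character(region)) {
    region <- rec$arena$regions[[region]]
    if (is.null(region)) stop("unknown region name")
  }
  region <- as.list(region)
  counts <- Reduce(`+`, lapply(rec$trajectories, function(t) {
    as.integer(t$x >= region$xmin & t$x <= region$xmax &
                 t$y >= region$ymin & t$y <= region$ymax)
  }))
  p <- counts / 4
  m <- mean(p)
  se <- stats::sd(p) / sqrt(length(p))
  q <- stats::qt(0.975, df = length(p) - 1)
  list(per_frame = p, mean = m, ci95 = c(m - q * se, m + q * se))
}

#' Signed turning angles at a fixed frame step
#'
#' Positions are sampled every `step` frames (0.25 s at 20 fps with the
#' default step of 5); for each consecutive pair of displacement vectors
#' v1, v2 the signed angle is `atan2(cross(v1, v2), dot(v1, v2))`, the
#' quadrant-correct form of the arctangent of cross over dot. Positive
#' angles are anticlockwise in a y-up frame. Steps where either displacement
#' is shorter than `eps` (a stationary fish) are marked invalid and excluded
#' from the clockwise/anticlockwise counts.
#'
#' @param traj A gap-filled `fish_trajectory`.
#' @param step Frame spacing between sampled positions (default 5).
#' @param eps Minimum displacement (cm) for a step to count. Default 1e-6.
#' @return An object of class `turning_series`: list with `theta` (signed
#'   radians in (-pi, pi]), `valid` (logical), `n_cw` (clockwise, negative),
#'   `n_ccw` (anticlockwise, positive), `step`, `frame_rate`.
#' @export
turning_angles <- function(traj, step = 5L, eps = 1e-6) {
  x <- traj$x[seq(1, length(traj$x), by = step)]
  y <- traj$y[seq(1, length(traj$y), by = step)]
  if (length(x) < 3L) stop("trajectory too short for two displacement steps")
  v1x <- diff(x)[-(length(x) - 1)]; v1y <- diff(y)[-(length(y) - 1)]
  v2x <- diff(x)[-1];               v2y <- diff(y)[-1]
  theta <- atan2(v1x * v2y - v1y * v2x, v1x * v2x + v1y * v2y)
  valid <- sqrt(v1x^2 + v1y^2) >= eps & sqrt(v2x^2 + v2y^2) >= eps
  structure(list(theta = theta, valid = valid,
                 n_cw = sum(theta < 0 & valid),
                 n_ccw = sum(theta > 0 & valid),
                 step = step, frame_rate = traj$frame_rate),
            class = "turning_series")
}

#' Turning-bias (repetitive turning) index
#'
#' The absolute base-2 log ratio of clockwise to anticlockwise turn counts,
#' `|log2((N1 + c) / (N2 + c))|`. A balanced turner scores 0; a fish circling
#' in one direction scores high. The Haldane-Anscombe constant `c = 0.5`
#' keeps the index finite when one direction never occurs.
#'
#' @param ts A `turning_series` from [turning_angles()], or a list with
#'   `n_cw` and `n_ccw`.
#' @param c Continuity constant added to both counts. Default 0.5.
#' @return Non-negative scalar.
#' @export
turning_bias_index <- function(ts, c = 0.5) {
  abs(log2((ts$n_cw + c) / (ts$n_ccw + c)))
}

#' Per-fish kinematic metric table
#'
#' Convenience summary across a list of recordings: one row per fish with
#' total distance, position index, turn counts and turning-bias index.
#'
#' @param recordings A list of gap-filled [group_recording()] objects.
#' @return A data.frame with columns `group_id`, `fish_id`,
#'   `population_label`, `total_distance_cm`, `position_index`,
#'   `turning_bias_index`, `n1`, `n2`, and any condition labels.
#' @export
fish_metrics <- function(recordings) {
  if (inherits(recordings, "group_recording")) recordings <- list(recordings)
  rows <- lapply(recordings, function(rec) {
    per_fish <- lapply(rec$trajectories, function(t) {
      ts <- turning_angles(t)
      data.frame(group_id = rec$group_id, fish_id = t$fish_id,
                 population_label = rec$population_label,
                 total_distance_cm = total_distance(t),
                 position_index = position_index(t, rec$arena),
                 turning_bias_index = turning_bias_index(ts),
                 n1 = ts$n_cw, n2 = ts$n_ccw)
    })
    out <- do.call(rbind, per_fish)
    for (nm in names(rec$condition_labels)) out[[nm]] <- rec$condition_labels[[nm]]
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
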
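# Fixtures built in code: tiny deterministic recordings and random helpers.

default_arena <- function(frame_rate = 20) arena_spec(frame_rate = frame_rate)

# Four fish pinned at fixed offsets from a base point, n frames.
pinned_recording <- function(xy, n = 100, arena = default_arena(),
                             group_id = "pinned") {
  stopifnot(nrow(xy) == 4)
  trajs <- lapply(1:4, function(k) {
    fish_trajectory(paste0("f", k), rep(xy[k, 1], n), rep(xy[k, 2], n),
                    frame_rate = arena$frame_rate)
  })
  group_recording(trajs, arena, group_id = group_id)
}

# Four fish at the corners of a square of given side, offset into the arena.
square_recording <- function(side = 10, n = 100, origin = c(5, 5),
                             arena = default_arena()) {
  xy <- rbind(origin,
              origin + c(side, 0),
              origin + c(0, side),
              origin + c(side, side))
  pinned_recording(xy, n = n, arena = arena)
}

# A straight constant-velocity trajectory.
straight_traj <- function(n = 100, start = c(1, 1), step = c(0.1, 0),
                          frame_rate = 20, fish_id = "s") {
  fish_trajectory(fish_id, start[1] + step[1] * (0:(n - 1)),
                  start[2] + step[2] * (0:(n - 1)),
                  frame_rate = frame_rate)
}

# Fold a coordinate into [lo, hi] by reflection (no teleports at the walls).
fold <- function(z, lo, hi) {
  r <- (z - lo) %% (2 * (hi - lo))
  lo + ifelse(r > hi - lo, 2 * (hi - lo) - r, r)
}

# Group of four independent random-walk fish confined to the arena.
random_recording <- function(n = 200, arena = default_arena(),
                             group_id = "rw") {
  trajs <- lapply(1:4, function(k) {
    x <- fold(stats::runif(1, 0, arena$width) +
                cumsum(stats::rnorm(n, 0, 0.3)), 0, arena$width)
    y <- fold(stats::runif(1, 0, arena$height) +
                cumsum(stats::rnorm(n, 0, 0.3)), 0, arena$height)
    fish_trajectory(paste0("f", k), x, y, frame_rate = arena$frame_rate)
  })
  group_recording(trajs, arena, group_id = group_id)
}

# Rotate a recording's coordinates about a centre point.
rotate_recording <- function(rec, angle, centre = c(0, 0)) {
  rec$trajectories <- lapply(rec$trajectories, function(t) {
    dx <- t$x - centre[1]; dy <- t$y - centre[2]
    t$x <- centre[1] + cos(angle) * dx - sin(angle) * dy
    t$y <- centre[2] + sin(angle) * dx + cos(angle) * dy
    t
  })
  rec
}

translate_recording <- function(rec, by = c(0, 0)) {
  rec$trajectories <- lapply(rec$trajectories, function(t) {
    t$x <- t$x + by[1]; t$y <- t$y + by[2]; t
  })
  rec
}

# Independent brute-force step-down adjustment, coded from the definition.
holm_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  running <- 0
  for (i in seq_len(m)) {
    cand <- (m - i + 1) * p[ord[i]]
    running <- max(running, min(1, cand))
    adj[ord[i]] <- running
  }
  adj
}

# Brute-force run-length bout oracle: scan frame by frame.
bout_oracle <- function(d, dist_cutoff, dur_cutoff, frame_rate) {
  min_len <- round(dur_cutoff * frame_rate)
  res <- list()
  i <- 1; n <- length(d)
  while (i <= n) {
    if (d[i] <= dist_cutoff) {
      j <- i
      while (j < n && d[j + 1] <= dist_cutoff) j <- j + 1
      if (j - i + 1 >= min_len) {
        res[[length(res) + 1]] <- c(start = i - 1, end = j,
                                    len = j - i + 1)
      }
      i <- j + 1
    } else i <- i + 1
  }
  if (length(res) == 0) {
    return(data.frame(start = integer(), end = integer(), len = integer()))
  }
  as.data.frame(do.call(rbind, res))
}

# Signed angle between vectors via explicit rotation: rotate v1 onto +x,
# read the angle of the rotated v2.
angle_oracle <- function(v1, v2) {
  a1 <- atan2(v1[2], v1[1])
  r <- c(cos(-a1) * v2[1] - sin(-a1) * v2[2],
         sin(-a1) * v2[1] + cos(-a1) * v2[2])
  atan2(r[2], r[1])
}
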
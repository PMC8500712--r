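#' Simulation parameters for a four-fish group
#'
#' Defaults mirror the group assay this package analyses: four fish in a
#' 50.8 x 25.4 cm arena filmed at 20 fps for 300 s, swimming a few cm/s.
#' Sociality and laterality are controlled by three dials: `turn_bias` (the
#' probability that a heading kick is anticlockwise; 0.5 = balanced,
#' extremes give repetitive one-way circling), `attraction_strength` (how
#' strongly a fish steers toward its nearest neighbour once engaged), and
#' `deceleration_factor` (speed multiplier while engaged, producing the
#' slow-down during proximity bouts that real groups show).
#'
#' Engagement: a fish whose nearest neighbour comes within `sensing_radius`
#' locks onto that neighbour for at least `min_dwell_s` seconds, during
#' which attraction steering and deceleration apply. With
#' `attraction_strength = 0` fish are fully independent correlated random
#' walkers and no engagement occurs.
#'
#' @param n_fish Number of fish. Default 4.
#' @param duration_s Recording length, s. Default 300.
#' @param frame_rate Frames per second. Default 20.
#' @param arena An [arena_spec()]. Default 50.8 x 25.4 cm at `frame_rate`.
#' @param base_speed Mean swimming speed, cm/s. Default 3.
#' @param speed_sd Per-frame speed noise sd, cm/s. Default 1.
#' @param heading_persistence In [0, 1): fraction of heading carried over
#'   per frame; the per-frame turn-kick scale is
#'   `(1 - heading_persistence) * pi / 2` radians. Default 0.9.
#' @param turn_bias Probability a turn kick is anticlockwise, in (0, 1).
#'   Default 0.5.
#' @param attraction_strength Steering weight toward the engaged neighbour,
#'   >= 0 (0 disables sociality). Default 0.
#' @param sensing_radius Engagement distance, cm. Default 5.
#' @param preferred_distance Separation (cm) an engaged fish tries to hold:
#'   it steers toward its partner when farther than this and away when
#'   closer, as real shoaling fish keep roughly a body length apart rather
#'   than converging onto one point. Default 2.
#' @param deceleration_factor Speed multiplier while engaged, in (0, 1].
#'   Default 1.
#' @param min_dwell_s Minimum engagement time once triggered, s. Default 5.
#' @param gap_rate Per-frame probability a fish's ID is lost. Default 0.01.
#' @param wall_margin Repulsion range from walls, cm. Default 1.
#' @param seed Integer seed.
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(n_fish = 4, duration_s = 300, frame_rate = 20,
                       arena = arena_spec(frame_rate = frame_rate),
                       base_speed = 3, speed_sd = 1,
                       heading_persistence = 0.9, turn_bias = 0.5,
                       attraction_strength = 0, sensing_radius = 5,
                       preferred_distance = 2,
                       deceleration_factor = 1, min_dwell_s = 5,
                       gap_rate = 0.01, wall_margin = 1, seed = NULL) {
  stopifnot(n_fish == 4L, duration_s > 0, frame_rate > 0,
            base_speed > 0, speed_sd >= 0,
            heading_persistence >= 0, heading_persistence < 1,
            turn_bias > 0, turn_bias < 1,
            attraction_strength >= 0, sensing_radius > 0,
            preferred_distance > 0, preferred_distance < sensing_radius,
            deceleration_factor > 0, deceleration_factor <= 1,
            min_dwell_s >= 0, gap_rate >= 0, gap_rate < 1)
  structure(as.list(environment()), class = "sim_params")
}

#' Simulate a four-fish group recording
#'
#' Correlated random walk per fish: each frame the heading receives a kick
#' whose magnitude is half-normal with scale `(1 - heading_persistence) *
#' pi/2` and whose sign is anticlockwise with probability `turn_bias`; the
#' frame speed is Gaussian noise around `base_speed`, clamped to
#' `[0, base_speed + 5 * speed_sd]`. When a fish's nearest neighbour enters
#' `sensing_radius`, the fish engages for at least `min_dwell_s` seconds:
#' its heading is steered toward the partner with weight
#' `attraction_strength` per frame and its speed is multiplied by
#' `deceleration_factor`. Walls act by short-range repulsive steering plus
#' specular reflection, so positions never leave the arena. Missing-ID gaps
#' are injected at `gap_rate` (never on the first or last frame).
#'
#' @param params A [sim_params()] object.
#' @param fill If `TRUE` (default) gap frames are immediately reconstructed
#'   with [fill_gaps()] so the recording is analysis-ready; the missing mask
#'   records where gaps were injected either way. With `fill = FALSE` the
#'   gap frames hold `NA`, as after [read_group()].
#' @param group_id,population_label,condition_labels Labels for the
#'   resulting [group_recording()].
#' @return A [group_recording()].
#' @export
simulate_group <- function(params = sim_params(), fill = TRUE,
                           group_id = "sim1",
                           population_label = "synthetic",
                           condition_labels = character()) {
  stopifnot(inherits(params, "sim_params"))
  p <- params
  n <- floor(p$duration_s * p$frame_rate)
  W <- p$arena$width; H <- p$arena$height
  dt <- 1 / p$frame_rate
  kick_scale <- (1 - p$heading_persistence) * pi / 2
  rec <- with_seed(p$seed, {
    kick_mag <- matrix(abs(stats::rnorm(n * 4, 0, kick_scale)), n, 4)
    kick_sign <- matrix(ifelse(stats::runif(n * 4) < p$turn_bias, 1, -1),
                        n, 4)
    speed <- matrix(stats::rnorm(n * 4, p$base_speed, p$speed_sd), n, 4)
    speed <- pmin(pmax(speed, 0), p$base_speed + 5 * p$speed_sd)
    gaps <- matrix(stats::runif(n * 4) < p$gap_rate, n, 4)
    gaps[1, ] <- FALSE; gaps[n, ] <- FALSE
    px <- stats::runif(4, 2, W - 2)
    py <- stats::runif(4, 2, H - 2)
    heading <- stats::runif(4, -pi, pi)
    dwell <- rep(0L, 4)
    partner <- rep(NA_integer_, 4)
    dwell_frames <- round(p$min_dwell_s * p$frame_rate)
    X <- matrix(NA_real_, n, 4); Y <- matrix(NA_real_, n, 4)
    X[1, ] <- px; Y[1, ] <- py
    wrap <- function(a) atan2(sin(a), cos(a))
    for (t in 2:n) {
      heading <- heading + kick_sign[t, ] * kick_mag[t, ]
      v <- speed[t, ]
      if (p$attraction_strength > 0) {
        dx <- outer(px, px, "-"); dy <- outer(py, py, "-")
        D <- sqrt(dx^2 + dy^2); diag(D) <- Inf
        nn <- max.col(-D)
        nnd <- D[cbind(1:4, nn)]
        hit <- nnd <= p$sensing_radius
        dwell[hit] <- dwell_frames
        partner[hit] <- nn[hit]
        eng <- dwell > 0L
        if (any(eng)) {
          tgt <- partner[eng]
          bearing <- atan2(py[tgt] - py[eng], px[tgt] - px[eng])
          # hold station near the partner: approach when beyond the
          # preferred separation, back off when inside it
          too_close <- D[cbind(which(eng), tgt)] < p$preferred_distance
          bearing[too_close] <- wrap(bearing[too_close] + pi)
          heading[eng] <- heading[eng] +
            pmin(1, p$attraction_strength) * wrap(bearing - heading[eng])
          v[eng] <- v[eng] * p$deceleration_factor
        }
        dwell <- pmax(dwell - 1L, 0L)
      }
      # steer away from nearby walls
      m <- p$wall_margin
      push_x <- (px < m) - (px > W - m)
      push_y <- (py < m) - (py > H - m)
      near_wall <- push_x != 0 | push_y != 0
      if (any(near_wall)) {
        away <- atan2(push_y[near_wall], push_x[near_wall])
        heading[near_wall] <- heading[near_wall] +
          0.5 * wrap(away - heading[near_wall])
      }
      heading <- wrap(heading)
      px <- px + v * dt * cos(heading)
      py <- py + v * dt * sin(heading)
      # specular reflection keeps positions inside
      ref_x <- px < 0 | px > W
      px <- pmin(pmax(ifelse(px < 0, -px, ifelse(px > W, 2 * W - px, px)),
                      0), W)
      heading[ref_x] <- wrap(pi - heading[ref_x])
      ref_y <- py < 0 | py > H
      py <- pmin(pmax(ifelse(py < 0, -py, ifelse(py > H, 2 * H - py, py)),
                      0), H)
      heading[ref_y] <- -heading[ref_y]
      X[t, ] <- px; Y[t, ] <- py
    }
    trajs <- lapply(1:4, function(k) {
      x <- X[, k]; y <- Y[, k]
      x[gaps[, k]] <- NA_real_; y[gaps[, k]] <- NA_real_
      fish_trajectory(paste0("fish", k), x, y, missing = gaps[, k],
                      frame_rate = p$frame_rate)
    })
    group_recording(trajs, p$arena, group_id = group_id,
                    population_label = population_label,
                    condition_labels = condition_labels)
  })
  if (fill) rec <- fill_gaps(rec)
  rec
}

#' Simulate a cohort of independent group recordings
#'
#' @param params A [sim_params()] template; its `seed` is ignored.
#' @param n_groups Number of groups (the group assay this emulates used 18
#'   groups per population).
#' @param seed Master seed; per-group seeds are derived from it so the whole
#'   cohort is reproducible.
#' @param ... Passed to [simulate_group()].
#' @return List of [group_recording()]s with ids `sim_1 .. sim_<n>`.
#' @export
simulate_cohort <- function(params = sim_params(), n_groups = 18,
                            seed = 1, ...) {
  sub_seeds <- with_seed(seed, sample.int(.Machine$integer.max, n_groups))
  lapply(seq_len(n_groups), function(i) {
    p <- params
    p$seed <- sub_seeds[i]
    simulate_group(p, group_id = paste0("sim_", i), ...)
  })
}

#' Monte-Carlo oracle for the passing-by duration closed form
#'
#' Simulates the two geometric averages behind the passing-by model: the
#' chord a fish crosses through a disc of radius R, `2 R sin(omega)` with
#' omega uniform on (0, pi), and the relative speed of two fish at equal
#' speed V with heading difference theta uniform on (0, pi),
#' `2 V sin(theta / 2)`. Their closed forms are 4R/pi and 4V/pi, so
#' `(E_chord / E_relspeed) * V` recovers R -- the product PbDur x V.
#'
#' @param V Swimming speed, cm/s. Default 2.
#' @param radius Disc radius R, cm. Default 5.
#' @param n_draws Number of Monte-Carlo draws. Default 1e5.
#' @param seed Integer seed.
#' @return List with `e_chord`, `e_relspeed`, their standard errors
#'   `se_chord`, `se_relspeed`, `pbdur_times_v` (= ratio x V, cm) and its
#'   delta-method standard error `se_pbdur_times_v`, and `n_draws`.
#' @export
pbdur_mc_oracle <- function(V = 2, radius = 5, n_draws = 1e5, seed = NULL) {
  stopifnot(V > 0, radius > 0, n_draws >= 1)
  with_seed(seed, {
    omega <- stats::runif(n_draws, 0, pi)
    theta <- stats::runif(n_draws, 0, pi)
    chord <- 2 * radius * sin(omega)
    relsp <- 2 * V * sin(theta / 2)
    e_chord <- mean(chord); e_rel <- mean(relsp)
    se_chord <- if (n_draws > 1) stats::sd(chord) / sqrt(n_draws) else 0
    se_rel <- if (n_draws > 1) stats::sd(relsp) / sqrt(n_draws) else 0
    ratio <- e_chord / e_rel * V
    se_ratio <- ratio * sqrt((se_chord / e_chord)^2 + (se_rel / e_rel)^2)
    list(e_chord = e_chord, e_relspeed = e_rel,
         se_chord = se_chord, se_relspeed = se_rel,
         pbdur_times_v = ratio, se_pbdur_times_v = se_ratio,
         n_draws = n_draws)
  })
}
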
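test_that("pairwise distances, IID and NND agree with geometry and oracles", {
  rec <- square_recording(side = 10)
  pd <- pairwise_distances(rec)
  expect_length(pd, 6)
  d1 <- sort(unname(vapply(pd, function(p) p$d[1], numeric(1))))
  expect_equal(d1, c(10, 10, 10, 10, 10 * sqrt(2), 10 * sqrt(2)))
  expect_equal(iid_per_frame(rec)[1], (40 + 20 * sqrt(2)) / 6)
  expect_equal(nnd_per_frame(rec)[1], 10)

  # coincident fish: everything collapses to zero
  co <- pinned_recording(matrix(5, 4, 2), n = 10)
  expect_true(all(vapply(pairwise_distances(co),
                         function(p) all(p$d == 0), logical(1))))
  expect_equal(iid_per_frame(co), rep(0, 10))
  expect_equal(nnd_per_frame(co), rep(0, 10))

  # random positions vs a brute-force double loop
  set.seed(42)
  rr <- random_recording(n = 50)
  pd <- pairwise_distances(rr)
  tr <- rr$trajectories
  for (f in c(1, 25, 50)) {
    pos <- t(vapply(tr, function(t) c(t$x[f], t$y[f]), numeric(2)))
    brute <- as.numeric(dist(pos))
    got <- sort(unname(vapply(pd, function(p) p$d[f], numeric(1))))
    expect_equal(got, sort(brute))
  }
  # IID is the framewise mean of the six series; NND never exceeds it
  iid <- iid_per_frame(rr)
  expect_equal(iid, Reduce(`+`, lapply(pd, `[[`, "d")) / 6)
  expect_true(all(nnd_per_frame(rr) <= iid + 1e-12))
})

test_that("distance metrics are invariant under translation and rotation", {
  set.seed(7)
  rec <- random_recording(n = 80)
  moved <- rotate_recording(translate_recording(rec, c(3, -2)), 0.7,
                            centre = c(10, 10))
  expect_equal(iid_per_frame(moved), iid_per_frame(rec), tolerance = 1e-10)
  expect_equal(nnd_per_frame(moved), nnd_per_frame(rec), tolerance = 1e-10)
})

test_that("speed_series and total_distance match oracles", {
  # 0.1 cm/frame at 20 fps is 2 cm/s at every frame
  tr <- straight_traj(100, step = c(0.1, 0))
  expect_equal(speed_series(tr), rep(2, 100))
  expect_equal(total_distance(tr), 99 * 0.1)

  still <- straight_traj(50, step = c(0, 0))
  expect_equal(speed_series(still), rep(0, 50))
  expect_equal(total_distance(still), 0)

  # sampled sine path vs analytic speed; central differences are second
  # order so interior frames agree closely
  fr <- 100
  tt <- seq(0, 2, by = 1 / fr)
  tr <- fish_trajectory("sine", tt, sin(tt), frame_rate = fr)
  v_true <- sqrt(1 + cos(tt)^2)
  v_est <- speed_series(tr)
  expect_equal(v_est[2:(length(tt) - 1)], v_true[2:(length(tt) - 1)],
               tolerance = 1e-3)

  # total distance equals the time integral of speed on a smooth path
  # (central differences average out sub-frame jitter, so the identity is
  # a statement about resolved motion)
  fr <- 50
  tt <- seq(0, 4, by = 1 / fr)
  smooth <- fish_trajectory("helix", 10 + 3 * cos(tt), 10 + 3 * sin(tt),
                            frame_rate = fr)
  expect_equal(total_distance(smooth),
               sum(speed_series(smooth)) / fr, tolerance = 0.01)
})

test_that("position index splits the arena into equal-area halves", {
  arena <- default_arena()
  centre <- pinned_recording(matrix(rep(c(25.4, 12.7), each = 4), 4, 2),
                             n = 10)$trajectories[[1]]
  expect_equal(position_index(centre, arena), 1)
  corner <- pinned_recording(matrix(rep(c(0.5, 0.5), each = 4), 4, 2),
                             n = 10)$trajectories[[1]]
  expect_equal(position_index(corner, arena), 0)
  # uniform positions: region 1 holds half the area
  set.seed(123)
  n <- 1e5
  unif <- fish_trajectory("u", stats::runif(n, 0, arena$width),
                          stats::runif(n, 0, arena$height))
  pi_hat <- position_index(unif, arena)
  expect_equal(pi_hat, 0.5, tolerance = 0.01)
  # centre and periphery fractions sum to one exactly
  inside <- pi_hat
  outside <- 1 - inside
  expect_equal(inside + outside, 1)
})

test_that("occupancy probability counts fish in a region per frame", {
  arena <- arena_spec(regions = list(
    lighted = c(xmin = 0, xmax = 25.4, ymin = 0, ymax = 25.4)))
  all_in <- pinned_recording(matrix(rep(c(10, 10), each = 4), 4, 2),
                             n = 50, arena = arena)
  occ <- occupancy_probability(all_in, "lighted")
  expect_equal(occ$mean, 1)
  all_out <- pinned_recording(matrix(rep(c(40, 10), each = 4), 4, 2),
                              n = 50, arena = arena)
  expect_equal(occupancy_probability(all_out, "lighted")$mean, 0)
  # uniform fish in a half-arena region: about half in, CI covers 0.5
  set.seed(9)
  trajs <- lapply(1:4, function(k) {
    fish_trajectory(paste0("f", k), stats::runif(2000, 0, 50.8),
                    stats::runif(2000, 0, 25.4))
  })
  rec <- group_recording(trajs, arena)
  occ <- occupancy_probability(rec, "lighted")
  expect_equal(occ$mean, 0.5, tolerance = 0.03)
  expect_lt(occ$ci95[1], occ$mean)
  expect_gt(occ$ci95[2], occ$mean)
})

test_that("turning angles carry the right sign, magnitude and exclusions", {
  fr <- 20
  # +x for 5 frames then +y for 5 frames: a quarter turn, anticlockwise in
  # a y-up frame
  x <- c(seq(0, 1, length.out = 6), rep(1, 10))
  y <- c(rep(0, 6), seq(0.2, 2, length.out = 10))
  ts <- turning_angles(fish_trajectory("q", x[1:16], y[1:16],
                                       frame_rate = fr), step = 5)
  expect_equal(ts$theta[1], pi / 2)

  # straight line: zero angle everywhere, no turns counted either way
  ts <- turning_angles(straight_traj(60), step = 5)
  expect_true(all(abs(ts$theta) < 1e-12))
  expect_equal(ts$n_cw + ts$n_ccw, 0)

  # stationary steps are invalid and excluded
  still <- fish_trajectory("st", rep(1, 60), rep(2, 60))
  ts <- turning_angles(still)
  expect_equal(sum(ts$valid), 0)

  # random displacement pairs vs the rotation oracle
  set.seed(31)
  for (i in 1:200) {
    v1 <- stats::rnorm(2); v2 <- stats::rnorm(2)
    x <- c(0, v1[1], v1[1] + v2[1])
    y <- c(0, v1[2], v1[2] + v2[2])
    ts <- turning_angles(fish_trajectory("o", x, y), step = 1)
    expect_equal(ts$theta[1], angle_oracle(v1, v2), tolerance = 1e-12)
  }
})

test_that("theta stays in (-pi, pi] and a balanced zig-zag scores zero", {
  set.seed(77)
  tr <- random_recording(n = 500)$trajectories[[1]]
  ts <- turning_angles(tr)
  expect_true(all(ts$theta > -pi - 1e-12 & ts$theta <= pi + 1e-12))
  # alternating +30/-30 degree turns: N1 == N2, index 0
  # (41 headings give 40 turning angles, an even, balanced count)
  ang <- cumsum(rep(c(pi / 6, -pi / 6), 21))[1:41]
  x <- cumsum(c(0, cos(ang))); y <- cumsum(c(0, sin(ang)))
  ts <- turning_angles(fish_trajectory("z", x, y), step = 1)
  expect_equal(ts$n_cw, ts$n_ccw)
  expect_equal(turning_bias_index(ts), 0)
})

test_that("turning bias index follows the log2 count ratio", {
  expect_equal(turning_bias_index(list(n_cw = 200, n_ccw = 200)), 0)
  expect_equal(turning_bias_index(list(n_cw = 100, n_ccw = 25)),
               abs(log2(100.5 / 25.5)))
  expect_equal(turning_bias_index(list(n_cw = 100, n_ccw = 25), c = 0), 2)

  # constant-curvature circle: every step turns the same way, and the
  # index hits the closed form log2((N + 0.5) / 0.5)
  n_steps <- 80
  ang <- cumsum(rep(pi / 20, n_steps))
  x <- cumsum(c(0, cos(ang))); y <- cumsum(c(0, sin(ang)))
  ts <- turning_angles(fish_trajectory("c", x, y), step = 1)
  expect_equal(ts$n_cw, 0)
  expect_equal(ts$n_ccw, n_steps - 1)
  expect_equal(turning_bias_index(ts),
               log2((n_steps - 1 + 0.5) / 0.5))
})

test_that("turning index is invariant under reflection", {
  set.seed(13)
  tr <- random_recording(n = 400)$trajectories[[2]]
  refl <- tr; refl$y <- -refl$y
  ts <- turning_angles(tr); tsr <- turning_angles(refl)
  expect_equal(tsr$n_cw, ts$n_ccw)
  expect_equal(tsr$n_ccw, ts$n_cw)
  expect_equal(turning_bias_index(tsr), turning_bias_index(ts))
})

test_that("fish_metrics produces one labelled row per fish", {
  set.seed(3)
  recs <- list(random_recording(n = 200, group_id = "g1"),
               random_recording(n = 200, group_id = "g2"))
  tab <- fish_metrics(recs)
  expect_equal(nrow(tab), 8)
  expect_setequal(unique(tab$group_id), c("g1", "g2"))
  expect_true(all(tab$total_distance_cm > 0))
  expect_true(all(tab$turning_bias_index >= 0))
})
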
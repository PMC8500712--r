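test_that("group mean speed averages the per-fish mean speeds", {
  arena <- default_arena()
  steps <- c(0.1, 0.05, 0.15, 0.2)  # cm/frame -> 2, 1, 3, 4 cm/s
  trajs <- lapply(1:4, function(k) {
    straight_traj(100, start = c(1, k * 5), step = c(steps[k], 0),
                  fish_id = paste0("f", k))
  })
  rec <- group_recording(trajs, arena)
  expect_equal(group_mean_speed(rec), 2.5)
  # equals the oracle mean of speed_series
  set.seed(2)
  rr <- random_recording(n = 100)
  expect_equal(group_mean_speed(rr),
               mean(sapply(rr$trajectories,
                           function(t) mean(speed_series(t)))))
})

test_that("passing-by duration follows the closed form R / V", {
  m <- passing_by_duration(1)
  expect_equal(m$pbdur, 5)
  expect_equal(passing_by_duration(2.5)$pbdur, 2)
  expect_equal(m$expected_relative_speed, 4 / pi)
  expect_equal(m$expected_chord, 20 / pi)
  expect_equal(m$pbdur * m$V, m$cutoff)
  expect_error(passing_by_duration(0), "stationary")
})

test_that("Monte-Carlo chord and relative-speed means recover R / V", {
  mc <- pbdur_mc_oracle(V = 3, radius = 5, n_draws = 1e5, seed = 99)
  expect_lt(abs(mc$e_chord - 20 / pi), 3 * mc$se_chord)
  expect_lt(abs(mc$e_relspeed - 4 * 3 / pi), 3 * mc$se_relspeed)
  expect_lt(abs(mc$pbdur_times_v - 5), 3 * mc$se_pbdur_times_v)
  # degenerate single draw still returns finite values
  one <- pbdur_mc_oracle(n_draws = 1, seed = 1)
  expect_true(is.finite(one$pbdur_times_v))
})

test_that("detect_bouts keeps only sub-cutoff runs of sufficient length", {
  fr <- 20
  # always 3 cm apart for 300 s
  b <- detect_bouts(rep(3, 6000), dist_cutoff = 5, dur_cutoff = 4,
                    frame_rate = fr)
  expect_equal(nrow(b), 1)
  expect_equal(b$raw_s, 300)
  expect_equal(b$start_frame, 0)
  expect_equal(b$end_frame, 6000)
  # never closer than 10 cm
  expect_equal(nrow(detect_bouts(rep(10, 6000), frame_rate = fr)), 0)
  # 79 frames (3.95 s) misses the 4-s cutoff, 80 frames makes it
  d79 <- c(rep(10, 50), rep(4, 79), rep(10, 50))
  d80 <- c(rep(10, 50), rep(4, 80), rep(10, 50))
  expect_equal(nrow(detect_bouts(d79, frame_rate = fr)), 0)
  b80 <- detect_bouts(d80, frame_rate = fr)
  expect_equal(nrow(b80), 1)
  expect_equal(b80$raw_s, 4)
  expect_equal(b80$start_frame, 50)
  expect_equal(b80$end_frame, 130)
})

test_that("detect_bouts matches the brute-force run-length oracle", {
  set.seed(17)
  for (i in 1:50) {
    d <- abs(cumsum(stats::rnorm(500, 0, 1))) + 1
    b <- detect_bouts(d, dist_cutoff = 5, dur_cutoff = 1, frame_rate = 20)
    o <- bout_oracle(d, 5, 1, 20)
    expect_equal(nrow(b), nrow(o))
    if (nrow(b) > 0) {
      expect_equal(b$start_frame, o$start)
      expect_equal(b$end_frame - b$start_frame, o$len)
    }
  }
})

test_that("bout detection is symmetric and monotone in its cutoffs", {
  set.seed(23)
  rec <- random_recording(n = 2000)
  pd <- pairwise_distances(rec)
  p <- pd[[1]]
  rev_p <- list(pair = rev(p$pair), d = p$d)
  b1 <- detect_bouts(p, dur_cutoff = 1, frame_rate = 20)
  b2 <- detect_bouts(rev_p, dur_cutoff = 1, frame_rate = 20)
  expect_equal(b1$start_frame, b2$start_frame)
  expect_equal(b1$raw_s, b2$raw_s)
  # lowering the duration cutoff never loses bouts; raising the distance
  # cutoff never loses bout time (it can merge adjacent runs, so the bout
  # count itself is not monotone)
  for (d in pd) {
    base <- detect_bouts(d, 5, 2, 20)
    expect_gte(nrow(detect_bouts(d, 5, 1, 20)), nrow(base))
    expect_gte(sum(detect_bouts(d, 7, 2, 20)$raw_s), sum(base$raw_s))
  }
})

test_that("adjustment floors at zero and accumulates per fish", {
  bouts <- data.frame(fish_a = "f1", fish_b = "f2", start_frame = 0L,
                      end_frame = 200L, raw_s = 10)
  s <- adjust_and_summarize(bouts, passing_by_duration(2.5),
                            paste0("f", 1:4))
  expect_equal(s$bouts$adjusted_s, 8)
  expect_equal(s$per_fish$total_adjusted_s, c(8, 8, 0, 0))
  expect_equal(s$per_fish$bout_count, c(1L, 1L, 0L, 0L))
  # pbdur longer than the bout: clamp to zero, not negative
  s0 <- adjust_and_summarize(bouts, 12, paste0("f", 1:4))
  expect_equal(s0$bouts$adjusted_s, 0)

  # random bout sets vs a brute-force per-fish accumulation
  set.seed(4)
  ids <- paste0("f", 1:4)
  for (rep in 1:20) {
    pairs <- t(utils::combn(ids, 2))
    k <- sample(1:10, 1)
    rows <- sample(nrow(pairs), k, replace = TRUE)
    bouts <- data.frame(fish_a = pairs[rows, 1], fish_b = pairs[rows, 2],
                        start_frame = 0L, end_frame = 0L,
                        raw_s = stats::runif(k, 4, 30))
    pb <- stats::runif(1, 0, 6)
    s <- adjust_and_summarize(bouts, pb, ids)
    for (f in ids) {
      inb <- bouts$fish_a == f | bouts$fish_b == f
      expect_equal(s$per_fish$total_adjusted_s[s$per_fish$fish_id == f],
                   sum(pmax(0, bouts$raw_s[inb] - pb)))
    }
  }
  # totals shrink as pbdur grows
  tot <- function(pb) sum(adjust_and_summarize(bouts, pb,
                                               ids)$per_fish$total_adjusted_s)
  expect_gte(tot(1), tot(3))
  expect_gte(tot(3), tot(6))
})

test_that("speed profile partitions frames and handles boutless fish", {
  arena <- default_arena()
  # constant-speed fish with one bout: all four window means equal
  trajs <- lapply(1:4, function(k) {
    straight_traj(1200, start = c(0.5, k * 3), step = c(0.02, 0),
                  fish_id = paste0("f", k))
  })
  rec <- group_recording(trajs, arena)
  bouts <- data.frame(fish_a = "f1", fish_b = "f2", start_frame = 400L,
                      end_frame = 600L, raw_s = 10)
  sp <- speed_profile(rec, "f1", bouts)
  expect_equal(sp$during, 0.4)
  expect_equal(sp$before, 0.4)
  expect_equal(sp$after, 0.4)
  expect_equal(sp$out, 0.4)
  expect_equal(unname(sp$n_frames["during"]), 200L)
  expect_equal(unname(sp$n_frames["before"]), 80L)
  expect_equal(unname(sp$n_frames["after"]), 80L)
  expect_equal(sum(sp$n_frames), 1200L)
  # fish with no bouts: out equals the overall mean, rest missing
  sp3 <- speed_profile(rec, "f3", bouts)
  expect_true(is.na(sp3$during))
  expect_equal(sp3$out, mean(speed_series(rec$trajectories[["f3"]])))
})

test_that("attracted, decelerating agents slow down during bouts", {
  p <- sim_params(seed = 505, duration_s = 150, attraction_strength = 0.2,
                  deceleration_factor = 0.5, gap_rate = 0)
  rec <- simulate_group(p)
  bouts <- detect_group_bouts(rec)
  expect_gt(nrow(bouts), 0)
  slower <- vapply(names(rec$trajectories), function(f) {
    sp <- speed_profile(rec, f, bouts)
    if (is.na(sp$during) || is.na(sp$out)) NA else sp$during < sp$out
  }, logical(1))
  expect_true(all(slower, na.rm = TRUE))
})

test_that("pair motion classification matches constructed geometries", {
  arena <- default_arena()
  fr <- 20
  mk_rec <- function(p1, p2) {
    filler <- function(k) straight_traj(40, start = c(1, 20 + k),
                                        step = c(0, 0),
                                        fish_id = paste0("x", k))
    group_recording(list(
      fish_trajectory("a", p1$x, p1$y, frame_rate = fr),
      fish_trajectory("b", p2$x, p2$y, frame_rate = fr),
      filler(1), filler(2)), arena)
  }
  tt <- 0:39
  # both +x, fish a ahead, constant 2-cm gap -> fish1 (a) leads
  rec <- mk_rec(list(x = 10 + 0.1 * tt, y = rep(10, 40)),
                list(x = 8 + 0.1 * tt, y = rep(10, 40)))
  cl <- classify_pair_motion(rec, c("a", "b"))
  expect_true(all(cl$label == "fish1_leads"))
  # same geometry, pair order flipped -> fish2 leads
  cl2 <- classify_pair_motion(rec, c("b", "a"))
  expect_true(all(cl2$label == "fish2_leads"))
  # head-on pass -> inverse_pass
  rec <- mk_rec(list(x = 5 + 0.2 * tt, y = rep(10, 40)),
                list(x = 15 - 0.2 * tt, y = rep(10.5, 40)))
  cl <- classify_pair_motion(rec, c("a", "b"))
  expect_true(all(cl$label == "inverse_pass"))
  # converging at 45 degrees -> gather; check against hand-computed
  # delta-d: both move 4 cm per window toward a meeting point
  rec <- mk_rec(list(x = 5 + 0.2 * tt / sqrt(2), y = 5 + 0.2 * tt / sqrt(2)),
                list(x = 15 - 0.2 * tt / sqrt(2), y = 5 + 0.2 * tt / sqrt(2)))
  cl <- classify_pair_motion(rec, c("a", "b"))
  expect_equal(as.character(cl$label[1]), "gather")
  # separating -> disperse
  rec <- mk_rec(list(x = 10 + 0.2 * tt, y = rep(10, 40)),
                list(x = rep(10, 40), y = 10 + 0.2 * tt))
  cl <- classify_pair_motion(rec, c("a", "b"))
  expect_equal(as.character(cl$label[1]), "disperse")
})

test_that("independent walkers match the null level; attraction raises it", {
  # mean per-fish adjusted duration of independent simulated groups is
  # statistically indistinguishable from regrouped null members
  p <- sim_params(duration_s = 120, gap_rate = 0)
  cohort <- simulate_cohort(p, n_groups = 12, seed = 314)
  adj_mean <- function(rec) {
    b <- detect_group_bouts(rec)
    s <- adjust_and_summarize(b, passing_by_duration(group_mean_speed(rec)),
                              names(rec$trajectories))
    mean(s$per_fish$total_adjusted_s)
  }
  actual <- vapply(cohort, adj_mean, numeric(1))
  ne <- build_null_groups(cohort, n = 12, seed = 315)
  nul <- vapply(ne$members, adj_mean, numeric(1))
  expect_gt(stats::t.test(actual, nul)$p.value, 0.01)

  # adjusted duration increases with attraction strength (rank test)
  totals <- lapply(c(0, 0.08, 0.25), function(a) {
    vapply(1:4, function(s) {
      adj_mean(simulate_group(sim_params(seed = 1000 + s, duration_s = 120,
                                         attraction_strength = a,
                                         deceleration_factor = 0.6,
                                         gap_rate = 0)))
    }, numeric(1))
  })
  med <- vapply(totals, stats::median, numeric(1))
  expect_true(all(diff(med) > 0))
  expect_lt(stats::wilcox.test(totals[[1]], totals[[3]],
                               alternative = "less",
                               exact = FALSE)$p.value, 0.05)
})
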
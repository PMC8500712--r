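#' Group mean swimming speed
#'
#' The mean over the four fish of each fish's mean frame speed across the
#' full analysis window. This is the V that sets the passing-by duration.
#'
#' @param rec A gap-filled [group_recording()].
#' @return Scalar speed, cm/s.
#' @export
group_mean_speed <- function(rec) {
  mean(vapply(rec$trajectories,
              function(t) mean(speed_series(t)), numeric(1)))
}

#' Passing-by duration model
#'
#' Expected time two independently swimming fish spend within the cutoff
#' radius of one another purely by chance. With both fish at the group mean
#' speed V and a uniformly distributed heading difference, the mean relative
#' speed is E(|Vr|) = 4V/pi; with a uniformly distributed chord angle the
#' mean chord crossed through a disc of radius R is E(|L|) = 4R/pi. Their
#' ratio collapses to PbDur = R / V: at the default 5 cm cutoff, a group
#' swimming 1 cm/s is expected to spend 5 s within range per chance
#' encounter. This duration is subtracted from each detected bout so that
#' only time beyond chance proximity counts as interaction.
#'
#' @param V Group mean speed, cm/s (must be > 0).
#' @param cutoff Interaction distance cutoff R, cm. Default 5.
#' @return An object of class `passing_by_model`: list with `V`,
#'   `expected_relative_speed` (4V/pi), `expected_chord` (4R/pi), `pbdur`
#'   (R/V, seconds), `cutoff`.
#' @export
passing_by_duration <- function(V, cutoff = 5) {
  stopifnot(is.numeric(V), length(V) == 1L, is.numeric(cutoff), cutoff > 0)
  if (!is.finite(V) || V <= 0) {
    stop("passing-by duration undefined for a stationary group (V = ", V, ")")
  }
  structure(list(V = V,
                 expected_relative_speed = 4 * V / pi,
                 expected_chord = 4 * cutoff / pi,
                 pbdur = cutoff / V,
                 cutoff = cutoff),
            class = "passing_by_model")
}

#' Detect nearby-interaction bouts in a pair distance series
#'
#' A bout is a maximal run of frames in which the pair distance stays at or
#' below `dist_cutoff` and whose length reaches `dur_cutoff` seconds;
#' shorter sub-cutoff runs are discarded. Frame spans are half-open
#' `[start, end)`, 0-based.
#'
#' @param pd One element of [pairwise_distances()] output (list with `pair`
#'   and `d`), or a bare numeric distance vector.
#' @param dist_cutoff Maximum distance, cm. Default 5.
#' @param dur_cutoff Minimum duration, s. Default 4.
#' @param frame_rate Frames per second. Default 20.
#' @return A data.frame with columns `fish_a`, `fish_b`, `start_frame`,
#'   `end_frame`, `raw_s` (and no rows when no run qualifies).
#' @export
detect_bouts <- function(pd, dist_cutoff = 5, dur_cutoff = 4,
                         frame_rate = 20) {
  if (is.numeric(pd)) pd <- list(pair = c("a", "b"), d = pd)
  near <- pd$d <= dist_cutoff
  r <- rle(near)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  min_len <- dur_cutoff * frame_rate
  keep <- r$values & (r$lengths >= min_len - 1e-9)
  data.frame(fish_a = rep(pd$pair[1], sum(keep)),
             fish_b = rep(pd$pair[2], sum(keep)),
             start_frame = starts[keep] - 1L,
             end_frame = ends[keep],
             raw_s = r$lengths[keep] / frame_rate)
}

#' Detect bouts for all six pairs of a group
#'
#' @param rec A gap-filled [group_recording()].
#' @param dist_cutoff,dur_cutoff As in [detect_bouts()].
#' @return A single bout data.frame with a `group_id` column prepended.
#' @export
detect_group_bouts <- function(rec, dist_cutoff = 5, dur_cutoff = 4) {
  fr <- rec$trajectories[[1]]$frame_rate
  pd <- pairwise_distances(rec)
  bouts <- do.call(rbind, lapply(pd, detect_bouts, dist_cutoff = dist_cutoff,
                                 dur_cutoff = dur_cutoff, frame_rate = fr))
  rownames(bouts) <- NULL
  cbind(data.frame(group_id = rep(rec$group_id, nrow(bouts))), bouts)
}

#' Apply the passing-by correction and summarize per fish
#'
#' Subtracts the group's passing-by duration from each bout (floored at
#' zero) and accumulates adjusted durations and bout counts per fish. Each
#' pairwise bout contributes to both participating fish; simultaneous bouts
#' with different partners are summed, not deduplicated.
#'
#' @param bouts A bout data.frame from [detect_bouts()] or
#'   [detect_group_bouts()].
#' @param pbm A `passing_by_model` from [passing_by_duration()], or a bare
#'   pbdur value in seconds.
#' @param fish_ids Character vector of all fish ids (fish with no bouts
#'   appear with zeros).
#' @return An object of class `interaction_summary`: list with `per_fish`
#'   (data.frame fish_id, total_adjusted_s, bout_count), `bouts` (input with
#'   an `adjusted_s` column), `pbdur`, `V`.
#' @export
adjust_and_summarize <- function(bouts, pbm, fish_ids) {
  pbdur <- if (inherits(pbm, "passing_by_model")) pbm$pbdur else pbm
  V <- if (inherits(pbm, "passing_by_model")) pbm$V else NA_real_
  bouts$adjusted_s <- pmax(0, bouts$raw_s - pbdur)
  per_fish <- data.frame(fish_id = as.character(fish_ids),
                         total_adjusted_s = 0, bout_count = 0L,
                         stringsAsFactors = FALSE)
  for (i in seq_len(nrow(bouts))) {
    for (f in c(bouts$fish_a[i], bouts$fish_b[i])) {
      k <- match(f, per_fish$fish_id)
      per_fish$total_adjusted_s[k] <- per_fish$total_adjusted_s[k] +
        bouts$adjusted_s[i]
      per_fish$bout_count[k] <- per_fish$bout_count[k] + 1L
    }
  }
  structure(list(per_fish = per_fish, bouts = bouts, pbdur = pbdur, V = V),
            class = "interaction_summary")
}

#' Bout-anchored speed profile for one fish
#'
#' Partitions a fish's frames into four classes and reports the mean speed
#' in each: `during` (union of the fish's bout frames), `before` (the
#' `window` seconds preceding each bout), `after` (the `window` seconds
#' following each bout), and `out` (everything else). Flanking windows are
#' truncated at the recording edges; frames claimed by any bout's `during`
#' win over `before`/`after`, and `after` of an earlier bout wins over
#' `before` of a later one.
#'
#' @param rec A gap-filled [group_recording()].
#' @param fish_id Which fish.
#' @param bouts Bout data.frame covering all pairs involving the fish.
#' @param window Flank length in seconds. Default 4.
#' @return List with `during`, `before`, `after`, `out` mean speeds (cm/s;
#'   `NA` where the class has no frames) and `n_frames` per class.
#' @export
speed_profile <- function(rec, fish_id, bouts, window = 4) {
  traj <- rec$trajectories[[as.character(fish_id)]]
  if (is.null(traj)) stop("unknown fish ", fish_id)
  fr <- traj$frame_rate
  n <- n_frames(traj)
  v <- speed_series(traj)
  mine <- bouts[bouts$fish_a == fish_id | bouts$fish_b == fish_id, ,
                drop = FALSE]
  w <- round(window * fr)
  cls <- rep("out", n)
  # later assignments win, so apply in increasing precedence
  for (i in seq_len(nrow(mine))) {
    s <- mine$start_frame[i] + 1L
    if (s > 1L) {
      pre <- seq.int(max(1L, s - w), s - 1L)
      cls[pre[cls[pre] == "out"]] <- "before"
    }
  }
  for (i in seq_len(nrow(mine))) {
    s <- mine$start_frame[i] + 1L; e <- mine$end_frame[i]
    if (e < n) {
      post <- seq.int(e + 1L, min(n, e + w))
      cls[post[cls[post] != "during"]] <- "after"
    }
  }
  for (i in seq_len(nrow(mine))) {
    cls[seq.int(mine$start_frame[i] + 1L, mine$end_frame[i])] <- "during"
  }
  if (nrow(mine) == 0L) {
    means <- c(during = NA_real_, before = NA_real_, after = NA_real_,
               out = mean(v))
    nf <- c(during = 0L, before = 0L, after = 0L, out = n)
  } else {
    means <- vapply(c("during", "before", "after", "out"), function(k) {
      if (any(cls == k)) mean(v[cls == k]) else NA_real_
    }, numeric(1))
    nf <- vapply(c("during", "before", "after", "out"),
                 function(k) sum(cls == k), integer(1))
  }
  list(during = means[["during"]], before = means[["before"]],
       after = means[["after"]], out = means[["out"]], n_frames = nf)
}

#' Classify pairwise relative motion in fixed windows
#'
#' Splits the recording into non-overlapping windows and labels each by the
#' pair's relative motion: `gather` (closing), `disperse` (separating),
#' `inverse_pass` (anti-aligned headings, swimming by in opposite
#' directions), `fish1_leads`/`fish2_leads` (aligned headings at a roughly
#' constant gap, ordered along the common heading), else `none`. The rules
#' use the net displacement vectors u1, u2 of each fish over the window:
#' `cos(phi)` is the alignment of u1 and u2 and `delta_d` the change in pair
#' distance. `inverse_pass` requires `cos(phi) < -align`; otherwise
#' `delta_d < -delta` is `gather` and `delta_d > delta` is `disperse`;
#' otherwise aligned motion (`cos(phi) > align`) with a stable gap is a
#' leading bout, the leader being the fish further along the mean heading.
#'
#' @param rec A gap-filled [group_recording()].
#' @param pair Character 2-vector of fish ids.
#' @param window Window length, seconds. Default 1.
#' @param delta Distance-change threshold, cm per window. Default 0.5.
#' @param align Alignment threshold on cos(phi). Default cos(pi/3) = 0.5.
#' @return A data.frame with `window_start_frame` and `label` (factor over
#'   the six categories).
#' @export
classify_pair_motion <- function(rec, pair, window = 1, delta = 0.5,
                                 align = cos(pi / 3)) {
  t1 <- rec$trajectories[[as.character(pair[1])]]
  t2 <- rec$trajectories[[as.character(pair[2])]]
  if (is.null(t1) || is.null(t2)) stop("unknown fish in pair")
  fr <- t1$frame_rate
  w <- round(window * fr)
  n <- n_frames(t1)
  starts <- seq.int(1L, n - w, by = w)
  labs <- vapply(starts, function(s) {
    e <- s + w
    u1 <- c(t1$x[e] - t1$x[s], t1$y[e] - t1$y[s])
    u2 <- c(t2$x[e] - t2$x[s], t2$y[e] - t2$y[s])
    d0 <- sqrt((t1$x[s] - t2$x[s])^2 + (t1$y[s] - t2$y[s])^2)
    d1 <- sqrt((t1$x[e] - t2$x[e])^2 + (t1$y[e] - t2$y[e])^2)
    dd <- d1 - d0
    n1 <- sqrt(sum(u1^2)); n2 <- sqrt(sum(u2^2))
    if (n1 < 1e-9 || n2 < 1e-9) return("none")
    cphi <- sum(u1 * u2) / (n1 * n2)
    if (cphi < -align) return("inverse_pass")
    if (dd < -delta) return("gather")
    if (dd > delta) return("disperse")
    if (cphi > align) {
      h <- (u1 / n1 + u2 / n2)
      p1 <- t1$x[s] * h[1] + t1$y[s] * h[2]
      p2 <- t2$x[s] * h[1] + t2$y[s] * h[2]
      return(if (p1 >= p2) "fish1_leads" else "fish2_leads")
    }
    "none"
  }, character(1))
  data.frame(window_start_frame = starts - 1L,
             label = factor(labs, levels = c("disperse", "inverse_pass",
                                             "gather", "fish1_leads",
                                             "fish2_leads", "none")))
}
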
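#' Arena and recording specification
#'
#' Describes the recording arena: physical dimensions in cm, the camera frame
#' rate, an optional pixel-to-cm calibration, and optional named rectangular
#' region masks (e.g. a lighted half for phototaxis scoring).
#'
#' @param width Arena width in cm (x extent). Default 50.8, a standard
#'   37.85 L tank footprint.
#' @param height Arena height in cm (y extent). Default 25.4.
#' @param frame_rate Frames per second of the recording. Default 20.
#' @param px_per_cm Optional scalar calibration; when supplied, coordinates
#'   read from file are treated as pixels and divided by this factor.
#' @param regions Optional named list of rectangular masks, each a list or
#'   numeric vector with elements `xmin`, `xmax`, `ymin`, `ymax` (cm). Each
#'   must lie within the arena rectangle.
#' @return An object of class `arena_spec`.
#' @export
arena_spec <- function(width = 50.8, height = 25.4, frame_rate = 20,
                       px_per_cm = NULL, regions = list()) {
  stopifnot(is.numeric(width), width > 0, is.numeric(height), height > 0,
            is.numeric(frame_rate), frame_rate > 0)
  if (!is.null(px_per_cm)) stopifnot(is.numeric(px_per_cm), px_per_cm > 0)
  regions <- lapply(regions, function(r) {
    r <- as.list(r)
    need <- c("xmin", "xmax", "ymin", "ymax")
    if (!all(need %in% names(r))) {
      stop("each region mask needs xmin, xmax, ymin, ymax")
    }
    r <- r[need]
    if (r$xmin < 0 || r$ymin < 0 || r$xmax > width || r$ymax > height ||
        r$xmin >= r$xmax || r$ymin >= r$ymax) {
      stop("region mask must be a non-empty rectangle inside the arena")
    }
    r
  })
  structure(list(width = width, height = height, frame_rate = frame_rate,
                 px_per_cm = px_per_cm, regions = regions),
            class = "arena_spec")
}

#' Single-fish trajectory
#'
#' Per-frame x/y positions (cm) with a missing-frame mask. Frames where the
#' tracker lost the fish's ID carry `NA` coordinates until [fill_gaps()] is
#' applied; the mask is kept afterwards as provenance.
#'
#' @param fish_id Identifier (coerced to character).
#' @param x,y Numeric vectors of equal length, positions in cm (`NA` where
#'   missing).
#' @param missing Logical vector, `TRUE` where the fish was unobserved.
#'   Defaults to `is.na(x)`.
#' @param frame_rate Frames per second.
#' @return An object of class `fish_trajectory`.
#' @export
fish_trajectory <- function(fish_id, x, y, missing = is.na(x),
                            frame_rate = 20) {
  stopifnot(length(x) == length(y), length(missing) == length(x),
            is.logical(missing), frame_rate > 0)
  if (all(missing)) stop("fish ", fish_id, " is missing for every frame")
  structure(list(fish_id = as.character(fish_id),
                 x = as.numeric(x), y = as.numeric(y),
                 missing = missing, frame_rate = frame_rate),
            class = "fish_trajectory")
}

#' Number of frames in a trajectory or group recording
#' @param x A `fish_trajectory` or `group_recording`.
#' @return Integer frame count.
#' @export
n_frames <- function(x) {
  if (inherits(x, "group_recording")) x <- x$trajectories[[1]]
  length(x$x)
}

#' Four-fish group recording
#'
#' The unit of analysis: exactly four equal-length trajectories recorded
#' together in one arena, plus labels for population and condition.
#'
#' @param trajectories List of exactly 4 `fish_trajectory` objects with
#'   distinct ids, equal lengths and equal frame rates.
#' @param arena An [arena_spec()].
#' @param group_id Group identifier.
#' @param population_label One of "surface", "cave", "synthetic".
#' @param condition_labels Optional named character vector (e.g. environment,
#'   treatment).
#' @return An object of class `group_recording`.
#' @export
group_recording <- function(trajectories, arena, group_id = "group1",
                            population_label = "synthetic",
                            condition_labels = character()) {
  if (length(trajectories) != 4L) {
    stop("expected 4 fish, got ", length(trajectories))
  }
  stopifnot(inherits(arena, "arena_spec"))
  ids <- vapply(trajectories, function(t) t$fish_id, character(1))
  if (anyDuplicated(ids)) stop("fish ids must be distinct")
  lens <- vapply(trajectories, n_frames, integer(1))
  if (length(unique(lens)) != 1L) {
    stop("inconsistent frame counts across fish: ",
         paste(lens, collapse = ", "))
  }
  frs <- vapply(trajectories, function(t) t$frame_rate, numeric(1))
  if (length(unique(frs)) != 1L) stop("trajectories disagree on frame rate")
  names(trajectories) <- ids
  structure(list(group_id = as.character(group_id),
                 population_label = match.arg(population_label,
                                              c("surface", "cave",
                                                "synthetic")),
                 condition_labels = condition_labels,
                 trajectories = trajectories, arena = arena),
            class = "group_recording")
}

#' @export
print.group_recording <- function(x, ...) {
  cat(sprintf(
    "<group_recording> %s (%s): 4 fish x %d frames @ %g fps, arena %g x %g cm\n",
    x$group_id, x$population_label, n_frames(x),
    x$trajectories[[1]]$frame_rate, x$arena$width, x$arena$height))
  miss <- vapply(x$trajectories, function(t) mean(t$missing), numeric(1))
  cat(sprintf("  fish: %s | missing%%: %s\n",
              paste(names(x$trajectories), collapse = ", "),
              paste(sprintf("%.1f", 100 * miss), collapse = ", ")))
  invisible(x)
}

#' Read a four-fish trajectory table
#'
#' Reads a delimited table with columns `frame, fish_id, x, y` (one row per
#' fish per observed frame; frames where a fish's ID was lost are simply
#' absent) and assembles a validated [group_recording()]. When the arena
#' carries a `px_per_cm` calibration, coordinates are converted from pixels
#' to cm. Frames between each fish's first and last observation that have no
#' row are flagged in the missing mask with `NA` positions; the common frame
#' range is the union across fish.
#'
#' @param path File path to a CSV table.
#' @param arena An [arena_spec()] supplying frame rate and calibration.
#' @param group_id,population_label,condition_labels Passed to
#'   [group_recording()].
#' @param teleport_warn_cm Warn if any consecutive observed displacement
#'   exceeds this many cm (likely an uncorrected identity switch).
#'   Default 20.
#' @return A [group_recording()].
#' @export
read_group <- function(path, arena, group_id = basename(path),
                       population_label = "synthetic",
                       condition_labels = character(),
                       teleport_warn_cm = 20) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame", "fish_id", "x", "y")
  if (!all(need %in% names(tab))) {
    stop("missing columns: ", paste(setdiff(need, names(tab)), collapse = ", "))
  }
  ids <- sort(unique(as.character(tab$fish_id)))
  if (length(ids) != 4L) {
    stop("expected 4 fish, got ", length(ids), " (",
         paste(ids, collapse = ", "), ")")
  }
  f0 <- min(tab$frame); f1 <- max(tab$frame)
  frames <- seq.int(f0, f1)
  n <- length(frames)
  scale <- if (is.null(arena$px_per_cm)) 1 else 1 / arena$px_per_cm
  trajs <- lapply(ids, function(id) {
    sub <- tab[tab$fish_id == id, , drop = FALSE]
    sub <- sub[order(sub$frame), , drop = FALSE]
    if (anyDuplicated(sub$frame)) stop("duplicated frames for fish ", id)
    idx <- match(frames, sub$frame)
    x <- sub$x[idx] * scale
    y <- sub$y[idx] * scale
    obs <- !is.na(idx)
    d <- sqrt(diff(x)^2 + diff(y)^2)
    if (any(d > teleport_warn_cm, na.rm = TRUE)) {
      warning("fish ", id, ": ", sum(d > teleport_warn_cm, na.rm = TRUE),
              " frame-to-frame jumps exceed ", teleport_warn_cm,
              " cm; check identity corrections")
    }
    fish_trajectory(id, x, y, missing = !obs, frame_rate = arena$frame_rate)
  })
  group_recording(trajs, arena, group_id = group_id,
                  population_label = population_label,
                  condition_labels = condition_labels)
}

#' Write a group recording as a trajectory table
#'
#' Inverse of [read_group()]: one row per fish per observed frame (rows for
#' masked frames are omitted), columns `frame, fish_id, x, y` in cm.
#'
#' @param rec A [group_recording()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_group <- function(rec, path) {
  stopifnot(inherits(rec, "group_recording"))
  rows <- lapply(rec$trajectories, function(t) {
    keep <- !t$missing
    data.frame(frame = which(keep) - 1L, fish_id = t$fish_id,
               x = t$x[keep], y = t$y[keep])
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$frame, tab$fish_id), ]
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Discard the lead-in of a recording
#'
#' Drops the first `seconds` of every trajectory; recordings begin with the
#' fish being released, which agitates the water and disrupts tracking, so
#' the first minute is conventionally discarded before analysis.
#'
#' @param rec A [group_recording()].
#' @param seconds Lead-in duration to discard (default 60).
#' @return The trimmed [group_recording()].
#' @export
trim_lead_in <- function(rec, seconds = 60) {
  stopifnot(inherits(rec, "group_recording"), seconds >= 0)
  fr <- rec$trajectories[[1]]$frame_rate
  k <- floor(seconds * fr)
  n <- n_frames(rec)
  if (k >= n) stop("trim of ", seconds, " s (", k,
                   " frames) leaves no frames from ", n)
  if (k == 0) return(rec)
  rec$trajectories <- lapply(rec$trajectories, function(t) {
    keep <- seq.int(k + 1L, n)
    fish_trajectory(t$fish_id, t$x[keep], t$y[keep], t$missing[keep],
                    t$frame_rate)
  })
  rec
}

#' Fill missing-ID gaps in a trajectory
#'
#' Replaces each run of missing frames by constant-velocity straight-line
#' interpolation between the flanking observed positions -- the unique path
#' with constant speed and heading, which is how "averaging velocity and
#' swimming direction" across a gap resolves. Gaps at the recording edges,
#' which have only one flank, hold the nearest observed position constant.
#' Observed frames are untouched and the missing mask is preserved as
#' provenance.
#'
#' @param traj A `fish_trajectory` (or a [group_recording()], in which case
#'   all four trajectories are filled).
#' @return The gap-filled object, same class as the input.
#' @export
fill_gaps <- function(traj) {
  if (inherits(traj, "group_recording")) {
    traj$trajectories <- lapply(traj$trajectories, fill_gaps)
    return(traj)
  }
  stopifnot(inherits(traj, "fish_trajectory"))
  if (!any(traj$missing)) return(traj)
  obs <- which(!traj$missing)
  if (length(obs) < 1L) stop("fish ", traj$fish_id, " has no observed frames")
  idx <- seq_along(traj$x)
  if (length(obs) == 1L) {
    traj$x[] <- traj$x[obs]
    traj$y[] <- traj$y[obs]
    return(traj)
  }
  traj$x <- stats::approx(obs, traj$x[obs], xout = idx, method = "linear",
                          rule = 2)$y
  traj$y <- stats::approx(obs, traj$y[obs], xout = idx, method = "linear",
                          rule = 2)$y
  traj
}
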
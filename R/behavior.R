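#' Visual preference index (VPI)
#'
#' VPI = (SC - No SC) / total frames, where SC is the number of tracked
#' frames with the fish centroid on the social-cue side of the midline and
#' No SC the number on the opposite side. Frames exactly on the midline
#' count to neither side but remain in the denominator; untracked frames
#' (`is_valid = FALSE`) are excluded from both numerator and denominator.
#' VPI ranges from -1 (complete avoidance) to +1 (complete preference).
#'
#' @param traj trajectory data.frame (columns `x`, `is_valid`).
#' @param layout an [arena_layout()].
#' @return VPI, a number in `[-1, 1]`.
#' @export
compute_vpi <- function(traj, layout) {
  stopifnot(inherits(layout, "arena_layout"))
  ok <- traj$is_valid
  n <- sum(ok)
  if (n == 0) stop("no valid tracked frames", call. = FALSE)
  x <- traj$x[ok]
  right <- sum(x > layout$midline_x_px)
  left <- sum(x < layout$midline_x_px)
  sc <- if (identical(layout$sc_side, "right")) right else left
  nosc <- if (identical(layout$sc_side, "right")) left else right
  (sc - nosc) / n
}

#' Classify a fish's sociality from its VPI
#'
#' Pro-social (`+S`) when VPI > 0.5, anti-social (`-S`) when VPI < -0.5,
#' non-social (`ns`) otherwise; the boundary values +/-0.5 fall in `ns`.
#'
#' @param vpi a VPI in `[-1, 1]`.
#' @return one of `"+S"`, `"-S"`, `"ns"`.
#' @export
classify_sociality <- function(vpi) {
  if (is.na(vpi) || vpi < -1 || vpi > 1) {
    stop("vpi must lie in [-1, 1]", call. = FALSE)
  }
  if (vpi > 0.5) "+S" else if (vpi < -0.5) "-S" else "ns"
}

#' Percent time moving
#'
#' 100 times the fraction of valid tracked frames flagged as moving
#' (frame-to-frame changed-pixel count above the motion floor).
#'
#' @param traj trajectory data.frame (columns `is_moving`, `is_valid`).
#' @return percentage in `[0, 100]`.
#' @export
percent_moving <- function(traj) {
  ok <- traj$is_valid
  n <- sum(ok)
  if (n == 0) stop("no valid tracked frames", call. = FALSE)
  100 * sum(traj$is_moving[ok]) / n
}

#' Detect freezing bouts and percent time freezing
#'
#' A freezing bout is a maximal run of consecutive non-moving frames whose
#' duration strictly exceeds `freeze_min_s` (default 3 s, the conventional
#' threshold separating freezing from inter-bout pauses). Percent freezing
#' is 100 times the fraction of frames belonging to such bouts. A single
#' moving frame terminates a run.
#'
#' @param traj trajectory data.frame (column `is_moving`).
#' @param freeze_min_s minimum bout duration, seconds (strict inequality).
#' @param fps frames per second.
#' @return list: `bouts` data.frame (`start_frame`, `end_frame` inclusive
#'   0-based, `duration_s`) and `percent_freezing`.
#' @export
detect_freezes <- function(traj, freeze_min_s = 3.0, fps) {
  if (fps <= 0) stop("fps must be positive", call. = FALSE)
  still <- !traj$is_moving
  r <- rle(still)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & (r$lengths / fps > freeze_min_s)
  bouts <- data.frame(
    start_frame = traj$frame[starts[keep]],
    end_frame = traj$frame[ends[keep]],
    duration_s = r$lengths[keep] / fps
  )
  denom <- if (!is.null(traj$is_valid)) sum(traj$is_valid) else nrow(traj)
  if (denom == 0) stop("no valid tracked frames", call. = FALSE)
  list(bouts = bouts,
       percent_freezing = 100 * sum(r$lengths[keep]) / denom)
}

#' One-minute binned VPI and percent-moving time courses
#'
#' Partitions the session into consecutive bins of `bin_s` seconds and
#' computes VPI and percent moving per bin with the same rules as the
#' session-level statistics. A trailing partial bin is reported with its
#' frame count; bins with no valid frames yield `NA`.
#'
#' @param traj trajectory data.frame.
#' @param layout an [arena_layout()].
#' @param bin_s bin width, seconds.
#' @return data.frame: `bin` (1-based), `n_frames`, `n_valid`, `vpi`,
#'   `percent_moving`.
#' @export
binned_series <- function(traj, layout, bin_s = 60) {
  if (bin_s <= 0) stop("bin_s must be positive", call. = FALSE)
  bin <- floor(traj$time_s / bin_s) + 1L
  bins <- sort(unique(bin))
  res <- lapply(bins, function(b) {
    sub <- traj[bin == b, , drop = FALSE]
    nv <- sum(sub$is_valid)
    data.frame(
      bin = b, n_frames = nrow(sub), n_valid = nv,
      vpi = if (nv > 0) compute_vpi(sub, layout) else NA_real_,
      percent_moving = if (nv > 0) percent_moving(sub) else NA_real_
    )
  })
  do.call(rbind, res)
}

#' All behavioural statistics for one session
#'
#' Convenience wrapper computing VPI, sociality class, percent moving,
#' freezing bouts and the binned time courses from one trajectory.
#'
#' @param traj trajectory data.frame from [track_video()] (or
#'   [as_trajectory()] on simulator ground truth).
#' @param layout an [arena_layout()].
#' @param freeze_min_s minimum freezing-bout duration, seconds.
#' @param bin_s time-course bin width, seconds.
#' @return object of class `session_metrics`: `vpi`, `sociality`,
#'   `percent_moving`, `percent_freezing`, `freeze_bouts`,
#'   `n_valid_frames`, `binned` (from [binned_series()]).
#' @export
session_metrics <- function(traj, layout, freeze_min_s = 3.0, bin_s = 60) {
  vpi <- compute_vpi(traj, layout)
  fr <- detect_freezes(traj, freeze_min_s, layout$fps)
  structure(list(
    vpi = vpi,
    sociality = classify_sociality(vpi),
    percent_moving = percent_moving(traj),
    percent_freezing = fr$percent_freezing,
    freeze_bouts = fr$bouts,
    n_valid_frames = sum(traj$is_valid),
    binned = binned_series(traj, layout, bin_s)
  ), class = "session_metrics")
}

#' @export
print.session_metrics <- function(x, ...) {
  cat(sprintf(
    "session: VPI %.3f (%s) | moving %.1f%% | freezing %.1f%% (%d bouts) | %d valid frames\n",
    x$vpi, x$sociality, x$percent_moving, x$percent_freezing,
    nrow(x$freeze_bouts), x$n_valid_frames))
  invisible(x)
}

#' Convert simulator ground truth to a trajectory table
#'
#' Gives a [generate_trajectory()] result the same column schema as
#' [track_video()] output (all frames valid, motion from the ground-truth
#' moving flag), so behavioural statistics can run directly on simulated
#' sessions without rendering and re-tracking video.
#'
#' @param truth a `ground_truth` object.
#' @return trajectory data.frame.
#' @export
as_trajectory <- function(truth) {
  stopifnot(inherits(truth, "ground_truth"))
  tr <- truth$trajectory
  data.frame(
    frame = tr$frame, time_s = tr$time_s, x = tr$x, y = tr$y,
    heading_deg = tr$heading_deg,
    motion_px = NA_integer_,
    is_moving = tr$is_moving,
    is_valid = TRUE
  )
}

#' Arena layout matching a simulation's parameters
#'
#' @param params a [behavior_sim_params()].
#' @return an [arena_layout()] covering the full simulated frame.
#' @export
layout_from_params <- function(params) {
  arena_layout(
    crop = c(0, 0, params$arena_width_px, params$arena_height_px),
    midline_x_px = params$midline_x_px,
    sc_side = params$sc_side,
    fps = params$fps
  )
}
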
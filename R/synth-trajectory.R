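#' Simulate a ground-truthed swimming trajectory
#'
#' Generates one session of bout-based fish locomotion in the
#' social-preference arena. Swim-bout onsets follow a Poisson process
#' (per-frame Bernoulli approximation at rate `bout_rate_hz / fps`); at each
#' bout the fish commits to the social-cue side with probability
#' `side_bias`, draws a target point uniformly within the committed side,
#' and displaces toward it by a gamma-distributed step capped at the target
#' distance (completing a midline crossing within the bout when the
#' committed side changes, so the stationary side occupancy equals the
#' bias). Between bouts the fish is stationary, so `is_moving` is true
#' exactly on frames with nonzero displacement. Freezing bouts arrive as a
#' second Poisson process with exponentially distributed durations and
#' suppress swim bouts while active.
#'
#' @param params a [behavior_sim_params()] object.
#' @return A list of class `ground_truth` with elements:
#'   \describe{
#'     \item{trajectory}{data.frame with one row per frame: `frame` (0-based),
#'       `time_s`, `x`, `y`, `heading_deg`, `is_moving`, `is_frozen`.}
#'     \item{expected_vpi}{`2 * side_bias - 1`, the stationary-occupancy
#'       expectation of the visual preference index.}
#'     \item{params}{the input parameters.}
#'   }
#' @examples
#' gt <- generate_trajectory(behavior_sim_params(duration_s = 60, seed = 7))
#' mean(gt$trajectory$is_moving)
#' @export
generate_trajectory <- function(params) {
  stopifnot(inherits(params, "behavior_sim_params"))
  validate_behavior_sim_params(params)
  p <- params
  n_frames <- as.integer(round(p$duration_s * p$fps))
  margin <- p$fish_length_px
  xr <- c(margin, p$arena_width_px - 1 - margin)
  yr <- c(margin, p$arena_height_px - 1 - margin)
  if (xr[1] >= xr[2] || yr[1] >= yr[2]) {
    stop("arena too small for fish_length_px margin", call. = FALSE)
  }
  # x ranges of the two sides, leaving the blob clear of the midline
  sc_right <- identical(p$sc_side, "right")
  side_xr <- function(social) {
    right <- xor(!social, sc_right)  # TRUE -> right half
    if (right) c(max(xr[1], p$midline_x_px + margin), xr[2])
    else c(xr[1], min(xr[2], p$midline_x_px - margin))
  }

  with_seed(p$seed, {
    # Injected freezing intervals (frame indices, 1-based)
    frozen <- rep(FALSE, n_frames)
    if (p$freeze_rate_hz > 0) {
      n_fr <- stats::rpois(1, p$freeze_rate_hz * p$duration_s)
      if (n_fr > 0) {
        onset <- sort(stats::runif(n_fr, 0, p$duration_s))
        dur <- stats::rexp(n_fr, rate = 1 / p$freeze_duration_s)
        for (i in seq_len(n_fr)) {
          a <- floor(onset[i] * p$fps) + 1
          b <- min(n_frames, floor((onset[i] + dur[i]) * p$fps))
          if (a <= b) frozen[a:b] <- TRUE
        }
      }
    }

    # Bout onset frames, suppressed during freezes
    p_bout <- min(1, p$bout_rate_hz / p$fps)
    bout_frames <- which(stats::runif(n_frames) < p_bout & !frozen)

    x <- numeric(n_frames)
    y <- numeric(n_frames)
    heading <- numeric(n_frames)
    moving <- rep(FALSE, n_frames)

    cx <- stats::runif(1, xr[1], xr[2])
    cy <- stats::runif(1, yr[1], yr[2])
    ch <- stats::runif(1, 0, 360)
    prev <- 1L
    for (f in bout_frames) {
      if (f > prev) {
        x[prev:(f - 1)] <- cx; y[prev:(f - 1)] <- cy
        heading[prev:(f - 1)] <- ch
      }
      social <- stats::runif(1) < p$side_bias
      txr <- side_xr(social)
      tx <- stats::runif(1, txr[1], txr[2])
      ty <- stats::runif(1, yr[1], yr[2])
      dx <- tx - cx; dy <- ty - cy
      dist <- sqrt(dx^2 + dy^2)
      step <- min(dist, stats::rgamma(1, shape = 4, scale = p$bout_step_px / 4))
      # a bout that commits to the other side swims at least far enough to
      # complete the crossing within the bout; each inter-bout interval is
      # then spent on an independently chosen side, making the stationary
      # SC occupancy exactly side_bias (and E[VPI] = 2*side_bias - 1)
      if (dist > 0) {
        u_x <- dx / dist
        if ((cx - p$midline_x_px) * (tx - p$midline_x_px) < 0) {
          cross <- (p$midline_x_px - cx) / u_x
          step <- max(step, min(dist, cross + stats::runif(1, 1, margin)))
        }
      }
      if (step > 0 && dist > 0) {
        cx <- min(max(cx + dx / dist * step, xr[1]), xr[2])
        cy <- min(max(cy + dy / dist * step, yr[1]), yr[2])
        ch <- (atan2(dy, dx) * 180 / pi) %% 360
        moving[f] <- TRUE
      }
      prev <- f
    }
    if (prev <= n_frames) {
      x[prev:n_frames] <- cx; y[prev:n_frames] <- cy
      heading[prev:n_frames] <- ch
    }

    traj <- data.frame(
      frame = seq_len(n_frames) - 1L,
      time_s = (seq_len(n_frames) - 1L) / p$fps,
      x = x, y = y, heading_deg = heading,
      is_moving = moving, is_frozen = frozen
    )
    structure(
      list(trajectory = traj,
           expected_vpi = 2 * p$side_bias - 1,
           params = p),
      class = "ground_truth"
    )
  })
}

#' @export
print.ground_truth <- function(x, ...) {
  tr <- x$trajectory
  cat(sprintf(
    "ground-truth trajectory: %d frames (%.1f s @ %g fps)\n",
    nrow(tr), x$params$duration_s, x$params$fps
  ))
  cat(sprintf("  expected VPI %.2f | %.1f%% frames moving | %.1f%% frozen\n",
              x$expected_vpi, 100 * mean(tr$is_moving),
              100 * mean(tr$is_frozen)))
  invisible(x)
}

# Ground-truth VPI of a simulated trajectory: fraction of frames on the
# social-cue side minus fraction on the other side (midline frames count to
# neither numerator term).
ground_truth_vpi <- function(truth) {
  p <- truth$params
  x <- truth$trajectory$x
  right <- x > p$midline_x_px
  left <- x < p$midline_x_px
  sc <- if (identical(p$sc_side, "right")) right else left
  no <- if (identical(p$sc_side, "right")) left else right
  (sum(sc) - sum(no)) / length(x)
}
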
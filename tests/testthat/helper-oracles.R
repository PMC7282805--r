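# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the freeze oracle is a frame-by-frame scan, and
# the rank-test oracle enumerates every group labelling.

# Brute-force freezing-bout detector: walk the motion sequence frame by
# frame, close a run when motion resumes, keep runs strictly longer than
# min_s seconds.
freeze_oracle <- function(is_moving, fps, min_s = 3.0) {
  bouts <- list()
  run_start <- NA_integer_
  for (i in seq_along(is_moving)) {
    if (!is_moving[i]) {
      if (is.na(run_start)) run_start <- i
    } else if (!is.na(run_start)) {
      len <- i - run_start
      if (len / fps > min_s) {
        bouts[[length(bouts) + 1]] <- c(run_start - 1L, i - 2L)
      }
      run_start <- NA_integer_
    }
  }
  if (!is.na(run_start)) {
    len <- length(is_moving) - run_start + 1L
    if (len / fps > min_s) {
      bouts[[length(bouts) + 1]] <- c(run_start - 1L, length(is_moving) - 1L)
    }
  }
  if (!length(bouts)) {
    return(data.frame(start_frame = integer(0), end_frame = integer(0)))
  }
  m <- do.call(rbind, bouts)
  data.frame(start_frame = m[, 1], end_frame = m[, 2])
}

# Exact Mann-Whitney by full enumeration: U for every way of labelling
# n_a of the pooled values as group A; two-sided p doubles the smaller
# tail, capped at 1.
mwu_enumeration_oracle <- function(x, y) {
  n_a <- length(x)
  pooled <- c(x, y)
  r <- rank(pooled)
  idx <- utils::combn(length(pooled), n_a)
  u_all <- apply(idx, 2, function(ii) sum(r[ii]) - n_a * (n_a + 1) / 2)
  u_obs <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  p <- 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs))
  list(u = u_obs, p = min(1, p))
}

# Minimal boolean-motion trajectory for behaviour-stage tests.
motion_traj <- function(is_moving, fps = 30) {
  n <- length(is_moving)
  data.frame(
    frame = seq_len(n) - 1L, time_s = (seq_len(n) - 1L) / fps,
    x = 0, y = 0, heading_deg = 0, motion_px = NA_integer_,
    is_moving = is_moving, is_valid = TRUE
  )
}

# Trajectory with prescribed x positions (all valid, never moving).
x_traj <- function(x, fps = 30) {
  n <- length(x)
  data.frame(
    frame = seq_len(n) - 1L, time_s = (seq_len(n) - 1L) / fps,
    x = x, y = 0, heading_deg = 0, motion_px = NA_integer_,
    is_moving = FALSE, is_valid = TRUE
  )
}

# A hand-built ground_truth holding a single fixed pose, for rendering
# tests that need exact control over position and heading.
fixed_pose_truth <- function(x, y, heading = 0, n = 1, params) {
  structure(list(
    trajectory = data.frame(
      frame = seq_len(n) - 1L, time_s = (seq_len(n) - 1L) / params$fps,
      x = rep(x, n), y = rep(y, n), heading_deg = rep(heading, n),
      is_moving = FALSE, is_frozen = FALSE
    ),
    expected_vpi = 0, params = params
  ), class = "ground_truth")
}

test_layout <- function(w = 200, h = 200, mid = 100, sc = "right", fps = 30) {
  arena_layout(c(0, 0, w, h), midline_x_px = mid, sc_side = sc, fps = fps)
}
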
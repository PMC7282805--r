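#' Arena layout for tracking and preference analysis
#'
#' Describes how frames map onto the three-chamber assay: the crop
#' rectangle containing the test-fish chamber, the x position of the
#' virtual midline separating the social-cue (SC) side from the
#' no-social-cue (No SC) side, which side holds the social cue, and the
#' frame rate. The cue chamber is randomized left/right across sessions, so
#' `sc_side` is part of the layout rather than a data transformation.
#'
#' @param crop integer vector `(x0, y0, width, height)` in 0-based pixel
#'   coordinates of the full frame.
#' @param midline_x_px x coordinate of the SC / No-SC divide, in cropped
#'   coordinates; must fall strictly inside the crop.
#' @param sc_side `"right"` (x > midline is the SC side) or `"left"`.
#' @param fps frames per second.
#' @return object of class `arena_layout`.
#' @export
arena_layout <- function(crop, midline_x_px, sc_side = c("right", "left"),
                         fps = 30) {
  sc_side <- match.arg(sc_side)
  crop <- as.integer(crop)
  if (length(crop) != 4 || any(crop[3:4] <= 0)) {
    stop("crop must be (x0, y0, width, height) with positive size",
         call. = FALSE)
  }
  if (fps <= 0) stop("fps must be positive", call. = FALSE)
  if (midline_x_px <= 0 || midline_x_px >= crop[3]) {
    stop("midline_x_px must fall strictly inside the crop", call. = FALSE)
  }
  structure(list(crop = crop, midline_x_px = midline_x_px,
                 sc_side = sc_side, fps = fps),
            class = "arena_layout")
}

#' Tracking configuration
#'
#' Thresholds for the crop / background-subtract / threshold chain. The
#' assay's camera and illumination vary between rigs, so all thresholds are
#' explicit configuration; the defaults are calibrated on the synthetic
#' videos of [rasterize_video()] (intensities in `[0, 1]`).
#'
#' @param intensity_threshold minimum absolute background difference for a
#'   pixel to count as fish.
#' @param min_area_px minimum connected-component area (pixels) for a valid
#'   fish detection.
#' @param pixel_delta_threshold minimum absolute frame-to-frame intensity
#'   change for a pixel to count as changed.
#' @param motion_count_threshold a frame is "moving" when more than this
#'   many pixels changed; keeps pure sensor noise below the motion floor.
#' @param background_stride stride of the frame sample used for the
#'   median background model.
#' @return object of class `track_config`.
#' @export
track_config <- function(intensity_threshold = 0.2,
                         min_area_px = 5,
                         pixel_delta_threshold = 0.1,
                         motion_count_threshold = 10,
                         background_stride = 10) {
  stopifnot(intensity_threshold > 0, min_area_px >= 1,
            pixel_delta_threshold > 0, motion_count_threshold >= 0,
            background_stride >= 1)
  structure(list(intensity_threshold = intensity_threshold,
                 min_area_px = min_area_px,
                 pixel_delta_threshold = pixel_delta_threshold,
                 motion_count_threshold = motion_count_threshold,
                 background_stride = as.integer(background_stride)),
            class = "track_config")
}

#' Median background model from a strided frame sample
#'
#' Per-pixel median over every `sample_stride`-th frame. The fish occupies
#' any one pixel a minority of the time, so the median recovers the empty
#' arena without needing a fish-free recording.
#'
#' @param frames array `h x w x n`.
#' @param sample_stride sampling stride (frames).
#' @return matrix `h x w`.
#' @export
build_background <- function(frames, sample_stride = 10) {
  stopifnot(is.array(frames), length(dim(frames)) == 3)
  n <- dim(frames)[3]
  if (n == 0) stop("empty frame stack", call. = FALSE)
  idx <- seq(1, n, by = as.integer(sample_stride))
  if (length(idx) < 2) {
    stop("background model needs at least 2 sampled frames", call. = FALSE)
  }
  sub <- frames[, , idx, drop = FALSE]
  apply(sub, c(1, 2), stats::median)
}

#' Segment the fish in one background-subtracted frame
#'
#' Thresholds the absolute background difference, labels connected
#' components, and takes the largest component above `min_area_px` as the
#' fish. The centroid is the difference-intensity-weighted component
#' centroid; the heading is the principal axis of the second-order moments,
#' pointed toward the heavier (head) half of the blob, with a confidence
#' score from the mass asymmetry (near zero for a symmetric blob, where the
#' head/tail choice is arbitrary).
#'
#' @param frame,background matrices of identical shape.
#' @param intensity_threshold,min_area_px see [track_config()].
#' @return list: `x`, `y` (0-based pixel coords), `heading_deg` in
#'   `[0, 360)`, `area` (pixels), `is_valid`, `head_confidence`.
#' @export
segment_fish <- function(frame, background, intensity_threshold = 0.2,
                         min_area_px = 5) {
  if (!identical(dim(frame), dim(background))) {
    stop("frame and background shapes differ", call. = FALSE)
  }
  d <- abs(frame - background)
  bw <- d > intensity_threshold
  none <- list(x = NA_real_, y = NA_real_, heading_deg = NA_real_,
               area = 0L, is_valid = FALSE, head_confidence = NA_real_)
  if (!any(bw)) return(none)
  lab <- EBImage::bwlabel(bw)
  sizes <- tabulate(lab[lab > 0])
  best <- which.max(sizes)
  if (sizes[best] < min_area_px) return(none)
  sel <- which(lab == best)
  wgt <- d[sel]
  rc <- arrayInd(sel, dim(frame))
  px <- rc[, 2] - 1  # x = column, 0-based
  py <- rc[, 1] - 1  # y = row, 0-based
  sw <- sum(wgt)
  cx <- sum(wgt * px) / sw
  cy <- sum(wgt * py) / sw
  # principal axis from second-order central moments
  mu20 <- sum(wgt * (px - cx)^2) / sw
  mu02 <- sum(wgt * (py - cy)^2) / sw
  mu11 <- sum(wgt * (px - cx) * (py - cy)) / sw
  ang <- 0.5 * atan2(2 * mu11, mu20 - mu02)  # radians, axis only
  # head/tail disambiguation: more intensity mass ahead of the centroid
  proj <- (px - cx) * cos(ang) + (py - cy) * sin(ang)
  asym <- sum(wgt * sign(proj)) / sw
  if (asym < 0) ang <- ang + pi
  list(x = cx, y = cy,
       heading_deg = (ang * 180 / pi) %% 360,
       area = sizes[best], is_valid = TRUE,
       head_confidence = abs(asym))
}

#' Count changed pixels between consecutive frames
#'
#' @param frame_t,frame_prev matrices of identical shape.
#' @param pixel_delta_threshold see [track_config()].
#' @return integer count of pixels whose absolute difference exceeds the
#'   threshold.
#' @export
detect_motion <- function(frame_t, frame_prev, pixel_delta_threshold = 0.1) {
  if (!identical(dim(frame_t), dim(frame_prev))) {
    stop("frame shapes differ", call. = FALSE)
  }
  sum(abs(frame_t - frame_prev) > pixel_delta_threshold)
}

#' Track a fish through a video
#'
#' The full video-analysis chain: crop each frame to the arena, build a
#' median background model, then per frame segment the fish and count
#' changed pixels versus the previous frame. Frames where no fish is found
#' are flagged `is_valid = FALSE` but retained, so frame indices stay
#' aligned with the video.
#'
#' @param video array `h x w x n`, multi-page TIFF path, or PNG directory
#'   (see [read_video()]).
#' @param layout an [arena_layout()].
#' @param config a [track_config()].
#' @return data.frame with one row per frame: `frame` (0-based), `time_s`,
#'   `x`, `y`, `heading_deg` (cropped 0-based pixel coords), `motion_px`,
#'   `is_moving`, `is_valid`. The first frame has `motion_px = 0` and
#'   `is_moving = FALSE` by convention.
#' @export
track_video <- function(video, layout, config = track_config()) {
  stopifnot(inherits(layout, "arena_layout"), inherits(config, "track_config"))
  frames <- read_video(video)
  d <- dim(frames)
  cr <- layout$crop
  if (cr[1] + cr[3] > d[2] || cr[2] + cr[4] > d[1]) {
    stop("arena crop exceeds frame bounds", call. = FALSE)
  }
  rows <- (cr[2] + 1):(cr[2] + cr[4])
  cols <- (cr[1] + 1):(cr[1] + cr[3])
  frames <- frames[rows, cols, , drop = FALSE]
  n <- d[3]
  bg <- build_background(frames, config$background_stride)

  out <- data.frame(
    frame = seq_len(n) - 1L,
    time_s = (seq_len(n) - 1L) / layout$fps,
    x = NA_real_, y = NA_real_, heading_deg = NA_real_,
    motion_px = 0L, is_moving = FALSE, is_valid = FALSE
  )
  for (i in seq_len(n)) {
    f <- frames[, , i]
    s <- segment_fish(f, bg, config$intensity_threshold, config$min_area_px)
    out$x[i] <- s$x; out$y[i] <- s$y
    out$heading_deg[i] <- s$heading_deg
    out$is_valid[i] <- s$is_valid
    if (i > 1) {
      m <- detect_motion(f, frames[, , i - 1], config$pixel_delta_threshold)
      out$motion_px[i] <- m
      out$is_moving[i] <- m > config$motion_count_threshold
    }
  }
  if (mean(out$is_valid) < 0.5) {
    warning("fish detected in fewer than 50% of frames", call. = FALSE)
  }
  out
}

#' Write / read a trajectory table as CSV
#'
#' @param traj trajectory data.frame from [track_video()].
#' @param path CSV path.
#' @return the path (write) or the trajectory data.frame (read).
#' @export
write_trajectory_csv <- function(traj, path) {
  utils::write.csv(traj, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path) {
  tr <- utils::read.csv(path)
  tr$is_moving <- as.logical(tr$is_moving)
  tr$is_valid <- as.logical(tr$is_valid)
  tr
}
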
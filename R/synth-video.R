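#' Rasterize a trajectory into a grayscale frame stack
#'
#' Renders each frame as a constant background with additive Gaussian pixel
#' noise and a uniform-intensity ellipse-shaped fish blob centred at the
#' trajectory position and oriented along the heading. The blob's
#' photometry is constant across frames, so frame-to-frame pixel changes
#' come only from fish displacement (and noise).
#'
#' Frames are matrices indexed `[y + 1, x + 1]` (image convention: x
#' rightward, y downward, 0-based pixel coordinates) with intensities in
#' `[0, 1]`.
#'
#' @param truth a `ground_truth` object from [generate_trajectory()].
#' @param params the [behavior_sim_params()] used for the trajectory
#'   (defaults to the ones stored in `truth`).
#' @return A numeric array `arena_height_px x arena_width_px x n_frames`.
#' @export
rasterize_video <- function(truth, params = truth$params) {
  stopifnot(inherits(truth, "ground_truth"))
  p <- params
  tr <- truth$trajectory
  h <- p$arena_height_px
  w <- p$arena_width_px
  if (any(tr$x < 0 | tr$x > w - 1 | tr$y < 0 | tr$y > h - 1)) {
    stop("trajectory leaves the arena bounds", call. = FALSE)
  }
  n <- nrow(tr)
  frames <- array(p$background_intensity, dim = c(h, w, n))
  # render noise with a stream derived from the seed so videos are
  # reproducible independently of trajectory generation
  with_seed(p$seed + 104729L, {
    if (p$noise_sd > 0) {
      frames <- frames + stats::rnorm(length(frames), 0, p$noise_sd)
    }
    for (i in seq_len(n)) {
      frames[, , i] <- draw_fish_blob(
        frames[, , i], tr$x[i], tr$y[i], tr$heading_deg[i],
        length_px = p$fish_length_px, intensity = p$fish_intensity
      )
    }
  })
  frames[frames < 0] <- 0
  frames[frames > 1] <- 1
  frames
}

# Paint a uniform ellipse (semi-axes L/2 along the heading, L/4 across)
# onto one frame; a pixel belongs to the blob if its centre falls inside
# the ellipse.
draw_fish_blob <- function(frame, x, y, heading_deg, length_px, intensity) {
  a <- length_px / 2
  b <- length_px / 4
  th <- heading_deg * pi / 180
  h <- nrow(frame); w <- ncol(frame)
  r0 <- max(1L, floor(y - a) + 1L); r1 <- min(h, ceiling(y + a) + 1L)
  c0 <- max(1L, floor(x - a) + 1L); c1 <- min(w, ceiling(x + a) + 1L)
  rows <- r0:r1; cols <- c0:c1
  py <- rows - 1; px <- cols - 1
  dx <- outer(rep(1, length(py)), px - x)
  dy <- outer(py - y, rep(1, length(px)))
  u <- dx * cos(th) + dy * sin(th)
  v <- -dx * sin(th) + dy * cos(th)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  sub <- frame[rows, cols, drop = FALSE]
  sub[inside] <- intensity
  frame[rows, cols] <- sub
  frame
}

#' Write a frame stack as a multi-page TIFF
#'
#' @param frames array `h x w x n` with values in `[0, 1]`.
#' @param path output file (`.tif`/`.tiff`).
#' @return `path`, invisibly.
#' @export
write_video_tiff <- function(frames, path) {
  stopifnot(is.array(frames), length(dim(frames)) == 3)
  pages <- lapply(seq_len(dim(frames)[3]), function(i) frames[, , i])
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Write a frame stack as a directory of numbered PNGs
#'
#' @param frames array `h x w x n` with values in `[0, 1]`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_video_png_dir <- function(frames, dir) {
  stopifnot(is.array(frames), length(dim(frames)) == 3)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  n <- dim(frames)[3]
  for (i in seq_len(n)) {
    png::writePNG(frames[, , i],
                  file.path(dir, sprintf("frame_%06d.png", i - 1L)))
  }
  invisible(dir)
}

#' Read a video as a frame-stack array
#'
#' Accepts a numeric array `h x w x n` (returned unchanged), a multi-page
#' TIFF file, or a directory of PNG frames (sorted by filename).
#'
#' @param video array, TIFF path, or PNG directory.
#' @return numeric array `h x w x n`.
#' @export
read_video <- function(video) {
  if (is.array(video) && length(dim(video)) == 3) return(video)
  if (!is.character(video) || length(video) != 1) {
    stop("video must be an array, a TIFF path, or a PNG directory",
         call. = FALSE)
  }
  if (dir.exists(video)) {
    files <- sort(list.files(video, pattern = "\\.png$", full.names = TRUE))
    if (!length(files)) stop("no PNG frames found in ", video, call. = FALSE)
    pages <- lapply(files, function(f) drop_channels(png::readPNG(f)))
  } else {
    if (!file.exists(video)) stop("cannot read video: ", video, call. = FALSE)
    pages <- tiff::readTIFF(video, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    pages <- lapply(pages, drop_channels)
  }
  array(unlist(pages, use.names = FALSE),
        dim = c(dim(pages[[1]])[1:2], length(pages)))
}

drop_channels <- function(img) {
  if (length(dim(img)) == 3) img[, , 1] else img
}
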
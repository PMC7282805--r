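#' Parameters for the behavioural session simulator
#'
#' Bundles everything needed to simulate one fish swimming in the
#' three-chamber social-preference arena: session geometry, bout-based
#' locomotion parameters, freezing-bout injection, and rendering photometry.
#'
#' Zebrafish locomotion is bout-like: brief propulsive events separated by
#' stillness. The simulator draws bout onsets as a Poisson process and, at
#' each bout, re-draws the side of the arena the fish is committed to with
#' probability `side_bias` for the social-cue side. Under this model the
#' stationary fraction of time spent on the social-cue side equals
#' `side_bias`, so the expected visual preference index is
#' `2 * side_bias - 1`.
#'
#' @param duration_s session length in seconds.
#' @param fps frames per second of the (virtual) camera.
#' @param arena_width_px,arena_height_px arena size in pixels.
#' @param midline_x_px x coordinate of the virtual line separating the
#'   social-cue side from the no-social-cue side.
#' @param sc_side which side of the midline holds the social cue
#'   (`"right"` means x > midline).
#' @param side_bias probability in `[0, 1]` that a bout commits the fish to
#'   the social-cue side.
#' @param bout_rate_hz swim-bout rate (bouts per second).
#' @param bout_step_px mean displacement per bout, pixels. Displacements are
#'   gamma-distributed (shape 4), capped at the distance to the current
#'   target; a bout that commits to the opposite side swims at least far
#'   enough to complete the crossing, so every inter-bout interval is spent
#'   on the side that bout committed to.
#' @param freeze_rate_hz rate of injected freezing bouts (per second).
#' @param freeze_duration_s mean duration of an injected freezing bout
#'   (exponentially distributed). Swim bouts are suppressed while frozen.
#' @param fish_length_px body length of the rendered fish, pixels.
#' @param noise_sd standard deviation of per-pixel Gaussian intensity noise
#'   added when rasterizing (intensities live in `[0, 1]`).
#' @param fish_intensity,background_intensity blob and arena intensities in
#'   `[0, 1]` used by [rasterize_video()].
#' @param seed integer RNG seed; identical seed and parameters give
#'   bit-identical trajectories and videos.
#'
#' @return An object of class `behavior_sim_params` (a validated list).
#' @seealso [generate_trajectory()], [rasterize_video()]
#' @export
behavior_sim_params <- function(duration_s = 900,
                                fps = 30,
                                arena_width_px = 200,
                                arena_height_px = 200,
                                midline_x_px = 100,
                                sc_side = c("right", "left"),
                                side_bias = 0.5,
                                bout_rate_hz = 2,
                                bout_step_px = 120,
                                freeze_rate_hz = 0,
                                freeze_duration_s = 5,
                                fish_length_px = 14,
                                noise_sd = 0.01,
                                fish_intensity = 0.8,
                                background_intensity = 0.1,
                                seed = 1L) {
  sc_side <- match.arg(sc_side)
  p <- list(
    duration_s = duration_s, fps = fps,
    arena_width_px = arena_width_px, arena_height_px = arena_height_px,
    midline_x_px = midline_x_px, sc_side = sc_side,
    side_bias = side_bias, bout_rate_hz = bout_rate_hz,
    bout_step_px = bout_step_px, freeze_rate_hz = freeze_rate_hz,
    freeze_duration_s = freeze_duration_s, fish_length_px = fish_length_px,
    noise_sd = noise_sd, fish_intensity = fish_intensity,
    background_intensity = background_intensity, seed = as.integer(seed)
  )
  validate_behavior_sim_params(p)
  structure(p, class = "behavior_sim_params")
}

validate_behavior_sim_params <- function(p) {
  stopifnot(is.numeric(p$duration_s), is.numeric(p$fps))
  if (p$duration_s <= 0 || p$fps <= 0) {
    stop("duration_s and fps must be positive", call. = FALSE)
  }
  if (p$side_bias < 0 || p$side_bias > 1) {
    stop("side_bias must lie in [0, 1]", call. = FALSE)
  }
  geom <- c(p$arena_width_px, p$arena_height_px, p$fish_length_px,
            p$bout_step_px)
  if (any(geom <= 0)) {
    stop("geometric parameters must be positive", call. = FALSE)
  }
  if (p$midline_x_px <= 0 || p$midline_x_px >= p$arena_width_px) {
    stop("midline_x_px must fall strictly inside the arena", call. = FALSE)
  }
  if (p$bout_rate_hz < 0 || p$freeze_rate_hz < 0 || p$freeze_duration_s <= 0) {
    stop("rates must be non-negative and freeze_duration_s positive",
         call. = FALSE)
  }
  if (p$noise_sd < 0) stop("noise_sd must be non-negative", call. = FALSE)
  invisible(p)
}

#' Parameters for the synthetic brain-volume cohort generator
#'
#' Describes a cohort of registered whole-brain fluorescence volumes: an
#' ellipsoidal "brain" filled with a noisy background fluorescence plateau
#' sitting inside a darker non-tissue region, per-fish affine intensity
#' distortions (gain and offset) that mimic session-to-session imaging
#' variation, and fold-change activations planted inside named region masks.
#'
#' Each fish `i` receives its own gain and offset: the gain is lognormal
#' around `session_gain` with 10% coefficient of variation and the offset is
#' normal around `session_offset` (sd = 10% of its magnitude + 1 unit), so
#' no two volumes share an intensity scale and the histogram normalization
#' step has real work to do. Non-tissue voxels carry reduced noise
#' (`background_sd / 5`), mimicking detector read-noise versus photon shot
#' noise in tissue; their intensity floor is what the bias estimate of the
#' normalization recovers.
#'
#' @param dims integer vector of voxel counts `(x, y, z)`.
#' @param background_level tissue background fluorescence, arbitrary units.
#' @param background_sd noise sd inside tissue, same units.
#' @param session_gain central multiplicative distortion (> 0).
#' @param session_offset central additive distortion, intensity units.
#' @param planted_effects named numeric vector: `mask_name = fold_change`
#'   with fold_change >= 0; voxels inside that mask have mean
#'   `background_level * fold_change`.
#' @param n_fish_per_group number of fish simulated per call to
#'   [generate_volume_cohort()].
#' @param seed integer RNG seed; identical seed gives bit-identical volumes.
#'
#' @return An object of class `volume_sim_params`.
#' @seealso [generate_volume_cohort()], [synthetic_region_masks()]
#' @export
volume_sim_params <- function(dims = c(64, 64, 32),
                              background_level = 1000,
                              background_sd = 50,
                              session_gain = 1,
                              session_offset = 0,
                              planted_effects = numeric(0),
                              n_fish_per_group = 10,
                              seed = 1L) {
  p <- list(
    dims = as.integer(dims), background_level = background_level,
    background_sd = background_sd, session_gain = session_gain,
    session_offset = session_offset, planted_effects = planted_effects,
    n_fish_per_group = as.integer(n_fish_per_group), seed = as.integer(seed)
  )
  if (length(p$dims) != 3L || any(p$dims <= 0L)) {
    stop("dims must be three positive voxel counts", call. = FALSE)
  }
  if (p$session_gain <= 0) stop("session_gain must be > 0", call. = FALSE)
  if (p$background_sd < 0) stop("background_sd must be >= 0", call. = FALSE)
  if (length(p$planted_effects) &&
      (is.null(names(p$planted_effects)) || any(p$planted_effects < 0))) {
    stop("planted_effects must be a named vector of fold changes >= 0",
         call. = FALSE)
  }
  if (p$n_fish_per_group < 1L) stop("n_fish_per_group must be >= 1",
                                    call. = FALSE)
  structure(p, class = "volume_sim_params")
}

# Evaluate `expr` under a private RNG stream seeded with `seed`, restoring
# the caller's .Random.seed afterwards so simulation calls do not perturb
# user code.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
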
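test_that("parameter validation rejects impossible sessions", {
  expect_error(behavior_sim_params(duration_s = 0), "positive")
  expect_error(behavior_sim_params(fps = -1), "positive")
  expect_error(behavior_sim_params(side_bias = 1.2), "side_bias")
  expect_error(behavior_sim_params(midline_x_px = 300), "midline")
  expect_error(volume_sim_params(session_gain = 0), "session_gain")
  expect_error(volume_sim_params(dims = c(64, 64)), "dims")
  expect_error(volume_sim_params(planted_effects = c(1.3)), "named")
})

test_that("trajectories are deterministic and the right length", {
  p <- behavior_sim_params(duration_s = 60, seed = 5, freeze_rate_hz = 0.05)
  a <- generate_trajectory(p)
  b <- generate_trajectory(p)
  expect_identical(a, b)
  expect_equal(nrow(a$trajectory), 60 * 30)
  expect_equal(a$expected_vpi, 2 * p$side_bias - 1)
  # different seed diverges
  c <- generate_trajectory(behavior_sim_params(duration_s = 60, seed = 6,
                                               freeze_rate_hz = 0.05))
  expect_false(identical(a$trajectory$x, c$trajectory$x))
})

test_that("full side bias pins the fish to the social-cue side", {
  p <- behavior_sim_params(duration_s = 120, side_bias = 1, seed = 2)
  gt <- generate_trajectory(p)
  expect_equal(gt$expected_vpi, 1)
  # after the first few bouts every frame is on the SC (right) side
  late <- gt$trajectory$x[gt$trajectory$time_s > 10]
  expect_true(all(late > p$midline_x_px))
})

test_that("no freeze bouts are injected when the freeze rate is zero", {
  gt <- generate_trajectory(behavior_sim_params(duration_s = 120, seed = 3))
  expect_equal(sum(gt$trajectory$is_frozen), 0)
})

test_that("injected freezes suppress motion and are marked in ground truth", {
  gt <- generate_trajectory(behavior_sim_params(
    duration_s = 300, freeze_rate_hz = 0.05, freeze_duration_s = 6, seed = 9))
  tr <- gt$trajectory
  expect_gt(sum(tr$is_frozen), 0)
  expect_false(any(tr$is_moving & tr$is_frozen))
})

test_that("moving flags mark exactly the frames with displacement", {
  gt <- generate_trajectory(behavior_sim_params(duration_s = 120, seed = 4))
  tr <- gt$trajectory
  disp <- c(0, sqrt(diff(tr$x)^2 + diff(tr$y)^2))
  expect_identical(tr$is_moving, disp > 0)
})

test_that("rendered blob centroid lands on the trajectory position", {
  p <- behavior_sim_params(noise_sd = 0, seed = 1)
  for (pose in list(c(50, 60, 0), c(120.3, 80.7, 37), c(100, 100, 90))) {
    gt <- fixed_pose_truth(pose[1], pose[2], pose[3], n = 1, params = p)
    fr <- rasterize_video(gt)[, , 1]
    mask <- fr > p$background_intensity + 0.1
    cx <- mean(which(mask, arr.ind = TRUE)[, 2] - 1)
    cy <- mean(which(mask, arr.ind = TRUE)[, 1] - 1)
    expect_lt(abs(cx - pose[1]), 0.5)
    expect_lt(abs(cy - pose[2]), 0.5)
  }
})

test_that("stationary noiseless frames are bit-identical; seeds reproduce", {
  p <- behavior_sim_params(noise_sd = 0, seed = 1)
  gt <- fixed_pose_truth(80, 90, 45, n = 2, params = p)
  vid <- rasterize_video(gt)
  expect_identical(vid[, , 1], vid[, , 2])

  p2 <- behavior_sim_params(duration_s = 3, noise_sd = 0.02, seed = 8)
  gt2 <- generate_trajectory(p2)
  expect_identical(rasterize_video(gt2), rasterize_video(gt2))
})

test_that("rasterizing a trajectory outside the arena errors", {
  p <- behavior_sim_params(noise_sd = 0)
  gt <- fixed_pose_truth(500, 60, 0, n = 1, params = p)
  expect_error(rasterize_video(gt), "arena bounds")
})

test_that("video writers and readers round-trip a frame stack", {
  p <- behavior_sim_params(duration_s = 1, noise_sd = 0, seed = 1)
  vid <- rasterize_video(generate_trajectory(p))
  tf <- tempfile(fileext = ".tif")
  write_video_tiff(vid, tf)
  back <- read_video(tf)
  expect_equal(dim(back), dim(vid))
  expect_lt(max(abs(back - vid)), 1 / 65535)  # 16-bit quantization
  td <- tempfile()
  write_video_png_dir(vid, td)
  back2 <- read_video(td)
  expect_equal(dim(back2), dim(vid))
  expect_lt(max(abs(back2 - vid)), 1 / 255)
})

test_that("volume cohorts are deterministic and masks must align", {
  dims <- c(32, 32, 16)
  ms <- synthetic_region_masks(dims, c("PTN", "tectum"))
  p <- volume_sim_params(dims = dims, n_fish_per_group = 3, seed = 11,
                         planted_effects = c(PTN = 1.5))
  a <- generate_volume_cohort(p, ms)
  b <- generate_volume_cohort(p, ms)
  expect_identical(a, b)
  expect_equal(a$truth$true_region_folds, c(PTN = 1.5, tectum = 1))

  bad <- synthetic_region_masks(c(16, 16, 8), "PTN")
  expect_error(generate_volume_cohort(p, bad), "dims")
  expect_error(
    generate_volume_cohort(
      volume_sim_params(dims = dims, planted_effects = c(missing = 2)), ms),
    "not supplied")
})

test_that("planted effects elevate mask means by exactly the fold before noise", {
  dims <- c(32, 32, 16)
  ms <- synthetic_region_masks(dims, c("PTN", "tectum"))
  p <- volume_sim_params(dims = dims, background_sd = 0, n_fish_per_group = 1,
                         seed = 4, planted_effects = c(PTN = 1.3),
                         session_gain = 2, session_offset = 500)
  co <- generate_volume_cohort(p, ms)
  v <- co$volumes[[1]]$voxels
  gain <- co$truth$gains[1]; off <- co$truth$offsets[1]
  inside <- mean(v[ms$PTN$voxels])
  bg <- mean(v[co$truth$brain & !ms$PTN$voxels & !ms$tectum$voxels])
  expect_equal((inside - off) / (bg - off), 1.3, tolerance = 1e-10)
  expect_equal(bg, gain * 1000 + off, tolerance = 1e-10)
})

test_that("volume NIfTI round-trip preserves voxels", {
  p <- volume_sim_params(dims = c(16, 16, 8), n_fish_per_group = 1, seed = 1)
  v <- generate_volume_cohort(p, list())$volumes[[1]]
  tf <- tempfile(fileext = ".nii.gz")
  write_volume_nifti(v, tf)
  back <- read_volume_nifti(tf, fish_id = v$fish_id)
  expect_equal(back$voxels, v$voxels, tolerance = 1e-6)
})
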
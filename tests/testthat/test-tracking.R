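test_that("background model recovers the empty arena", {
  # constant frames: background equals that constant image
  frames <- array(0.3, dim = c(10, 12, 5))
  expect_equal(build_background(frames, 1), matrix(0.3, 10, 12))
  # too few samples
  expect_error(build_background(frames, 10), "at least 2")

  # moving fish, no noise: median over time sees the empty arena everywhere
  p <- behavior_sim_params(duration_s = 20, noise_sd = 0, seed = 13)
  vid <- rasterize_video(generate_trajectory(p))
  bg <- build_background(vid, 5)
  empty <- matrix(p$background_intensity, p$arena_height_px, p$arena_width_px)
  expect_lt(max(abs(bg - empty)), 1e-12)
})

test_that("segmentation finds the blob centroid and flags empty frames", {
  p <- behavior_sim_params(noise_sd = 0)
  bg <- matrix(p$background_intensity, 200, 200)
  gt <- fixed_pose_truth(50, 60, 20, n = 1, params = p)
  fr <- rasterize_video(gt)[, , 1]
  s <- segment_fish(fr, bg)
  expect_true(s$is_valid)
  expect_lt(abs(s$x - 50), 0.5)
  expect_lt(abs(s$y - 60), 0.5)
  expect_gt(s$area, 20)

  empty <- segment_fish(bg, bg)
  expect_false(empty$is_valid)
  expect_true(is.na(empty$x))

  expect_error(segment_fish(fr, matrix(0, 10, 10)), "shapes differ")
})

test_that("the largest connected component is taken as the fish", {
  fr <- matrix(0, 60, 60)
  fr[10:19, 10:21] <- 1   # 120 px blob
  fr[40:47, 40:44] <- 1   # 40 px blob
  s <- segment_fish(fr, matrix(0, 60, 60), intensity_threshold = 0.5)
  expect_equal(s$area, 120L)
  expect_lt(abs(s$x - mean(9:20)), 1e-9)  # centroid of the 120 px blob
  expect_lt(abs(s$y - mean(9:18)), 1e-9)
})

test_that("heading follows the blob's principal axis", {
  p <- behavior_sim_params(noise_sd = 0)
  bg <- matrix(p$background_intensity, 200, 200)
  for (h in c(0, 30, 90, 150)) {
    fr <- rasterize_video(fixed_pose_truth(100, 100, h, 1, p))[, , 1]
    got <- segment_fish(fr, bg)$heading_deg
    axis_err <- min(abs(got - h) %% 180, 180 - abs(got - h) %% 180)
    expect_lt(axis_err, 6)
  }
})

test_that("motion counts changed pixels and stays silent on noise", {
  a <- matrix(0.2, 50, 50)
  expect_equal(detect_motion(a, a), 0)
  expect_error(detect_motion(a, matrix(0, 10, 10)), "shapes differ")

  # displaced blob, no noise: count equals the symmetric footprint difference
  p <- behavior_sim_params(noise_sd = 0)
  f1 <- rasterize_video(fixed_pose_truth(80, 100, 0, 1, p))[, , 1]
  f2 <- rasterize_video(fixed_pose_truth(85, 100, 0, 1, p))[, , 1]
  m1 <- f1 > p$background_intensity + 0.1
  m2 <- f2 > p$background_intensity + 0.1
  expect_equal(detect_motion(f2, f1), sum(xor(m1, m2)))

  # pure Gaussian noise with a 6-sigma pixel threshold: almost never moving
  sd <- 0.01
  set.seed(42)
  moving <- vapply(1:1000, function(i) {
    fa <- matrix(rnorm(100 * 100, 0.5, sd), 100, 100)
    fb <- matrix(rnorm(100 * 100, 0.5, sd), 100, 100)
    detect_motion(fa, fb, pixel_delta_threshold = 6 * sd) > 10
  }, logical(1))
  expect_lt(mean(moving), 0.01)
})

test_that("full tracking recovers the trajectory and is deterministic", {
  p <- behavior_sim_params(duration_s = 10, noise_sd = 0, seed = 21)
  gt <- generate_trajectory(p)
  layout <- layout_from_params(p)
  vid <- rasterize_video(gt)
  tr <- track_video(vid, layout)
  expect_equal(nrow(tr), nrow(gt$trajectory))
  expect_true(all(tr$is_valid))
  rmse <- sqrt(mean((tr$x - gt$trajectory$x)^2 + (tr$y - gt$trajectory$y)^2))
  expect_lt(rmse, 1)
  expect_gte(mean(tr$is_moving == gt$trajectory$is_moving), 0.99)
  expect_identical(tr, track_video(vid, layout))
})

test_that("a permanently frozen fish produces no motion at all", {
  p <- behavior_sim_params(noise_sd = 0)
  gt <- fixed_pose_truth(70, 120, 10, n = 60, params = p)
  # a fish that never moves is absorbed into the median background model,
  # so detection fails (and warns) while motion stays correctly silent
  expect_warning(tr <- track_video(rasterize_video(gt), layout_from_params(p)),
                 "fewer than 50%")
  expect_false(any(tr$is_moving))
  expect_true(all(tr$motion_px == 0))
})

test_that("recovered centroids are translation-equivariant", {
  p <- behavior_sim_params(duration_s = 5, noise_sd = 0, seed = 31)
  gt <- generate_trajectory(p)
  gt2 <- gt
  gt2$trajectory$x <- gt$trajectory$x + 3
  gt2$trajectory$y <- gt$trajectory$y - 5
  layout <- layout_from_params(p)
  t1 <- track_video(rasterize_video(gt), layout)
  t2 <- track_video(rasterize_video(gt2), layout)
  expect_equal(t2$x, t1$x + 3)
  expect_equal(t2$y, t1$y - 5)
})

test_that("tracking respects the crop and reads from TIFF on disk", {
  p <- behavior_sim_params(duration_s = 3, noise_sd = 0, seed = 17,
                           arena_width_px = 120, arena_height_px = 100,
                           midline_x_px = 60)
  gt <- generate_trajectory(p)
  vid <- rasterize_video(gt)
  # embed the arena inside a larger dark frame, offset by (15, 10)
  big <- array(0, dim = c(140, 160, dim(vid)[3]))
  big[11:110, 16:135, ] <- vid
  layout <- arena_layout(c(15, 10, 120, 100), midline_x_px = 60, fps = 30)
  tf <- tempfile(fileext = ".tif")
  write_video_tiff(big, tf)
  tr <- track_video(tf, layout)
  ok <- tr$is_valid
  expect_gt(mean(ok), 0.99)
  rmse <- sqrt(mean((tr$x[ok] - gt$trajectory$x[ok])^2 +
                    (tr$y[ok] - gt$trajectory$y[ok])^2))
  expect_lt(rmse, 1)
  expect_error(track_video(vid, arena_layout(c(150, 0, 200, 200), 100)),
               "crop exceeds")
})

test_that("trajectory CSV round-trips", {
  p <- behavior_sim_params(duration_s = 2, seed = 3)
  tr <- as_trajectory(generate_trajectory(p))
  tf <- tempfile(fileext = ".csv")
  write_trajectory_csv(tr, tf)
  back <- read_trajectory_csv(tf)
  expect_equal(back$x, tr$x)
  expect_identical(back$is_moving, tr$is_moving)
})
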
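test_that("VPI follows the frame-count definition", {
  layout <- test_layout()
  # all frames on the SC (right) side
  expect_equal(compute_vpi(x_traj(rep(150, 100)), layout), 1)
  # 600 SC, 400 No-SC of 1000
  tr <- x_traj(c(rep(150, 600), rep(50, 400)))
  expect_equal(compute_vpi(tr, layout), 0.2)
  # 500 SC, 300 No-SC, 200 exactly on the midline: midline frames count to
  # neither side but stay in the denominator
  tr2 <- x_traj(c(rep(150, 500), rep(50, 300), rep(100, 200)))
  expect_equal(compute_vpi(tr2, layout), 0.2)
  # sc_side = left flips the sign
  expect_equal(compute_vpi(tr, test_layout(sc = "left")), -0.2)
  # no valid frames
  bad <- x_traj(rep(150, 10)); bad$is_valid <- FALSE
  expect_error(compute_vpi(bad, layout), "no valid")
})

test_that("VPI is antisymmetric under midline mirroring and conserves frames", {
  layout <- test_layout()
  set.seed(7)
  for (i in 1:20) {
    x <- runif(500, 0, 199)
    x[sample(500, 20)] <- 100  # some exactly on the midline
    tr <- x_traj(x)
    mir <- tr; mir$x <- 2 * layout$midline_x_px - tr$x
    expect_identical(compute_vpi(mir, layout), -compute_vpi(tr, layout))
    sc <- sum(x > 100); nosc <- sum(x < 100); mid <- sum(x == 100)
    expect_equal(sc + nosc + mid, sum(tr$is_valid))
  }
})

test_that("sociality classes split at +/-0.5 with boundaries non-social", {
  expect_equal(classify_sociality(0.6), "+S")
  expect_equal(classify_sociality(-0.51), "-S")
  expect_equal(classify_sociality(0.5), "ns")
  expect_equal(classify_sociality(-0.5), "ns")
  expect_equal(classify_sociality(0), "ns")
  expect_error(classify_sociality(1.2), "\\[-1, 1\\]")
  expect_error(classify_sociality(NA), "\\[-1, 1\\]")
})

test_that("percent moving is the moving fraction of valid frames", {
  expect_equal(percent_moving(motion_traj(rep(TRUE, 50))), 100)
  expect_equal(percent_moving(motion_traj(rep(FALSE, 50))), 0)
  tr <- motion_traj(rep(c(TRUE, FALSE, FALSE, FALSE), 250))
  expect_equal(percent_moving(tr), 25)
  # invalid frames leave the denominator
  tr$is_valid[1:100] <- FALSE
  expect_equal(percent_moving(tr),
               100 * sum(tr$is_moving[-(1:100)]) / 900)
})

test_that("freeze bouts obey the strict 3 s rule", {
  fps <- 30
  # one 120-frame (4 s) still run inside a 3000-frame session
  mv <- rep(TRUE, 3000); mv[1001:1120] <- FALSE
  fr <- detect_freezes(motion_traj(mv, fps), 3, fps)
  expect_equal(nrow(fr$bouts), 1)
  expect_equal(fr$bouts$start_frame, 1000)
  expect_equal(fr$bouts$end_frame, 1119)
  expect_equal(fr$bouts$duration_s, 4)
  expect_equal(fr$percent_freezing, 100 * 120 / 3000)

  # exactly 90 frames = 3.0 s is not a bout; 91 frames is
  mv90 <- rep(TRUE, 1000); mv90[101:190] <- FALSE
  expect_equal(nrow(detect_freezes(motion_traj(mv90, fps), 3, fps)$bouts), 0)
  mv91 <- rep(TRUE, 1000); mv91[101:191] <- FALSE
  expect_equal(nrow(detect_freezes(motion_traj(mv91, fps), 3, fps)$bouts), 1)

  # all moving: nothing
  none <- detect_freezes(motion_traj(rep(TRUE, 500), fps), 3, fps)
  expect_equal(nrow(none$bouts), 0)
  expect_equal(none$percent_freezing, 0)
  expect_error(detect_freezes(motion_traj(rep(TRUE, 10)), 3, fps = 0),
               "fps")
})

test_that("freeze detection matches the frame-scan oracle on random motion", {
  fps <- 30
  set.seed(11)
  for (i in 1:50) {
    mv <- runif(600) < runif(1, 0.02, 0.5)
    got <- detect_freezes(motion_traj(mv, fps), 3, fps)
    want <- freeze_oracle(mv, fps, 3)
    expect_equal(got$bouts$start_frame, want$start_frame)
    expect_equal(got$bouts$end_frame, want$end_frame)
  }
})

test_that("raising the minimum freeze duration never increases freezing", {
  fps <- 30
  set.seed(13)
  mv <- runif(3000) < 0.02
  pf <- vapply(c(1, 2, 3, 5, 8),
               function(s) detect_freezes(motion_traj(mv, fps), s, fps)$percent_freezing,
               numeric(1))
  expect_true(all(diff(pf) <= 0))
})

test_that("binned time courses follow the session-level rules per bin", {
  layout <- test_layout()
  fps <- 30
  # 15-minute session in 60 s bins: 15 bins
  n <- 15 * 60 * fps
  tr <- x_traj(rep(150, n), fps)
  b <- binned_series(tr, layout, 60)
  expect_equal(nrow(b), 15)
  expect_true(all(b$vpi == 1))
  expect_true(all(b$n_frames == 60 * fps))

  # side switch exactly at 7.5 min: bins 1-7 at +1, bin 8 at 0, 9-15 at -1
  x <- c(rep(150, n / 2), rep(50, n / 2))
  b2 <- binned_series(x_traj(x, fps), layout, 60)
  expect_equal(b2$vpi[1:7], rep(1, 7))
  expect_equal(b2$vpi[8], 0)
  expect_equal(b2$vpi[9:15], rep(-1, 7))

  # trailing partial bin keeps its frame count
  b3 <- binned_series(x_traj(rep(150, 90 * fps), fps), layout, 60)
  expect_equal(nrow(b3), 2)
  expect_equal(b3$n_frames[2], 30 * fps)

  expect_error(binned_series(tr, layout, 0), "bin_s")
})

test_that("session metrics bundle all statistics consistently", {
  p <- behavior_sim_params(duration_s = 120, side_bias = 0.8,
                           freeze_rate_hz = 0.03, freeze_duration_s = 6,
                           seed = 19)
  gt <- generate_trajectory(p)
  sm <- session_metrics(as_trajectory(gt), layout_from_params(p))
  expect_s3_class(sm, "session_metrics")
  expect_equal(sm$vpi,
               compute_vpi(as_trajectory(gt), layout_from_params(p)))
  expect_equal(sm$sociality, classify_sociality(sm$vpi))
  expect_true(sm$percent_freezing >= 0 && sm$percent_freezing <= 100)
  expect_equal(sm$n_valid_frames, nrow(gt$trajectory))
  expect_equal(nrow(sm$binned), 2)
})
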
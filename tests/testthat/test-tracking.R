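test_that("detect_centroid computes the intensity-weighted mean", {
  fr <- matrix(0, 30, 30)
  fr[20, 10] <- 100
  expect_equal(detect_centroid(fr), c(cx = 10, cy = 20))

  # hand-evaluated two-pixel case: (0*100 + 10*200)/300 columns apart
  fr2 <- matrix(0, 5, 15)
  fr2[3, 2] <- 100
  fr2[3, 12] <- 200
  cen <- detect_centroid(fr2)
  expect_equal(unname(cen["cx"]), 2 + 10 * 200 / 300)
  expect_equal(unname(cen["cy"]), 3)

  # uniform weighting ignores intensity differences
  cen_u <- detect_centroid(fr2, weighted = FALSE)
  expect_equal(unname(cen_u["cx"]), 7)
})

test_that("frames with nothing above the threshold are missing", {
  fr <- matrix(60, 10, 10)  # strictly-greater rule: 60 itself is not enough
  expect_null(detect_centroid(fr))
  fr[5, 5] <- 60.5
  expect_equal(detect_centroid(fr), c(cx = 5, cy = 5))
  expect_error(detect_centroid(numeric(0)), "matrix")
})

test_that("raising the threshold never creates a detection", {
  set.seed(31)
  for (i in 1:20) {
    fr <- matrix(runif(100, 0, 120), 10, 10)
    detected <- !vapply(sort(runif(8, 0, 200)), function(th) {
      is.null(detect_centroid(fr, threshold = th))
    }, logical(1))
    # once lost under an increasing threshold, never regained
    expect_true(all(diff(detected) <= 0))
  }
})

test_that("tracking a constant blob gives zero displacement", {
  wp <- walker_params(duration = 1, seed = 1)
  tr <- simulate_walker(wp)
  tr$positions$x[] <- 2
  tr$positions$y[] <- -3
  rp <- render_params(background_sd = 0)
  fr <- render_frames(tr, rp, seed = 1)
  traj <- track_frames(fr, calibration_from_render(rp), frame_rate = 10)
  expect_true(all(traj$detected))
  expect_lt(max(abs(diff(traj$x))) + max(abs(diff(traj$y))), 1e-9)
})

test_that("tracker recovers noiseless rendered walkers to sub-pixel accuracy", {
  rp <- render_params(background_sd = 0)
  cal <- calibration_from_render(rp)
  for (s in 1:3) {
    wp <- walker_params(duration = 3, seed = s)
    tr <- simulate_walker(wp)
    traj <- track_frames(render_frames(tr, rp, seed = s), cal,
                         frame_rate = wp$frame_rate)
    err_px <- sqrt((traj$x - tr$positions$x)^2 +
                   (traj$y - tr$positions$y)^2) / rp$mm_per_pixel
    expect_lt(max(err_px), 0.15)
    expect_lt(sqrt(mean(err_px^2)), 0.1)
  }
})

test_that("blank frames are flagged missing, not interpolated", {
  wp <- walker_params(duration = 2, seed = 4)
  tr <- simulate_walker(wp)
  rp <- render_params(background_mean = 20, background_sd = 0)
  fr <- render_frames(tr, rp, seed = 1)
  blank <- c(3, 7, 11)
  for (i in blank) fr[[i]] <- matrix(20, rp$image_size, rp$image_size)
  traj <- track_frames(fr, calibration_from_render(rp), frame_rate = 10)
  expect_identical(which(!traj$detected), as.integer(blank))
  expect_true(all(is.na(traj$x[blank])))
  expect_equal(attr(traj, "fraction_detected"), 1 - 3 / 20)
})

test_that("arena calibration recovers the pixel scale from a disk", {
  cal <- calibrate_from_arena(arena_disk_frame(size = 500, radius = 200))
  expect_equal(cal$mm_per_pixel, 20 / 400, tolerance = 0.005)
  expect_equal(cal$arena_center, c(250.5, 250.5), tolerance = 0.01)

  # manual override skips fitting entirely
  man <- calibration(0.05, c(10, 10), 100)
  expect_identical(calibrate_from_arena(matrix(0, 5, 5), override = man), man)

  expect_error(calibrate_from_arena(matrix(0, 50, 50)), "no arena")
  expect_error(calibrate_from_arena(arena_disk_frame(40, 5)),
               "resolution too low")
})

test_that("mm to pixel calibration round-trips", {
  cal <- calibration(mm_per_pixel = 0.05, arena_center = c(250, 250),
                     arena_radius_px = 200)
  x_mm <- c(-9.5, 0, 3.25)
  px <- cal$arena_center[1] + x_mm / cal$mm_per_pixel
  back <- (px - cal$arena_center[1]) * cal$mm_per_pixel
  expect_equal(back, x_mm)
})

test_that("track_frames validates its inputs", {
  expect_error(track_frames(list(), calibration(0.05, c(5, 5), 3)),
               "no frames")
  # calibration circle poking outside the image is rejected
  expect_error(
    track_frames(list(matrix(0, 20, 20)), calibration(0.05, c(10, 10), 15)),
    "outside the image")
})

test_that("trajectories round-trip through CSV with JSON header", {
  wp <- walker_params(duration = 2, seed = 6)
  traj <- trajectory_from_truth(simulate_walker(wp))
  csv <- tempfile(fileext = ".csv")
  write_trajectory(traj, csv)
  back <- read_trajectory(csv)
  expect_equal(back$x, traj$x)
  expect_equal(attr(back, "frame_rate"), 10)
  expect_equal(attr(back, "arena_radius"), 10)
})
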
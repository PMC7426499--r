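test_that("a steady 0.2 mm/frame walk at 10 fps quantizes to 2 mm/s runs", {
  # 10 steps of 0.2 mm fall inside each closed 1-s quantum window
  traj <- traj_from_quantum_speeds(rep(2, 5), frame_rate = 10)
  qt <- quantize(traj)
  expect_equal(nrow(qt), 5)
  expect_equal(qt$mean_speed, rep(2, 5))
  expect_true(all(qt$state == "run"))
})

test_that("a stationary fly rests at speed zero", {
  traj <- traj_from_quantum_speeds(rep(0, 4), frame_rate = 10)
  qt <- quantize(traj)
  expect_equal(qt$mean_speed, rep(0, 4))
  expect_true(all(qt$state == "rest"))
})

test_that("the 1 mm/s boundary itself classifies as run", {
  qt <- qt_from_states(c("S", "R"), run_speeds = 1.00, rest_speeds = 0.99)
  expect_identical(qt$state, c("rest", "run"))
})

test_that("quanta with fewer than two detected samples are invalid", {
  traj <- traj_from_quantum_speeds(c(2, 3, 4), frame_rate = 2)
  traj$detected[3:5] <- FALSE  # quantum 2 loses all but its boundary sample
  qt <- quantize(traj)
  expect_identical(qt$valid, c(TRUE, FALSE, TRUE))
  expect_true(is.na(qt$mean_speed[2]))
  prof <- compute_profile(qt)
  expect_equal(prof$n_quanta, 2)
})

test_that("quantize rejects too-short trajectories", {
  traj <- traj_from_quantum_speeds(2, frame_rate = 10)
  short <- traj[1:5, ]
  attr(short, "frame_rate") <- 10
  attr(short, "arena_radius") <- 10
  class(short) <- class(traj)
  expect_error(quantize(short), "shorter than one quantum")
})

test_that("bout segmentation enumerates maximal run blocks", {
  qt <- qt_from_states(c("R", "R", "S", "S", "R", "S", "S", "S", "R", "R"),
                       run_speeds = c(2, 4, 3, 2, 4),
                       rest_speeds = c(0.5, 0.5, 0.2, 0.4, 0.4))
  b <- segment_bouts(qt)
  expect_equal(nrow(b), 3)
  expect_equal(b$length_quanta, c(2, 1, 2))
  expect_equal(b$start_quantum, c(1, 5, 9))
  expect_equal(b$duration, c(2, 1, 2))

  all_rest <- qt_from_states(rep("S", 6), numeric(0), rep(0.3, 6))
  expect_equal(nrow(segment_bouts(all_rest)), 0)

  all_run <- qt_from_states(rep("R", 10), rep(2, 10), numeric(0))
  b2 <- segment_bouts(all_run)
  expect_equal(nrow(b2), 1)
  expect_equal(b2$duration, 10)
})

test_that("the five SLA parameters match the hand-worked example", {
  qt <- qt_from_states(c("R", "R", "S", "S", "R", "S", "S", "S", "R", "R"),
                       run_speeds = c(2, 4, 3, 2, 4),
                       rest_speeds = c(0.5, 0.5, 0.2, 0.4, 0.4))
  prof <- compute_profile(qt, fly_id = "worked")
  expect_equal(prof$index_of_activity, 0.5)
  expect_equal(prof$run_frequency, 30)
  expect_equal(prof$running_speed, 3.0)
  expect_equal(prof$total_speed, 1.7)
  expect_equal(prof$run_bout_time, 5 / 3)
  expect_equal(prof$run_frequency * prof$run_bout_time,
               100 * prof$index_of_activity)
  # percent toggle
  expect_equal(compute_profile(qt, activity_as_percent = TRUE)$index_of_activity,
               50)
})

test_that("an all-rest record has zero activity and absent run metrics", {
  qt <- qt_from_states(rep("S", 8), numeric(0), rep(0.4, 8))
  prof <- compute_profile(qt)
  expect_equal(prof$index_of_activity, 0)
  expect_equal(prof$run_frequency, 0)
  expect_equal(prof$total_speed, 0.4)
  expect_true(is.na(prof$running_speed))
  expect_true(is.na(prof$run_bout_time))
})

test_that("run_frequency x run_bout_time = 100 x index_of_activity always", {
  for (s in 1:30) {
    wp <- walker_params(
      rate_rest_to_run = runif(1, 0.05, 0.5),
      rate_run_to_rest = runif(1, 0.05, 0.5),
      run_speed_mean = runif(1, 1.5, 6),
      duration = 60, seed = s)
    prof <- sla_profile(trajectory_from_truth(simulate_walker(wp)))
    if (!is.na(prof$run_bout_time)) {
      expect_equal(prof$run_frequency * prof$run_bout_time,
                   100 * prof$index_of_activity, tolerance = 1e-12)
      expect_lte(prof$total_speed, prof$running_speed + 1e-12)
    }
  }
})

test_that("wall-following walkers score higher centrophobia than reflective ones", {
  centro <- function(bias, s) {
    wp <- walker_params(wall_bias = bias, turning_concentration = 30,
                        duration = 300, seed = s)
    sla_profile(trajectory_from_truth(simulate_walker(wp)))$centrophobia_index
  }
  hug <- mean(vapply(1:5, function(s) centro(1, s), numeric(1)))
  refl <- mean(vapply(1:5, function(s) centro(0, s), numeric(1)))
  expect_gt(hug, refl)
})

test_that("plot_track returns a ggplot of the arena path", {
  wp <- walker_params(duration = 10, seed = 3)
  p <- plot_track(trajectory_from_truth(simulate_walker(wp)))
  expect_s3_class(p, "ggplot")
})
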
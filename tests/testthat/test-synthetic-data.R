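test_that("identical seeds reproduce identical walker output", {
  wp <- walker_params(duration = 30, seed = 42)
  a <- simulate_walker(wp)
  b <- simulate_walker(wp)
  expect_identical(a$positions, b$positions)
  expect_identical(a$states, b$states)
  c2 <- simulate_walker(walker_params(duration = 30, seed = 43))
  expect_false(identical(a$positions, c2$positions))
})

test_that("walker parameter validation rejects bad values", {
  expect_error(walker_params(rate_rest_to_run = -1), "rate_rest_to_run")
  expect_error(walker_params(run_speed_mean = 0.5), "run_speed_mean")
  expect_error(walker_params(rest_speed_mean = 1.2), "rest_speed_mean")
  expect_error(walker_params(wall_bias = 1.5), "wall_bias")
  expect_error(walker_params(arena_radius = 0), "arena_radius")
  expect_error(walker_params(frame_rate = Inf), "frame_rate")
})

test_that("zero rest-to-run rate is an absorbing rest state", {
  wp <- walker_params(rate_rest_to_run = 0, duration = 60, seed = 7)
  tr <- simulate_walker(wp)
  expect_true(all(tr$states == "rest"))
  # net displacement over any 1-s window stays below the run threshold
  spq <- wp$frame_rate
  n <- nrow(tr$positions)
  i0 <- seq(1, n - spq, by = spq)
  net <- sqrt((tr$positions$x[i0 + spq] - tr$positions$x[i0])^2 +
              (tr$positions$y[i0 + spq] - tr$positions$y[i0])^2)
  expect_true(all(net < 1))
})

test_that("equal switching rates give a half-run stationary fraction", {
  wp <- walker_params(rate_rest_to_run = 0.1, rate_run_to_rest = 0.1,
                      duration = 10000, seed = 11)
  tr <- simulate_walker(wp)
  expect_lt(abs(mean(tr$states == "run") - 0.5), 0.02)
})

test_that("empirical run fraction matches the chain's stationary law", {
  # over 20 seeds with uneven rates, mean fraction within 3 SE of
  # p1/(p1+p2), the stationary run probability of the sampled chain
  k1 <- 0.25
  k2 <- 0.08
  p1 <- 1 - exp(-k1)
  p2 <- 1 - exp(-k2)
  frac <- vapply(1:20, function(s) {
    tr <- simulate_walker(walker_params(
      rate_rest_to_run = k1, rate_run_to_rest = k2,
      duration = 2000, seed = s))
    mean(tr$states == "run")
  }, numeric(1))
  se <- sd(frac) / sqrt(length(frac))
  expect_lt(abs(mean(frac) - p1 / (p1 + p2)), 3 * se)
})

test_that("no generated position leaves the arena disk", {
  for (s in 1:5) {
    wp <- walker_params(duration = 60, wall_bias = runif(1),
                        run_speed_mean = runif(1, 1, 8),
                        arena_radius = runif(1, 5, 15), seed = s)
    tr <- simulate_walker(wp)
    expect_lte(max(sqrt(tr$positions$x^2 + tr$positions$y^2)),
               wp$arena_radius + 1e-9)
  }
})

test_that("rendered frames put the blob at the fly position", {
  wp <- walker_params(duration = 1, seed = 1)
  tr <- simulate_walker(wp)
  tr$positions$x[] <- 0
  tr$positions$y[] <- 0
  rp <- render_params(image_size = 121L, background_sd = 0)
  fr <- render_frames(tr, rp, seed = 1)
  ctr <- (rp$image_size + 1) / 2  # odd size: centre falls on a pixel
  am <- which(fr[[1]] == max(fr[[1]]), arr.ind = TRUE)
  expect_equal(unname(am[1, ]), c(ctr, ctr))
  # identical seed, identical frames
  expect_identical(fr, render_frames(tr, rp, seed = 1))
})

test_that("frames without a fly yield missing detections", {
  wp <- walker_params(duration = 1, seed = 2)
  tr <- simulate_walker(wp)
  rp <- render_params(background_mean = 20, background_sd = 5)
  fr <- render_frames(tr, rp, seed = 3, draw_fly = FALSE)
  expect_true(all(vapply(fr, function(f) is.null(detect_centroid(f)),
                         logical(1))))
})

test_that("positions mapping outside the image are rejected", {
  wp <- walker_params(duration = 1, seed = 1)
  tr <- simulate_walker(wp)
  rp <- render_params(image_size = 30L, mm_per_pixel = 0.2)
  tr$positions$x[1] <- 9.9  # 9.9 mm -> ~50 px from centre, off a 30-px frame
  expect_error(render_frames(tr, rp), "outside the image")
})

test_that("dot-blot phantom renders darkness proportional to concentration", {
  ph <- dilution_phantom(c(1, 2, 4, 8))
  ms <- measure_dotblot_series(ph)
  expect_equal(ms$ods / ms$ods[1], c(1, 2, 4, 8))
  # zero concentration is indistinguishable from background
  ph0 <- dilution_phantom(c(0, 1, 2))
  expect_equal(measure_dotblot_series(ph0)$ods[1], 0)
  # identical seed, identical membrane
  expect_identical(synth_dotblot(ph), synth_dotblot(ph))
})

test_that("overlapping dot-blot spots are rejected", {
  expect_error(
    dotblot_phantom(spot_centers = rbind(c(20, 20), c(25, 20)),
                    concentrations = c(1, 2), spot_radius = 6),
    "overlap")
})

test_that("brain phantom dims the pedunculus disk in selected slices", {
  fx <- clean_ped_fixture(ped_contrast = 0.5, noise_sd = 0)
  st <- synth_brain_stack(fx$bp)
  expect_identical(st, synth_brain_stack(fx$bp))
  # dimmed slices are exactly the configured ones
  expect_identical(select_dimmed_slices(st, fx$spec), 4:6)
  # no dimming -> statistically uniform stack
  fx1 <- clean_ped_fixture(ped_contrast = 1, noise_sd = 0)
  st1 <- synth_brain_stack(fx1$bp)
  expect_equal(max(st1) - min(st1), 0)
})

test_that("brain phantom validation enforces geometry and contrast", {
  expect_error(brain_phantom_params(ped_contrast = 0), "ped_contrast")
  expect_error(brain_phantom_params(ped_contrast = 1.5), "ped_contrast")
  expect_error(brain_phantom_params(ped_center = c(2, 2)), "inside")
  expect_error(brain_phantom_params(dimmed_slices = 99), "dimmed_slices")
})

test_that("ground truth round-trips through CSV + JSON sidecar", {
  wp <- walker_params(duration = 5, seed = 9)
  tr <- simulate_walker(wp)
  csv <- tempfile(fileext = ".csv")
  write_ground_truth(tr, csv)
  df <- read.csv(csv)
  expect_equal(df$x_mm, tr$positions$x)
  expect_equal(df$state, tr$states)
  js <- jsonlite::read_json(sub("\\.csv$", ".json", csv),
                            simplifyVector = TRUE)
  expect_equal(js$seed, 9)
  expect_equal(js$arena_radius, wp$arena_radius)
})
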
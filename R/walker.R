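#' Parameters of the synthetic rest/run walker
#'
#' The generative model behind all trajectory-level validation: a two-state
#' (rest/run) Markov walker confined to a circular arena. Behavioural state
#' switches on the 1-s quantum grid (per-second switch probabilities
#' `1 - exp(-rate)`), each run bout draws one speed from a normal law
#' (truncated below at 1 mm/s so runs classify as runs), headings persist
#' through a wrapped-normal turning kernel, rest is isotropic sub-threshold
#' jitter, and wall contact combines specular reflection with a tangential
#' alignment of strength `wall_bias` (0 = pure reflection, 1 = full
#' wall-following), which reproduces the centrophobia real flies show.
#'
#' @param rate_rest_to_run,rate_run_to_rest Transition rates (1/s) of the
#'   rest/run chain. The stationary run fraction of the sampled chain is
#'   `p1/(p1 + p2)` with `p_i = 1 - exp(-rate_i)`; for equal rates this is
#'   exactly `rate_rest_to_run / (rate_rest_to_run + rate_run_to_rest)`.
#' @param run_speed_mean,run_speed_sd Mean and SD (mm/s) of the per-bout
#'   run-speed law. `run_speed_mean` must be >= 1 so run bouts exceed the
#'   1 mm/s rest threshold.
#' @param rest_speed_mean Mean jitter speed (mm/s) while resting; must be
#'   in [0, 1) so rest stays below the rest threshold.
#' @param turning_concentration Heading persistence during runs; heading
#'   increments are wrapped-normal with SD `1/sqrt(turning_concentration)`.
#' @param wall_bias Weight in [0, 1] pulling the post-contact heading
#'   toward the wall tangent.
#' @param arena_radius Arena radius in mm (default 10, i.e. the 20-mm
#'   diameter chamber).
#' @param frame_rate Sampling rate, frames/s.
#' @param duration Record duration in seconds.
#' @param seed Integer seed; identical seeds give identical output.
#' @return An object of class `walker_params`.
#' @export
#' @examples
#' wp <- walker_params(duration = 60, seed = 1)
#' tr <- simulate_walker(wp)
#' max(sqrt(tr$positions$x^2 + tr$positions$y^2)) <= wp$arena_radius
walker_params <- function(rate_rest_to_run = 0.1, rate_run_to_rest = 0.1,
                          run_speed_mean = 3, run_speed_sd = 0.5,
                          rest_speed_mean = 0.1,
                          turning_concentration = 10, wall_bias = 0.7,
                          arena_radius = 10, frame_rate = 10,
                          duration = 3600, seed = 1L) {
  stop_if_not_scalar_finite(rate_rest_to_run, "rate_rest_to_run", nonneg = TRUE)
  stop_if_not_scalar_finite(rate_run_to_rest, "rate_run_to_rest", nonneg = TRUE)
  stop_if_not_scalar_finite(run_speed_mean, "run_speed_mean")
  if (run_speed_mean < 1) {
    stop("`run_speed_mean` must be >= 1 mm/s so runs classify as runs",
         call. = FALSE)
  }
  stop_if_not_scalar_finite(run_speed_sd, "run_speed_sd", nonneg = TRUE)
  stop_if_not_scalar_finite(rest_speed_mean, "rest_speed_mean", nonneg = TRUE)
  if (rest_speed_mean >= 1) {
    stop("`rest_speed_mean` must be < 1 mm/s", call. = FALSE)
  }
  stop_if_not_scalar_finite(turning_concentration, "turning_concentration",
                            positive = TRUE)
  stop_if_not_scalar_finite(wall_bias, "wall_bias", nonneg = TRUE)
  if (wall_bias > 1) stop("`wall_bias` must be in [0, 1]", call. = FALSE)
  stop_if_not_scalar_finite(arena_radius, "arena_radius", positive = TRUE)
  stop_if_not_scalar_finite(frame_rate, "frame_rate", positive = TRUE)
  stop_if_not_scalar_finite(duration, "duration", positive = TRUE)
  stop_if_not_scalar_finite(seed, "seed")
  structure(
    list(rate_rest_to_run = rate_rest_to_run,
         rate_run_to_rest = rate_run_to_rest,
         run_speed_mean = run_speed_mean, run_speed_sd = run_speed_sd,
         rest_speed_mean = rest_speed_mean,
         turning_concentration = turning_concentration,
         wall_bias = wall_bias, arena_radius = arena_radius,
         frame_rate = frame_rate, duration = duration,
         seed = as.integer(seed)),
    class = "walker_params")
}

#' @export
print.walker_params <- function(x, ...) {
  cat("Rest/run walker parameters\n")
  cat(sprintf("  rates rest->run %.3g/s, run->rest %.3g/s\n",
              x$rate_rest_to_run, x$rate_run_to_rest))
  cat(sprintf("  run speed %.2f +/- %.2f mm/s; rest jitter %.2f mm/s\n",
              x$run_speed_mean, x$run_speed_sd, x$rest_speed_mean))
  cat(sprintf("  arena radius %g mm; %g fps x %g s; wall bias %.2f; seed %d\n",
              x$arena_radius, x$frame_rate, x$duration, x$wall_bias, x$seed))
  invisible(x)
}

# Per-second rest/run state sequence of the discrete-sampled chain.
sample_state_seconds <- function(n_sec, p_rest_to_run, p_run_to_rest,
                                 init = "rest") {
  states <- character(n_sec)
  u <- runif(n_sec)
  s <- init
  for (k in seq_len(n_sec)) {
    states[k] <- s
    flip <- if (s == "rest") u[k] < p_rest_to_run else u[k] < p_run_to_rest
    if (flip) s <- if (s == "rest") "run" else "rest"
  }
  states
}

# Blend two angles on the circle with weight w on `b`.
circ_blend <- function(a, b, w) {
  atan2((1 - w) * sin(a) + w * sin(b), (1 - w) * cos(a) + w * cos(b))
}

#' Simulate a rest/run walker in a circular arena
#'
#' Generates a ground-truthed trajectory: per-frame positions (mm,
#' arena-centred), the per-frame behavioural state, and the generating
#' parameters. Step length during a run frame is exactly
#' `bout_speed / frame_rate`; wall contact rotates the heading
#' (reflection blended toward the tangent by `wall_bias`) and the full
#' step is retaken with the new heading, so the path length — and hence
#' the recoverable running speed — is preserved at the wall.
#'
#' @param params A [walker_params()] object.
#' @return An object of class `ground_truth`: a list with `positions`
#'   (data.frame `t`, `x`, `y`), `states` (character, per frame) and
#'   `params`.
#' @export
simulate_walker <- function(params) {
  if (!inherits(params, "walker_params")) {
    stop("`params` must be a `walker_params` object", call. = FALSE)
  }
  p <- params
  dt <- 1 / p$frame_rate
  n_frames <- as.integer(round(p$duration * p$frame_rate))
  spq <- max(1L, as.integer(round(p$frame_rate)))  # frames per second
  n_sec <- as.integer(ceiling(n_frames / spq))
  R <- p$arena_radius
  R2 <- R * R

  with_seed(p$seed, {
    sec_states <- sample_state_seconds(
      n_sec,
      p_rest_to_run = 1 - exp(-p$rate_rest_to_run),
      p_run_to_rest = 1 - exp(-p$rate_run_to_rest))
    state_f <- rep(sec_states, each = spq)[seq_len(n_frames)]
    is_run <- state_f == "run"

    # one speed per run bout, shared by all frames of the bout
    rl <- rle(sec_states)
    n_bouts <- sum(rl$values == "run")
    bout_speed_sec <- rep(NA_real_, n_sec)
    if (n_bouts > 0) {
      speeds <- pmax(rnorm(n_bouts, p$run_speed_mean, p$run_speed_sd), 1)
      bout_id <- cumsum(rl$values == "run")  # per rle block
      bout_speed_sec <- rep(ifelse(rl$values == "run",
                                   speeds[pmax(bout_id, 1L)], NA_real_),
                            rl$lengths)
    }
    speed_f <- rep(bout_speed_sec, each = spq)[seq_len(n_frames)]

    # per-frame step lengths and heading inputs
    step_len <- numeric(n_frames)
    step_len[is_run] <- speed_f[is_run] * dt
    n_rest <- sum(!is_run)
    if (n_rest > 0 && p$rest_speed_mean > 0) {
      step_len[!is_run] <- rexp(n_rest, rate = 1 / (p$rest_speed_mean * dt))
    }
    dh <- rnorm(n_frames, 0, 1 / sqrt(p$turning_concentration))
    rest_dir <- runif(n_frames, 0, 2 * pi)

    # start uniformly over the arena disk
    r0 <- R * sqrt(runif(1))
    a0 <- runif(1, 0, 2 * pi)
    x <- r0 * cos(a0)
    y <- r0 * sin(a0)
    h <- runif(1, 0, 2 * pi)

    # sample i is the position at t = (i-1)*dt; step i (state of the
    # second containing that interval) connects samples i and i+1, so
    # every 1-s quantum holds exactly frame_rate steps of its own state
    xs <- numeric(n_frames)
    ys <- numeric(n_frames)
    w <- p$wall_bias
    for (i in seq_len(n_frames)) {
      xs[i] <- x
      ys[i] <- y
      if (i == n_frames) break
      L <- step_len[i]
      if (is_run[i]) h <- h + dh[i] else h <- rest_dir[i]
      ex <- x + L * cos(h)
      ey <- y + L * sin(h)
      if (ex * ex + ey * ey > R2) {
        for (try in 1:8) {
          phi <- atan2(y, x)
          tg <- phi + pi / 2
          if (cos(h - tg) < 0) tg <- phi - pi / 2
          h <- circ_blend(2 * tg - h, tg, w)
          ex <- x + L * cos(h)
          ey <- y + L * sin(h)
          if (ex * ex + ey * ey <= R2) break
        }
        if (ex * ex + ey * ey > R2) {
          # rare fallback: step straight toward the arena centre
          h <- atan2(-y, -x)
          ex <- x + L * cos(h)
          ey <- y + L * sin(h)
          sc <- sqrt(ex * ex + ey * ey)
          if (sc > R) {  # numerically clamp onto the boundary
            ex <- ex * R / sc
            ey <- ey * R / sc
          }
        }
      }
      x <- ex
      y <- ey
    }

    structure(
      list(positions = data.frame(t = (seq_len(n_frames) - 1) * dt,
                                  x = xs, y = ys),
           states = state_f,
           params = p),
      class = "ground_truth")
  })
}

#' @export
print.ground_truth <- function(x, ...) {
  n <- nrow(x$positions)
  cat(sprintf(
    "Walker ground truth: %d frames (%.1f s at %g fps), %.1f%% run\n",
    n, x$params$duration, x$params$frame_rate,
    100 * mean(x$states == "run")))
  invisible(x)
}

#' Write walker ground truth to CSV plus a JSON parameter sidecar
#'
#' @param truth A `ground_truth` object.
#' @param csv_path Output CSV (`t`, `x_mm`, `y_mm`, `state`).
#' @param json_path Output JSON of the generating [walker_params()];
#'   defaults to the CSV path with a `.json` extension.
#' @return Invisibly, the CSV path.
#' @export
write_ground_truth <- function(truth, csv_path,
                               json_path = sub("\\.csv$", ".json", csv_path)) {
  stopifnot(inherits(truth, "ground_truth"))
  df <- data.frame(t = truth$positions$t,
                   x_mm = truth$positions$x,
                   y_mm = truth$positions$y,
                   state = truth$states)
  write.csv(df, csv_path, row.names = FALSE)
  jsonlite::write_json(unclass(truth$params), json_path,
                       auto_unbox = TRUE, digits = NA)
  invisible(csv_path)
}

#' Convert walker ground truth to a trajectory object
#'
#' Bypasses rendering and tracking: yields the trajectory the tracker
#' would recover from a perfect recording, with every sample flagged
#' detected. Used by simulation-mode cohort runs and recovery tests.
#'
#' @param truth A `ground_truth` object.
#' @return A [fly_trajectory] data.frame (`t`, `x`, `y`, `detected`).
#' @export
trajectory_from_truth <- function(truth) {
  stopifnot(inherits(truth, "ground_truth"))
  new_trajectory(
    t = truth$positions$t, x = truth$positions$x, y = truth$positions$y,
    detected = rep(TRUE, nrow(truth$positions)),
    frame_rate = truth$params$frame_rate,
    arena_radius = truth$params$arena_radius)
}
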
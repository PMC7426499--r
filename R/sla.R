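#' Analysis configuration for SLA quantification
#'
#' @param quantum Quantum length in seconds (default 1: the record is cut
#'   into 1-s quanta).
#' @param rest_threshold Rest/run boundary in mm/s: quanta with mean
#'   speed lower than this are rest, all others (including exactly the
#'   threshold) are run. Default 1 mm/s.
#' @param centro_annulus_fraction Fraction of the arena radius beyond
#'   which a sample counts as "at the wall" for the centrophobia index
#'   (default 0.7; under uniform-over-area exploration the expected index
#'   is `1 - 0.7^2 = 0.51`).
#' @param record_duration Nominal record duration in s (informational;
#'   default 3600, a 1-h recording).
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(quantum = 1, rest_threshold = 1,
                            centro_annulus_fraction = 0.7,
                            record_duration = 3600) {
  stop_if_not_scalar_finite(quantum, "quantum", positive = TRUE)
  stop_if_not_scalar_finite(rest_threshold, "rest_threshold", positive = TRUE)
  stop_if_not_scalar_finite(centro_annulus_fraction,
                            "centro_annulus_fraction", positive = TRUE)
  if (centro_annulus_fraction >= 1) {
    stop("`centro_annulus_fraction` must be in (0, 1)", call. = FALSE)
  }
  structure(list(quantum = quantum, rest_threshold = rest_threshold,
                 centro_annulus_fraction = centro_annulus_fraction,
                 record_duration = record_duration),
            class = "analysis_config")
}

#' Quantize a trajectory into per-second speed quanta
#'
#' Cuts the record into consecutive quanta of `cfg$quantum` seconds.
#' Quantum k covers the closed time interval `[(k-1)q, kq]`, i.e. it
#' shares its boundary sample with the next quantum, so a full quantum at
#' `f` frames/s contains `f` inter-sample steps and the mean speed of a
#' steady walker equals its true speed. Mean speed is the summed
#' displacement between consecutive *detected* samples inside the quantum
#' window divided by the quantum duration (path length, not net
#' displacement). Quanta with fewer than two detected samples are flagged
#' invalid and excluded from every downstream parameter.
#'
#' @param traj A `fly_trajectory` (from [track_frames()],
#'   [trajectory_from_truth()] or [read_trajectory()]).
#' @param cfg An [analysis_config()].
#' @param arena_radius Arena radius in mm; defaults to the trajectory's
#'   `arena_radius` attribute.
#' @return A `quantized_track` data.frame with columns `index`,
#'   `mean_speed` (mm/s), `state` (`"rest"`/`"run"`), `n_detected`,
#'   `n_outer` (detected samples beyond the centrophobia annulus),
#'   `mean_radius` (mm) and `valid`.
#' @export
quantize <- function(traj, cfg = analysis_config(),
                     arena_radius = attr(traj, "arena_radius")) {
  stopifnot(inherits(traj, "fly_trajectory"), inherits(cfg, "analysis_config"))
  fr <- attr(traj, "frame_rate")
  spq <- round(cfg$quantum * fr)
  if (abs(spq - cfg$quantum * fr) > 1e-8 || spq < 1) {
    stop("quantum must hold an integer number of frames", call. = FALSE)
  }
  n <- nrow(traj)
  n_q <- floor((n - 1) / spq)
  if (n_q < 1) stop("trajectory shorter than one quantum", call. = FALSE)
  if (is.null(arena_radius)) arena_radius <- 10
  cutoff <- cfg$centro_annulus_fraction * arena_radius

  r <- sqrt(traj$x^2 + traj$y^2)
  mean_speed <- numeric(n_q)
  n_det <- integer(n_q)
  n_outer <- integer(n_q)
  mean_rad <- rep(NA_real_, n_q)
  for (k in seq_len(n_q)) {
    i0 <- (k - 1L) * spq + 1L
    idx <- i0:(i0 + spq)            # spq + 1 samples, boundary shared
    det <- idx[traj$detected[idx]]
    nd <- length(det)
    n_det[k] <- nd
    if (nd >= 1) {
      mean_rad[k] <- mean(r[det])
      n_outer[k] <- sum(r[det] > cutoff)
    }
    if (nd >= 2) {
      mean_speed[k] <- sum(sqrt(diff(traj$x[det])^2 +
                                diff(traj$y[det])^2)) / cfg$quantum
    } else {
      mean_speed[k] <- NA_real_
    }
  }
  valid <- n_det >= 2
  state <- ifelse(!valid, NA_character_,
                  ifelse(mean_speed >= cfg$rest_threshold, "run", "rest"))
  structure(
    data.frame(index = seq_len(n_q), mean_speed = mean_speed,
               state = state, n_detected = n_det, n_outer = n_outer,
               mean_radius = mean_rad, valid = valid),
    config = cfg, arena_radius = arena_radius,
    class = c("quantized_track", "data.frame"))
}

#' Segment run bouts from a quantized track
#'
#' A bout is a maximal block of consecutive valid run quanta; invalid
#' quanta break bouts. Bouts truncated by the record edges are counted.
#'
#' @param qt A `quantized_track`.
#' @return data.frame with `start_quantum`, `length_quanta`, `duration`
#'   (s); zero rows if the fly never ran.
#' @export
segment_bouts <- function(qt) {
  stopifnot(inherits(qt, "quantized_track"))
  if (nrow(qt) == 0) stop("empty quantized track", call. = FALSE)
  q <- attr(qt, "config")$quantum
  is_run <- qt$valid & !is.na(qt$state) & qt$state == "run"
  rl <- rle(is_run)
  ends <- cumsum(rl$lengths)
  starts <- ends - rl$lengths + 1L
  keep <- rl$values
  data.frame(start_quantum = starts[keep],
             length_quanta = rl$lengths[keep],
             duration = rl$lengths[keep] * q)
}

#' Compute the per-fly SLA profile
#'
#' The five standard locomotor parameters plus a centrophobia index, all
#' over valid quanta only:
#' \describe{
#'   \item{index_of_activity}{run quanta / valid quanta (fraction; the
#'     conventional-units scale of the assay; set
#'     `activity_as_percent = TRUE` for percent).}
#'   \item{run_frequency}{bouts per 100 s of valid record
#'     (`100 * n_bouts / (valid quanta * quantum)`).}
#'   \item{running_speed}{mean quantum speed over run quanta (mm/s; `NA`
#'     if the fly never ran).}
#'   \item{total_speed}{mean quantum speed over all valid quanta (mm/s).}
#'   \item{run_bout_time}{mean bout duration (s; `NA` without bouts).}
#'   \item{centrophobia_index}{fraction of detected samples farther from
#'     the arena centre than `centro_annulus_fraction * arena_radius`.}
#' }
#' By construction `run_frequency * run_bout_time =
#' 100 * index_of_activity` whenever bouts exist.
#'
#' @param qt A `quantized_track` from [quantize()].
#' @param bouts Bout table; defaults to [segment_bouts()] of `qt`.
#' @param fly_id Identifier copied into the output row.
#' @param activity_as_percent Report index of activity in percent rather
#'   than as a fraction.
#' @return One-row data.frame of class `sla_profile`.
#' @export
compute_profile <- function(qt, bouts = segment_bouts(qt), fly_id = NA,
                            activity_as_percent = FALSE) {
  stopifnot(inherits(qt, "quantized_track"))
  cfg <- attr(qt, "config")
  valid <- qt$valid
  nv <- sum(valid)
  if (nv == 0) stop("no valid quanta", call. = FALSE)
  run_q <- valid & !is.na(qt$state) & qt$state == "run"
  n_run <- sum(run_q)
  ioa <- n_run / nv
  n_bouts <- nrow(bouts)
  run_freq <- 100 * n_bouts / (nv * cfg$quantum)
  running_speed <- if (n_run > 0) mean(qt$mean_speed[run_q]) else NA_real_
  total_speed <- mean(qt$mean_speed[valid])
  bout_time <- if (n_bouts > 0) mean(bouts$duration) else NA_real_
  n_det_tot <- sum(qt$n_detected)
  centro <- if (n_det_tot > 0) sum(qt$n_outer) / n_det_tot else NA_real_
  structure(
    data.frame(fly_id = fly_id,
               index_of_activity = if (activity_as_percent) 100 * ioa else ioa,
               run_frequency = run_freq,
               running_speed = running_speed,
               total_speed = total_speed,
               run_bout_time = bout_time,
               centrophobia_index = centro,
               n_quanta = nv),
    class = c("sla_profile", "data.frame"))
}

#' Full trajectory-to-profile convenience wrapper
#'
#' @param traj A `fly_trajectory`.
#' @inheritParams compute_profile
#' @inheritParams quantize
#' @return One-row `sla_profile` data.frame.
#' @export
sla_profile <- function(traj, cfg = analysis_config(), fly_id = NA,
                        arena_radius = attr(traj, "arena_radius")) {
  qt <- quantize(traj, cfg, arena_radius = arena_radius)
  compute_profile(qt, fly_id = fly_id)
}

#' Plot a fly track inside the arena
#'
#' Presentational: the path of detected samples inside the arena circle,
#' axes in mm, equal aspect. Wall-following ("centrophobic") flies show
#' the characteristic annular path.
#'
#' @param traj A `fly_trajectory`.
#' @param arena_radius Arena radius in mm.
#' @return A ggplot object.
#' @export
plot_track <- function(traj, arena_radius = attr(traj, "arena_radius")) {
  stopifnot(inherits(traj, "fly_trajectory"))
  if (is.null(arena_radius)) arena_radius <- 10
  th <- seq(0, 2 * pi, length.out = 361)
  wall <- data.frame(x = arena_radius * cos(th), y = arena_radius * sin(th))
  pts <- as.data.frame(traj)[traj$detected, , drop = FALSE]
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_path(data = wall, colour = "grey40") +
    ggplot2::geom_path(colour = "#2166ac", linewidth = 0.3) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)") +
    ggplot2::theme_minimal()
}
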
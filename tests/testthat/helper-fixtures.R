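# Fixture builders shared across the suite. Everything is generated in
# code; nothing is read from disk.

# Straight-line trajectory realizing the given per-quantum mean speeds
# exactly: `frame_rate` equal steps of speed*dt per quantum, boundary
# sample shared between quanta.
traj_from_quantum_speeds <- function(speeds, frame_rate = 2, quantum = 1) {
  spq <- frame_rate * quantum
  step_per_frame <- rep(speeds / frame_rate, each = spq)
  x <- c(0, cumsum(step_per_frame))
  n <- length(x)
  flysla:::new_trajectory(
    t = (seq_len(n) - 1) / frame_rate, x = x, y = rep(0, n),
    detected = rep(TRUE, n), frame_rate = frame_rate,
    arena_radius = max(abs(x)) + 1)
}

# Quantized track with prescribed states and speeds (R = run, S = rest),
# built through the public quantize() path.
qt_from_states <- function(states, run_speeds, rest_speeds,
                           rest_threshold = 1) {
  speeds <- numeric(length(states))
  speeds[states == "R"] <- run_speeds
  speeds[states == "S"] <- rest_speeds
  traj <- traj_from_quantum_speeds(speeds)
  quantize(traj, analysis_config(rest_threshold = rest_threshold))
}

# Synthetic bright arena disk on a dark frame.
arena_disk_frame <- function(size = 500, radius = 200, value = 255) {
  ctr <- (size + 1) / 2
  fr <- matrix(0, size, size)
  d2 <- outer((seq_len(size) - ctr)^2, (seq_len(size) - ctr)^2, `+`)
  fr[d2 <= radius^2] <- value
  fr
}

# Brain phantom + ROI pair whose geometry keeps the x ROI inside the
# dimmed disk and the reference ROI clear of it.
clean_ped_fixture <- function(ped_contrast = 0.5, noise_sd = 0, seed = 1,
                              dimmed_slices = 4:6, n_slices = 10) {
  bp <- brain_phantom_params(
    stack_size = c(n_slices, 80, 64), surround_intensity = 100,
    ped_center = c(32, 50), ped_radius = 6, ped_contrast = ped_contrast,
    dimmed_slices = dimmed_slices, noise_sd = noise_sd, seed = seed)
  list(bp = bp, spec = roi_spec(x = 28, y = 46, side = 8, y_offset = -16))
}

# Standard 4-spot serial-dilution membrane phantom.
dilution_phantom <- function(concentrations = c(1, 2, 4, 8),
                             background_sd = 0, seed = 1) {
  dotblot_phantom(
    spot_centers = cbind(20 + 40 * (seq_along(concentrations) - 1), 20),
    concentrations = concentrations, spot_radius = 6,
    darkness_per_unit = 10, background_mean = 200,
    background_sd = background_sd, image_size = c(40, 40 * length(concentrations)),
    seed = seed)
}
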
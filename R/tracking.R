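#' Spatial calibration of an arena recording
#'
#' @param mm_per_pixel Millimetres per pixel (> 0).
#' @param arena_center Pixel coordinates `c(cx, cy)` of the arena centre
#'   (1-based, pixel centres at integer coordinates; `cx` along columns,
#'   `cy` along rows).
#' @param arena_radius_px Arena radius in pixels.
#' @return An object of class `calibration`.
#' @export
calibration <- function(mm_per_pixel, arena_center, arena_radius_px) {
  stop_if_not_scalar_finite(mm_per_pixel, "mm_per_pixel", positive = TRUE)
  stop_if_not_scalar_finite(arena_radius_px, "arena_radius_px",
                            positive = TRUE)
  if (length(arena_center) != 2 || !all(is.finite(arena_center))) {
    stop("`arena_center` must be c(cx, cy)", call. = FALSE)
  }
  structure(list(mm_per_pixel = mm_per_pixel,
                 arena_center = as.numeric(arena_center),
                 arena_radius_px = arena_radius_px),
            class = "calibration")
}

#' @export
print.calibration <- function(x, ...) {
  cat(sprintf(
    "Calibration: %.4g mm/px; centre (%.1f, %.1f) px; radius %.1f px (%.1f mm)\n",
    x$mm_per_pixel, x$arena_center[1], x$arena_center[2],
    x$arena_radius_px, x$arena_radius_px * x$mm_per_pixel))
  invisible(x)
}

#' Detect the fly centroid in one frame
#'
#' Returns the weighted mean position of all pixels strictly brighter
#' than `threshold` (default 60 on the 8-bit scale). With
#' `weighted = TRUE` (default) weights are the pixel intensities, giving
#' sub-pixel accuracy; with `weighted = FALSE` all super-threshold pixels
#' weigh equally (binary-mask centroid).
#'
#' @param frame Numeric matrix, intensities in [0, 255], `frame[row, col]`.
#' @param threshold Detection threshold; pixels with intensity
#'   `> threshold` participate.
#' @param weighted Intensity-weighted (default) or uniform weights.
#' @return Named numeric `c(cx, cy)` in pixel coordinates (1-based,
#'   `cx` = column, `cy` = row), or `NULL` if no pixel exceeds the
#'   threshold (missing detection).
#' @export
#' @examples
#' fr <- matrix(0, 30, 30); fr[20, 10] <- 100
#' detect_centroid(fr)  # c(cx = 10, cy = 20)
detect_centroid <- function(frame, threshold = 60, weighted = TRUE) {
  if (!is.matrix(frame) || !is.numeric(frame) || length(frame) == 0) {
    stop("`frame` must be a non-empty numeric matrix", call. = FALSE)
  }
  idx <- which(frame > threshold, arr.ind = TRUE)
  if (nrow(idx) == 0) return(NULL)
  w <- if (weighted) frame[idx] else rep(1, nrow(idx))
  c(cx = sum(w * idx[, "col"]) / sum(w),
    cy = sum(w * idx[, "row"]) / sum(w))
}

new_trajectory <- function(t, x, y, detected, frame_rate,
                           arena_radius = NULL, calibration = NULL,
                           threshold = NULL) {
  df <- data.frame(t = t, x = x, y = y, detected = detected)
  structure(df,
            frame_rate = frame_rate,
            arena_radius = arena_radius,
            calibration = calibration,
            threshold = threshold,
            class = c("fly_trajectory", "data.frame"))
}

#' Track a frame sequence into a calibrated trajectory
#'
#' Applies [detect_centroid()] to every frame and converts pixel
#' centroids to arena-centred mm coordinates:
#' `x = (cx - centre_x) * mm_per_pixel`,
#' `y = -(cy - centre_y) * mm_per_pixel` (image y points down, so it is
#' negated to make +y "up"). Frames with no super-threshold pixel are
#' carried as flagged gaps (`detected = FALSE`, coordinates `NA`), never
#' interpolated.
#'
#' @param frames List of grayscale matrices (0-255).
#' @param calibration A [calibration()] object consistent with the frame
#'   geometry.
#' @param threshold Detection threshold (default 60).
#' @param frame_rate Frames per second (default 10).
#' @param weighted Passed to [detect_centroid()].
#' @return A `fly_trajectory` data.frame (`t`, `x`, `y`, `detected`) with
#'   attributes `frame_rate`, `calibration`, `arena_radius` (mm) and
#'   `fraction_detected`.
#' @export
track_frames <- function(frames, calibration, threshold = 60,
                         frame_rate = 10, weighted = TRUE) {
  if (length(frames) == 0) stop("no frames supplied", call. = FALSE)
  stopifnot(inherits(calibration, "calibration"))
  d <- dim(frames[[1]])
  ctr <- calibration$arena_center
  if (ctr[1] - calibration$arena_radius_px < 0.5 ||
      ctr[1] + calibration$arena_radius_px > d[2] + 0.5 ||
      ctr[2] - calibration$arena_radius_px < 0.5 ||
      ctr[2] + calibration$arena_radius_px > d[1] + 0.5) {
    stop("calibration circle extends outside the image", call. = FALSE)
  }
  n <- length(frames)
  x <- rep(NA_real_, n)
  y <- rep(NA_real_, n)
  det <- logical(n)
  for (i in seq_len(n)) {
    cen <- detect_centroid(frames[[i]], threshold = threshold,
                           weighted = weighted)
    if (!is.null(cen)) {
      det[i] <- TRUE
      x[i] <- (cen[["cx"]] - ctr[1]) * calibration$mm_per_pixel
      y[i] <- -(cen[["cy"]] - ctr[2]) * calibration$mm_per_pixel
    }
  }
  tr <- new_trajectory(
    t = (seq_len(n) - 1) / frame_rate, x = x, y = y, detected = det,
    frame_rate = frame_rate,
    arena_radius = calibration$arena_radius_px * calibration$mm_per_pixel,
    calibration = calibration, threshold = threshold)
  attr(tr, "fraction_detected") <- mean(det)
  tr
}

#' Calibrate from an image of the illuminated arena
#'
#' Finds the largest bright connected region (assumed to be the arena
#' disk), fits a circle as its centroid plus the radius implied by its
#' area, and sets `mm_per_pixel = diameter_mm / fitted diameter`.
#'
#' @param frame Grayscale matrix (0-255) in which the arena disk is the
#'   largest bright region.
#' @param diameter_mm True arena diameter in mm (default 20, the standard
#'   chamber).
#' @param threshold Intensity above which a pixel counts as bright;
#'   default halfway between the image minimum and maximum.
#' @param override Optional [calibration()]: when supplied, fitting is
#'   skipped and the override is returned unchanged (manual calibration).
#' @return A [calibration()] object.
#' @export
calibrate_from_arena <- function(frame, diameter_mm = 20, threshold = NULL,
                                 override = NULL) {
  if (!is.null(override)) {
    stopifnot(inherits(override, "calibration"))
    return(override)
  }
  if (!is.matrix(frame) || length(frame) == 0) {
    stop("`frame` must be a non-empty matrix", call. = FALSE)
  }
  rng <- range(frame)
  if (is.null(threshold)) threshold <- mean(rng)
  mask <- frame > threshold
  if (!any(mask)) stop("no arena detected (no pixels above threshold)",
                       call. = FALSE)
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  labm <- EBImage::imageData(lab)
  # EBImage images are (x, y) transposed relative to R matrices; the
  # mask was passed as [row, col], so labm rows are matrix rows here.
  tab <- tabulate(labm[labm > 0])
  biggest <- which.max(tab)
  idx <- which(labm == biggest, arr.ind = TRUE)
  area <- nrow(idx)
  diameter_px <- 2 * sqrt(area / pi)
  if (diameter_px < 20) {
    stop("fitted arena diameter below 20 px: resolution too low",
         call. = FALSE)
  }
  calibration(mm_per_pixel = diameter_mm / diameter_px,
              arena_center = c(mean(idx[, 2]), mean(idx[, 1])),
              arena_radius_px = diameter_px / 2)
}

#' Write / read a trajectory as CSV with a JSON header sidecar
#'
#' @param traj A `fly_trajectory`.
#' @param csv_path Output CSV (`t`, `x_mm`, `y_mm`, `detected`).
#' @param json_path Sidecar JSON (frame rate, threshold, calibration);
#'   defaults to the CSV path with a `.json` extension.
#' @return Invisibly, the CSV path.
#' @export
write_trajectory <- function(traj, csv_path,
                             json_path = sub("\\.csv$", ".json", csv_path)) {
  stopifnot(inherits(traj, "fly_trajectory"))
  write.csv(data.frame(t = traj$t, x_mm = traj$x, y_mm = traj$y,
                       detected = traj$detected),
            csv_path, row.names = FALSE)
  cal <- attr(traj, "calibration")
  hdr <- list(frame_rate = attr(traj, "frame_rate"),
              threshold = attr(traj, "threshold"),
              arena_radius_mm = attr(traj, "arena_radius"),
              calibration = if (!is.null(cal)) unclass(cal))
  jsonlite::write_json(hdr, json_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(csv_path)
}

#' @rdname write_trajectory
#' @param check_json Read the sidecar if present.
#' @export
read_trajectory <- function(csv_path,
                            json_path = sub("\\.csv$", ".json", csv_path),
                            check_json = TRUE) {
  df <- read.csv(csv_path)
  frame_rate <- NULL
  arena_radius <- NULL
  threshold <- NULL
  if (check_json && file.exists(json_path)) {
    hdr <- jsonlite::read_json(json_path, simplifyVector = TRUE)
    frame_rate <- hdr$frame_rate
    arena_radius <- hdr$arena_radius_mm
    threshold <- hdr$threshold
  }
  if (is.null(frame_rate)) {
    dtv <- diff(df$t)
    frame_rate <- 1 / stats::median(dtv)
  }
  new_trajectory(t = df$t, x = df$x_mm, y = df$y_mm,
                 detected = as.logical(df$detected),
                 frame_rate = frame_rate, arena_radius = arena_radius,
                 threshold = threshold)
}
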
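#' Rendering parameters for synthetic arena frames
#'
#' Controls how a walker trajectory is painted into 8-bit grayscale
#' frames: a radially symmetric Gaussian bright blob (the fly) on a noisy
#' dark background. The invariant `fly_peak_intensity > 60 >
#' background_mean + 3 * background_sd` guarantees the fly is detectable
#' at the standard threshold of 60 while the background (almost surely)
#' is not.
#'
#' @param image_size Side of the square frame in pixels.
#' @param mm_per_pixel Spatial calibration (mm per pixel).
#' @param fly_peak_intensity Peak blob intensity, 0-255.
#' @param fly_radius_sigma Blob Gaussian sigma in pixels.
#' @param background_mean,background_sd Background intensity law, 0-255.
#' @param bit_depth Bits per pixel; 8 (values rounded to integers 0-255).
#' @return An object of class `render_params`.
#' @export
render_params <- function(image_size = 120L, mm_per_pixel = 0.2,
                          fly_peak_intensity = 200, fly_radius_sigma = 2,
                          background_mean = 20, background_sd = 0,
                          bit_depth = 8L) {
  stop_if_not_scalar_finite(image_size, "image_size", positive = TRUE)
  stop_if_not_scalar_finite(mm_per_pixel, "mm_per_pixel", positive = TRUE)
  stop_if_not_scalar_finite(fly_peak_intensity, "fly_peak_intensity",
                            positive = TRUE)
  stop_if_not_scalar_finite(fly_radius_sigma, "fly_radius_sigma",
                            positive = TRUE)
  stop_if_not_scalar_finite(background_mean, "background_mean", nonneg = TRUE)
  stop_if_not_scalar_finite(background_sd, "background_sd", nonneg = TRUE)
  if (!(fly_peak_intensity > 60 &&
        60 > background_mean + 3 * background_sd)) {
    stop(paste("need fly_peak_intensity > 60 >",
               "background_mean + 3 * background_sd"), call. = FALSE)
  }
  if (bit_depth != 8) stop("only bit_depth = 8 is supported", call. = FALSE)
  structure(
    list(image_size = as.integer(image_size), mm_per_pixel = mm_per_pixel,
         fly_peak_intensity = fly_peak_intensity,
         fly_radius_sigma = fly_radius_sigma,
         background_mean = background_mean, background_sd = background_sd,
         bit_depth = 8L),
    class = "render_params")
}

#' Image centre (pixel coordinates) used when rendering an arena
#' @noRd
render_center <- function(rp) (rp$image_size + 1) / 2

#' Render a walker trajectory into grayscale frames
#'
#' Each frame is normal background noise plus a Gaussian blob of peak
#' `fly_peak_intensity` centred at the fly position (mm coordinates
#' mapped to pixels around the image centre, +y up). Values are clipped
#' to [0, 255] and rounded to 8-bit integers. Deterministic given `seed`.
#'
#' @param truth A `ground_truth` object (or any data.frame with `x`, `y`
#'   in mm).
#' @param rp A [render_params()] object.
#' @param seed Seed for the background noise.
#' @param draw_fly If `FALSE` the blob is omitted (blank frames, used to
#'   exercise missing-detection handling).
#' @return List of numeric matrices (rows = image y, cols = image x),
#'   intensities 0-255.
#' @export
render_frames <- function(truth, rp, seed = 1L, draw_fly = TRUE) {
  stopifnot(inherits(rp, "render_params"))
  pos <- if (inherits(truth, "ground_truth")) truth$positions else truth
  n <- nrow(pos)
  if (n == 0) stop("no positions to render", call. = FALSE)
  ctr <- render_center(rp)
  pcol <- ctr + pos$x / rp$mm_per_pixel
  prow <- ctr - pos$y / rp$mm_per_pixel
  if (any(pcol < 1 | pcol > rp$image_size | prow < 1 | prow > rp$image_size)) {
    stop("position maps outside the image; increase image_size or shrink",
         " mm_per_pixel", call. = FALSE)
  }
  sz <- rp$image_size
  half <- ceiling(5 * rp$fly_radius_sigma)
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      fr <- matrix(rnorm(sz * sz, rp$background_mean, rp$background_sd),
                   nrow = sz, ncol = sz)
      if (draw_fly) {
        r0 <- max(1L, floor(prow[i] - half))
        r1 <- min(sz, ceiling(prow[i] + half))
        c0 <- max(1L, floor(pcol[i] - half))
        c1 <- min(sz, ceiling(pcol[i] + half))
        rr <- r0:r1
        cc <- c0:c1
        blob <- rp$fly_peak_intensity *
          outer(exp(-(rr - prow[i])^2 / (2 * rp$fly_radius_sigma^2)),
                exp(-(cc - pcol[i])^2 / (2 * rp$fly_radius_sigma^2)))
        fr[rr, cc] <- fr[rr, cc] + blob
      }
      round(pmin(pmax(fr, 0), 255))
    })
  })
}

#' Calibration matching a render_params geometry
#'
#' Convenience for round-trip tests: the [calibration()] whose centre and
#' scale invert the mm-to-pixel mapping used by [render_frames()].
#'
#' @param rp A [render_params()] object.
#' @param arena_radius Arena radius in mm.
#' @return A [calibration()] object.
#' @export
calibration_from_render <- function(rp, arena_radius = 10) {
  stopifnot(inherits(rp, "render_params"))
  ctr <- render_center(rp)
  calibration(mm_per_pixel = rp$mm_per_pixel,
              arena_center = c(ctr, ctr),
              arena_radius_px = arena_radius / rp$mm_per_pixel)
}

#' Write frames as numbered 8-bit PNG files
#'
#' @param frames List of matrices (0-255).
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Invisibly, the vector of file paths.
#' @export
write_frames_png <- function(frames, dir, prefix = "frame") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, sprintf("%s_%05d.png", prefix, seq_along(frames)))
  for (i in seq_along(frames)) {
    png::writePNG(frames[[i]] / 255, paths[i])
  }
  invisible(paths)
}

#' Read a frame sequence
#'
#' Accepts a directory of numbered PNG files or a (multi-page) TIFF file
#' and returns frames as matrices with intensities on the 0-255 scale.
#'
#' @param path Directory of `*.png` frames or a `.tif`/`.tiff` file.
#' @return List of numeric matrices.
#' @export
read_frames <- function(path) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE))
    if (length(files) == 0) stop("no PNG frames in ", path, call. = FALSE)
    lapply(files, function(f) round(png::readPNG(f) * 255))
  } else if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    lapply(pages, function(m) {
      if (length(dim(m)) == 3) m <- m[, , 1]
      round(m * 255)
    })
  } else {
    stop("`path` must be a directory of PNGs or a TIFF file", call. = FALSE)
  }
}
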
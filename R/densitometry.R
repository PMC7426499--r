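#' Circular spot specification for dot-blot densitometry
#'
#' A spot disk plus a disjoint concentric background annulus, all in
#' pixels (1-based pixel centres).
#'
#' @param center `c(cx, cy)` pixel coordinates of the spot centre.
#' @param radius Spot radius in pixels.
#' @param annulus `c(inner, outer)` radii of the background annulus;
#'   `inner >= radius` so the annulus is disjoint from the spot.
#' @return An object of class `spot_spec`.
#' @export
spot_spec <- function(center, radius, annulus = c(radius + 2, radius + 6)) {
  if (length(center) != 2 || !all(is.finite(center))) {
    stop("`center` must be c(cx, cy)", call. = FALSE)
  }
  stop_if_not_scalar_finite(radius, "radius", positive = TRUE)
  if (length(annulus) != 2 || annulus[1] < radius ||
      annulus[2] <= annulus[1]) {
    stop("`annulus` must be c(inner, outer) with inner >= radius < outer",
         call. = FALSE)
  }
  structure(list(center = as.numeric(center), radius = radius,
                 annulus = as.numeric(annulus)),
            class = "spot_spec")
}

disk_mask_values <- function(image, center, r_min, r_max) {
  nr <- nrow(image)
  nc <- ncol(image)
  cx <- center[1]
  cy <- center[2]
  c0 <- max(1L, floor(cx - r_max))
  c1 <- min(nc, ceiling(cx + r_max))
  r0 <- max(1L, floor(cy - r_max))
  r1 <- min(nr, ceiling(cy + r_max))
  if (c0 > c1 || r0 > r1) return(numeric(0))
  sub <- image[r0:r1, c0:c1, drop = FALSE]
  d2 <- outer(((r0:r1) - cy)^2, ((c0:c1) - cx)^2, `+`)
  sub[d2 > r_min^2 & d2 <= r_max^2]
}

#' Measure the optical density of a membrane spot
#'
#' OD is operationalized for light membranes with dark spots as
#' `max(0, mean(background annulus) - mean(spot disk))` on the 0-255
#' intensity scale: a darker spot gives a larger OD, and a spot no darker
#' than its local background reads 0. Using a local annulus makes the
#' measurement invariant to adding a constant to the whole image and
#' robust to illumination gradients.
#'
#' @param image Grayscale matrix (0-255).
#' @param spec A [spot_spec()], fully inside the image.
#' @return List of class `spot_od`: `od`, `spot_mean`, `background_mean`,
#'   `n_pixels` (spot pixel count).
#' @export
measure_od <- function(image, spec) {
  stopifnot(is.matrix(image), inherits(spec, "spot_spec"))
  cx <- spec$center[1]
  cy <- spec$center[2]
  r_out <- spec$annulus[2]
  if (cx - r_out < 0.5 || cx + r_out > ncol(image) + 0.5 ||
      cy - r_out < 0.5 || cy + r_out > nrow(image) + 0.5) {
    stop("spot spec (including annulus) extends outside the image",
         call. = FALSE)
  }
  spot <- disk_mask_values(image, spec$center, -1, spec$radius)
  bg <- disk_mask_values(image, spec$center, spec$annulus[1], spec$annulus[2])
  if (length(spot) == 0) stop("empty spot disk", call. = FALSE)
  if (length(bg) == 0) stop("empty background annulus", call. = FALSE)
  sm <- mean(spot)
  bm <- mean(bg)
  structure(list(od = max(0, bm - sm), spot_mean = sm, background_mean = bm,
                 n_pixels = length(spot)),
            class = "spot_od")
}

od_value <- function(x) {
  if (inherits(x, "spot_od")) x$od else as.numeric(x)
}

#' Normalize a densitometric signal
#'
#' The three normalization schemes used for PB-3-HOK dot blots:
#' `beta_actin` and `total_protein` divide the target OD by a reference
#' OD measured on the same sample (loading control); `age_mean_cu`
#' divides each OD of an age cohort by the cohort mean, yielding
#' conventional units whose cohort mean is exactly 1.
#'
#' @param target A `spot_od` or numeric OD (for the ratio schemes), or a
#'   vector of ODs / list of `spot_od` (for `age_mean_cu`).
#' @param reference Reference `spot_od` or numeric OD (> 0); required for
#'   the ratio schemes.
#' @param scheme One of `"beta_actin"`, `"total_protein"`,
#'   `"age_mean_cu"`.
#' @return For ratio schemes a single normalized value; for
#'   `age_mean_cu` the vector of cohort values (mean 1). The result
#'   carries a `scheme` attribute.
#' @export
normalize_signal <- function(target, reference = NULL,
                             scheme = c("beta_actin", "total_protein",
                                        "age_mean_cu")) {
  scheme <- match.arg(scheme)
  if (scheme == "age_mean_cu") {
    ods <- vapply(if (is.list(target)) target else as.list(target),
                  od_value, numeric(1))
    if (length(ods) == 0) stop("empty cohort", call. = FALSE)
    m <- mean(ods)
    if (m <= 0) stop("cohort mean OD is zero; cannot normalize",
                     call. = FALSE)
    out <- ods / m
  } else {
    if (is.null(reference)) {
      stop("ratio schemes need a `reference`", call. = FALSE)
    }
    ref <- od_value(reference)
    if (ref <= 0) stop("reference OD must be > 0", call. = FALSE)
    out <- od_value(target) / ref
  }
  attr(out, "scheme") <- scheme
  out
}

#' Fit the serial-dilution standard curve
#'
#' Ordinary least squares of OD on concentration: `od = slope * conc +
#' intercept`, with the coefficient of determination reported. The assay
#' is valid in its linear range, so the fit also records the
#' concentration range it covers.
#'
#' @param concentrations Numeric, arbitrary concentration units; at
#'   least 3 points with at least 2 distinct values.
#' @param ods Numeric ODs (or list of `spot_od`), same length.
#' @return List of class `standard_curve`: `slope`, `intercept`,
#'   `r_squared`, `concentration_range`, `fit` (the `lm` object).
#' @export
fit_standard_curve <- function(concentrations, ods) {
  ods <- vapply(if (is.list(ods)) ods else as.list(ods), od_value,
                numeric(1))
  if (length(concentrations) != length(ods)) {
    stop("`concentrations` and `ods` lengths differ", call. = FALSE)
  }
  if (length(ods) < 3) stop("need at least 3 points", call. = FALSE)
  if (length(unique(concentrations)) < 2) {
    stop("need at least 2 distinct concentrations", call. = FALSE)
  }
  fit <- lm(ods ~ concentrations)
  ss_res <- sum(residuals(fit)^2)
  ss_tot <- sum((ods - mean(ods))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = r2,
                 concentration_range = range(concentrations),
                 fit = fit),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("Standard curve: od = %.4g * conc + %.4g (R^2 = %.4f)\n",
              x$slope, x$intercept, x$r_squared))
  invisible(x)
}

#' Invert a standard curve: OD to concentration
#'
#' @param curve A [fit_standard_curve()] result.
#' @param od OD value(s) to convert.
#' @return Estimated concentration(s); warns when the estimate falls
#'   outside the fitted concentration range (extrapolation).
#' @export
invert_standard_curve <- function(curve, od) {
  stopifnot(inherits(curve, "standard_curve"))
  if (abs(curve$slope) < 1e-12) {
    stop("flat standard curve (slope 0) cannot be inverted", call. = FALSE)
  }
  conc <- (od_value(od) - curve$intercept) / curve$slope
  rng <- curve$concentration_range
  if (any(conc < rng[1] | conc > rng[2])) {
    warning("estimated concentration outside the fitted standard range; ",
            "extrapolating")
  }
  conc
}

#' Antibody-specificity delta
#'
#' OD difference with and without pre-incubation of the antibody with its
#' antigen: a positive delta is blockable, i.e. specific, signal. A
#' negative delta (blocked spot darker than unblocked) is reported as-is
#' with a warning.
#'
#' @param od_without_block,od_with_block ODs (`spot_od` or numeric,
#'   both >= 0).
#' @return `od_without_block - od_with_block`.
#' @export
specificity_delta <- function(od_without_block, od_with_block) {
  a <- od_value(od_without_block)
  b <- od_value(od_with_block)
  if (a < 0 || b < 0) stop("ODs must be >= 0", call. = FALSE)
  delta <- a - b
  if (delta < 0) {
    warning("blocked OD exceeds unblocked OD (negative specificity delta)")
  }
  delta
}

#' Dot-blot membrane phantom specification
#'
#' Synthetic membrane for validating densitometry: dark spots on a light
#' noisy background, spot darkness proportional to analyte concentration
#' (`darkness = darkness_per_unit * concentration`, clipped to
#' `[0, background_mean]`), emulating a serial-dilution standard series.
#'
#' @param spot_centers Two-column matrix (cx, cy) of spot centres in
#'   pixels, one row per spot.
#' @param spot_radius Spot radius in pixels (common to all spots).
#' @param concentrations Per-spot concentrations, arbitrary units.
#' @param darkness_per_unit Intensity decrement per concentration unit.
#' @param background_mean,background_sd Background intensity law (light
#'   membrane, e.g. mean 200).
#' @param image_size `c(rows, cols)` of the membrane image.
#' @param seed Noise seed.
#' @return Object of class `dotblot_phantom`.
#' @export
dotblot_phantom <- function(spot_centers, concentrations, spot_radius = 6,
                            darkness_per_unit = 10, background_mean = 200,
                            background_sd = 0, image_size = NULL,
                            seed = 1L) {
  spot_centers <- matrix(as.numeric(spot_centers), ncol = 2)
  n <- nrow(spot_centers)
  if (length(concentrations) != n) {
    stop("one concentration per spot required", call. = FALSE)
  }
  if (any(concentrations < 0)) {
    stop("concentrations must be >= 0", call. = FALSE)
  }
  if (n > 1) {
    d <- as.matrix(dist(spot_centers))
    diag(d) <- Inf
    if (any(d <= 2 * spot_radius)) {
      stop("overlapping spot disks", call. = FALSE)
    }
  }
  if (is.null(image_size)) {
    image_size <- c(ceiling(max(spot_centers[, 2]) + 4 * spot_radius),
                    ceiling(max(spot_centers[, 1]) + 4 * spot_radius))
  }
  structure(list(spot_centers = spot_centers, spot_radius = spot_radius,
                 concentrations = as.numeric(concentrations),
                 darkness_per_unit = darkness_per_unit,
                 background_mean = background_mean,
                 background_sd = background_sd,
                 image_size = as.integer(image_size),
                 seed = as.integer(seed)),
            class = "dotblot_phantom")
}

#' Render a dot-blot membrane phantom
#'
#' @param phantom A [dotblot_phantom()].
#' @return Numeric matrix (0-255 scale; values are left unrounded so the
#'   noiseless rendering is exactly linear in concentration).
#' @export
synth_dotblot <- function(phantom) {
  stopifnot(inherits(phantom, "dotblot_phantom"))
  p <- phantom
  nr <- p$image_size[1]
  nc <- p$image_size[2]
  with_seed(p$seed, {
    img <- matrix(p$background_mean +
                    rnorm(nr * nc, 0, p$background_sd),
                  nrow = nr, ncol = nc)
    for (i in seq_len(nrow(p$spot_centers))) {
      dark <- min(max(p$darkness_per_unit * p$concentrations[i], 0),
                  p$background_mean)
      cx <- p$spot_centers[i, 1]
      cy <- p$spot_centers[i, 2]
      c0 <- max(1L, floor(cx - p$spot_radius))
      c1 <- min(nc, ceiling(cx + p$spot_radius))
      r0 <- max(1L, floor(cy - p$spot_radius))
      r1 <- min(nr, ceiling(cy + p$spot_radius))
      d2 <- outer(((r0:r1) - cy)^2, ((c0:c1) - cx)^2, `+`)
      sub <- img[r0:r1, c0:c1]
      sub[d2 <= p$spot_radius^2] <- sub[d2 <= p$spot_radius^2] - dark
      img[r0:r1, c0:c1] <- sub
    }
    pmin(pmax(img, 0), 255)
  })
}

#' Measure a rendered dilution series and fit its standard curve
#'
#' Convenience for validation: renders the phantom, measures each spot's
#' OD with the default annulus, and fits the standard curve against the
#' phantom's concentrations.
#'
#' @param phantom A [dotblot_phantom()].
#' @return List with `ods` (numeric), `curve` (a `standard_curve`).
#' @export
measure_dotblot_series <- function(phantom) {
  img <- synth_dotblot(phantom)
  ods <- vapply(seq_len(nrow(phantom$spot_centers)), function(i) {
    spec <- spot_spec(phantom$spot_centers[i, ], phantom$spot_radius)
    measure_od(img, spec)$od
  }, numeric(1))
  list(ods = ods,
       curve = fit_standard_curve(phantom$concentrations, ods))
}
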
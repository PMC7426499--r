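#' Brain phantom parameters
#'
#' Synthetic confocal stack for validating the pedunculus ratio: a
#' uniform bright neuropil (`surround_intensity`) with, in selected
#' slices, a darkened circular "pedunculus" region of intensity
#' `ped_contrast * surround_intensity`, plus per-pixel Gaussian noise.
#'
#' @param stack_size `c(slices, height, width)` in pixels.
#' @param surround_intensity Background neuropil intensity, 0-255.
#' @param ped_center `c(cx, cy)` pixel coordinates of the pedunculus
#'   disk.
#' @param ped_radius Disk radius in pixels; the disk must lie strictly
#'   inside the image.
#' @param ped_contrast In (0, 1]: 1 means no dimming.
#' @param dimmed_slices Slice indices (1-based) where the disk is dimmed.
#' @param noise_sd Per-pixel Gaussian noise SD.
#' @param seed Noise seed.
#' @return Object of class `brain_phantom_params`.
#' @export
brain_phantom_params <- function(stack_size = c(10L, 64L, 64L),
                                 surround_intensity = 100,
                                 ped_center = c(32, 40), ped_radius = 6,
                                 ped_contrast = 0.5,
                                 dimmed_slices = 4:6, noise_sd = 0,
                                 seed = 1L) {
  if (length(stack_size) != 3 || any(stack_size < 1)) {
    stop("`stack_size` must be c(slices, height, width)", call. = FALSE)
  }
  stop_if_not_scalar_finite(surround_intensity, "surround_intensity",
                            positive = TRUE)
  stop_if_not_scalar_finite(ped_contrast, "ped_contrast", positive = TRUE)
  if (ped_contrast > 1) stop("`ped_contrast` must be in (0, 1]",
                             call. = FALSE)
  stop_if_not_scalar_finite(ped_radius, "ped_radius", positive = TRUE)
  h <- stack_size[2]
  w <- stack_size[3]
  if (ped_center[1] - ped_radius <= 1 || ped_center[1] + ped_radius >= w ||
      ped_center[2] - ped_radius <= 1 || ped_center[2] + ped_radius >= h) {
    stop("pedunculus disk must lie strictly inside the image",
         call. = FALSE)
  }
  if (any(dimmed_slices < 1 | dimmed_slices > stack_size[1])) {
    stop("`dimmed_slices` outside the stack", call. = FALSE)
  }
  stop_if_not_scalar_finite(noise_sd, "noise_sd", nonneg = TRUE)
  structure(list(stack_size = as.integer(stack_size),
                 surround_intensity = surround_intensity,
                 ped_center = as.numeric(ped_center),
                 ped_radius = ped_radius, ped_contrast = ped_contrast,
                 dimmed_slices = as.integer(dimmed_slices),
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "brain_phantom_params")
}

#' Render a brain phantom stack
#'
#' @param bp A [brain_phantom_params()].
#' @return 3-D numeric array `[row, col, slice]`, 0-255 scale (unrounded
#'   so noiseless contrast is exact).
#' @export
synth_brain_stack <- function(bp) {
  stopifnot(inherits(bp, "brain_phantom_params"))
  ns <- bp$stack_size[1]
  h <- bp$stack_size[2]
  w <- bp$stack_size[3]
  with_seed(bp$seed, {
    stack <- array(bp$surround_intensity, dim = c(h, w, ns))
    d2 <- outer((seq_len(h) - bp$ped_center[2])^2,
                (seq_len(w) - bp$ped_center[1])^2, `+`)
    disk <- d2 <= bp$ped_radius^2
    for (s in bp$dimmed_slices) {
      sl <- stack[, , s]
      sl[disk] <- bp$ped_contrast * bp$surround_intensity
      stack[, , s] <- sl
    }
    if (bp$noise_sd > 0) {
      stack <- stack + array(rnorm(h * w * ns, 0, bp$noise_sd),
                             dim = c(h, w, ns))
    }
    stack
  })
}

#' ROI specification for the pedunculus ratio
#'
#' A square ROI on the dimmed pedunculus (`x` ROI) given by its top-left
#' pixel and side length; the reference `y` ROI is the same-size square
#' immediately above it (shifted toward the image top by one side
#' length, i.e. adjacent and non-overlapping).
#'
#' @param x,y Top-left pixel of the pedunculus ROI (column `x`, row `y`,
#'   1-based).
#' @param side Side length in pixels.
#' @param channel Channel index of the measurement channel (for
#'   multi-channel stacks).
#' @param y_offset Row offset of the reference ROI's top-left relative
#'   to the pedunculus ROI; default `-side` (immediately above).
#' @return Object of class `roi_spec`.
#' @export
roi_spec <- function(x, y, side, channel = 1L, y_offset = -side) {
  stop_if_not_scalar_finite(side, "side", positive = TRUE)
  if (side != round(side)) stop("`side` must be an integer", call. = FALSE)
  structure(list(x = as.integer(x), y = as.integer(y),
                 side = as.integer(side), channel = as.integer(channel),
                 y_offset = as.integer(y_offset)),
            class = "roi_spec")
}

roi_slice_matrix <- function(stack, spec, s) {
  if (length(dim(stack)) == 4) {
    stack[, , s, spec$channel]
  } else {
    stack[, , s]
  }
}

check_roi_inside <- function(stack, spec) {
  h <- dim(stack)[1]
  w <- dim(stack)[2]
  y2_top <- spec$y + spec$y_offset
  ok <- spec$x >= 1 && spec$x + spec$side - 1 <= w &&
    spec$y >= 1 && spec$y + spec$side - 1 <= h &&
    y2_top >= 1 && y2_top + spec$side - 1 <= h
  if (!ok) {
    stop("ROI (or its reference ROI above) falls outside the image",
         call. = FALSE)
  }
}

roi_mean <- function(mat, x, y, side) {
  mean(mat[y:(y + side - 1), x:(x + side - 1)])
}

#' Select the slices with maximum pedunculus dimming
#'
#' Returns the `k` slices whose mean intensity inside the pedunculus ROI
#' is lowest (ties broken toward the lower slice index), sorted
#' ascending.
#'
#' @param stack 3-D array `[row, col, slice]` (or 4-D with channels).
#' @param spec A [roi_spec()].
#' @param k Number of slices to select (default 3).
#' @return Integer vector of `k` slice indices.
#' @export
select_dimmed_slices <- function(stack, spec, k = 3L) {
  stopifnot(inherits(spec, "roi_spec"))
  check_roi_inside(stack, spec)
  ns <- dim(stack)[3]
  if (ns < k) stop("stack has fewer than ", k, " slices", call. = FALSE)
  means <- vapply(seq_len(ns), function(s) {
    roi_mean(roi_slice_matrix(stack, spec, s), spec$x, spec$y, spec$side)
  }, numeric(1))
  sort(order(means)[seq_len(k)])
}

#' Pedunculus ratio R = x/y
#'
#' The relative decrease of staining in the pedunculus: `x` is the mean
#' intensity of the pedunculus ROI and `y` that of the same-size ROI
#' immediately above it, both averaged over the `k` slices with maximum
#' pedunculus dimming (averaging over slices happens before the ratio;
#' set `slice_average = "after_ratio"` to average per-slice ratios
#' instead). R near 1 means no local dimming.
#'
#' @inheritParams select_dimmed_slices
#' @param slice_average `"before_ratio"` (default) or `"after_ratio"`.
#' @return List of class `ped_ratio_result`: `x`, `y`, `R`,
#'   `slices_used`.
#' @export
ped_ratio <- function(stack, spec, k = 3L,
                      slice_average = c("before_ratio", "after_ratio")) {
  slice_average <- match.arg(slice_average)
  slices <- select_dimmed_slices(stack, spec, k)
  y_top <- spec$y + spec$y_offset
  xs <- vapply(slices, function(s) {
    roi_mean(roi_slice_matrix(stack, spec, s), spec$x, spec$y, spec$side)
  }, numeric(1))
  ys <- vapply(slices, function(s) {
    roi_mean(roi_slice_matrix(stack, spec, s), spec$x, y_top, spec$side)
  }, numeric(1))
  x <- mean(xs)
  y <- mean(ys)
  if (y <= 0) stop("reference ROI mean is not positive", call. = FALSE)
  R <- if (slice_average == "before_ratio") x / y else mean(xs / ys)
  structure(list(x = x, y = y, R = R, slices_used = slices),
            class = "ped_ratio_result")
}

#' @export
print.ped_ratio_result <- function(x, ...) {
  cat(sprintf("Ped ratio R = %.4f (x = %.2f, y = %.2f; slices %s)\n",
              x$R, x$x, x$y, paste(x$slices_used, collapse = ", ")))
  invisible(x)
}

#' Batch pedunculus ratios with a group comparison
#'
#' Computes one [ped_ratio()] per brain and, when at least two groups
#' have two or more brains each, compares R between groups — by default
#' with Welch's two-sided t-test (the convention for this ratio), or
#' with the Mann-Whitney U test.
#'
#' @param stacks List of stacks, one per brain.
#' @param specs A single [roi_spec()] (recycled) or list of specs.
#' @param groups Group label per brain.
#' @param brain_ids Optional identifiers.
#' @param test `"t"` (Welch) or `"mann_whitney"`.
#' @param ... Passed to [ped_ratio()].
#' @return List with `table` (brain_id, group, x, y, R, slices_used) and
#'   `tests` (data.frame of pairwise group tests with p and tier, or
#'   `NULL` when no group pair is testable).
#' @export
batch_ratios <- function(stacks, specs, groups,
                         brain_ids = seq_along(stacks),
                         test = c("t", "mann_whitney"), ...) {
  test <- match.arg(test)
  n <- length(stacks)
  if (length(groups) != n) stop("one group label per stack", call. = FALSE)
  if (inherits(specs, "roi_spec")) specs <- rep(list(specs), n)
  res <- lapply(seq_len(n), function(i) ped_ratio(stacks[[i]], specs[[i]], ...))
  tab <- data.frame(
    brain_id = brain_ids, group = as.character(groups),
    x = vapply(res, `[[`, numeric(1), "x"),
    y = vapply(res, `[[`, numeric(1), "y"),
    R = vapply(res, `[[`, numeric(1), "R"),
    slices_used = vapply(res, function(r) {
      paste(r$slices_used, collapse = ";")
    }, character(1)))
  lev <- unique(tab$group)
  tests <- NULL
  if (length(lev) >= 2) {
    pairs <- combn(lev, 2)
    rows <- list()
    for (j in seq_len(ncol(pairs))) {
      ra <- tab$R[tab$group == pairs[1, j]]
      rb <- tab$R[tab$group == pairs[2, j]]
      if (length(ra) < 2 || length(rb) < 2) next
      if (test == "t") {
        ht <- t.test(ra, rb)
        rows[[length(rows) + 1L]] <- data.frame(
          group_a = pairs[1, j], group_b = pairs[2, j],
          statistic = unname(ht$statistic), p = ht$p.value,
          tier = significance_tier(ht$p.value), method = "welch_t")
      } else {
        mw <- mann_whitney_u(ra, rb)
        rows[[length(rows) + 1L]] <- data.frame(
          group_a = pairs[1, j], group_b = pairs[2, j],
          statistic = mw$U, p = mw$p_two_tailed, tier = mw$tier,
          method = paste0("mann_whitney_", mw$method))
      }
    }
    if (length(rows)) tests <- do.call(rbind, rows)
  }
  list(table = tab, tests = tests)
}

#' Write / read an image stack as multi-page TIFF
#'
#' @param stack 3-D array `[row, col, slice]`, 0-255 scale.
#' @param path Output `.tif` path.
#' @return Invisibly, `path`. `read_stack_tiff` returns the 3-D array.
#' @export
write_stack_tiff <- function(stack, path) {
  pages <- lapply(seq_len(dim(stack)[3]), function(s) {
    pmin(pmax(stack[, , s], 0), 255) / 255
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  invisible(path)
}

#' @rdname write_stack_tiff
#' @export
read_stack_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(0, dim = c(dim(pages[[1]])[1], dim(pages[[1]])[2],
                          length(pages)))
  for (s in seq_along(pages)) {
    m <- pages[[s]]
    if (length(dim(m)) == 3) m <- m[, , 1]
    arr[, , s] <- m * 255
  }
  arr
}
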
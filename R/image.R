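#' Labeled 3-D image volume
#'
#' Grayscale voxel array with named binary region-of-interest masks, standing
#' in for a registered post-contrast vessel-wall MRI with wall segmentations
#' ("wall_free_of_IST", "wall_next_to_IST").
#'
#' @param voxels numeric 3-D array (arbitrary intensity units)
#' @param spacing mm per axis, length 3, all > 0
#' @param masks named list of logical arrays, same shape as `voxels`
#' @return object of class `image_volume`
#' @export
image_volume <- function(voxels, spacing = c(1, 1, 1), masks = list()) {
  voxels <- as.array(voxels)
  stop_if_not(length(dim(voxels)) == 3, "voxels must be a 3-D array")
  stop_if_not(length(spacing) == 3 && all(spacing > 0),
              "spacing must be 3 positive values (mm)")
  stop_if_not(all(is.finite(voxels)), "non-finite voxel intensities")
  for (nm in names(masks)) {
    m <- masks[[nm]]
    stop_if_not(identical(dim(m), dim(voxels)),
                "mask '%s' shape differs from voxels", nm)
    masks[[nm]] <- array(as.logical(m), dim(voxels))
  }
  structure(list(voxels = voxels, spacing = as.numeric(spacing),
                 masks = masks),
            class = "image_volume")
}

voxel_volume <- function(img) prod(img$spacing)

get_mask <- function(img, roi) {
  stop_if_not(roi %in% names(img$masks), "ROI '%s' not present", roi)
  m <- img$masks[[roi]]
  stop_if_not(any(m), "ROI '%s' is empty", roi)
  m
}

#' Synthetic textured image volume with analytic first-order truth
#'
#' Patterns emulate wall-enhancement heterogeneity at controllable texture:
#' `constant` (value c), `axis_gradient` (intensity = index along an axis),
#' `checkerboard` (two gray levels, parity of i+j+k: every axis-neighbour pair
#' differs by exactly one level), and `gaussian_random_field` (white noise
#' smoothed by a separable Gaussian kernel of given correlation length, scaled
#' to a target variance). Deterministic given the seed.
#'
#' @param shape integer length-3 array dimensions
#' @param pattern one of "constant", "axis_gradient", "checkerboard",
#'   "gaussian_random_field"
#' @param spacing voxel spacing (mm)
#' @param masks named list of logical arrays, or NULL for a single full-volume
#'   mask named "roi"
#' @param seed RNG seed (used by the random-field pattern)
#' @param value constant value (pattern "constant")
#' @param axis gradient axis 1..3 (pattern "axis_gradient")
#' @param levels two gray values (pattern "checkerboard")
#' @param correlation_length smoothing length, voxels (pattern GRF)
#' @param variance target voxel variance (pattern GRF)
#' @param mean mean intensity offset (pattern GRF)
#' @return list(image = `image_volume`, truth)
#' @export
make_texture_image <- function(shape, pattern = "constant",
                               spacing = c(1, 1, 1), masks = NULL, seed = 1,
                               value = 5, axis = 1, levels = c(1, 2),
                               correlation_length = 2, variance = 1,
                               mean = 0) {
  shape <- as.integer(shape)
  stop_if_not(length(shape) == 3 && all(shape >= 1),
              "shape must be 3 integers >= 1")
  pattern <- match.arg(pattern, c("constant", "axis_gradient", "checkerboard",
                                  "gaussian_random_field"))
  vox <- switch(pattern,
    constant = array(value, shape),
    axis_gradient = {
      idx <- slice.index(array(0, shape), axis)
      array(as.numeric(idx), shape)
    },
    checkerboard = {
      i <- slice.index(array(0, shape), 1)
      j <- slice.index(array(0, shape), 2)
      k <- slice.index(array(0, shape), 3)
      array(levels[1 + (i + j + k) %% 2], shape)
    },
    gaussian_random_field = {
      set.seed(seed)
      z <- array(stats::rnorm(prod(shape)), shape)
      z <- gaussian_smooth3(z, correlation_length)
      s <- stats::sd(as.numeric(z))
      if (s > 0) z <- z / s * sqrt(variance)
      z + mean
    })
  if (is.null(masks)) masks <- list(roi = array(TRUE, shape))
  for (nm in names(masks)) stop_if_not(any(masks[[nm]]), "mask '%s' empty", nm)
  img <- image_volume(vox, spacing, masks)
  truth <- list(generator = "make_texture_image",
                parameters = list(shape = shape, pattern = pattern,
                                  spacing = spacing, seed = seed),
                first_order = NULL)
  if (pattern == "constant") {
    nvox <- vapply(masks, sum, numeric(1))
    truth$first_order <- lapply(nvox, function(n)
      list(Mean = value, Minimum = value, RMS = abs(value),
           Energy = n * value^2,
           `Total Energy` = prod(spacing) * n * value^2))
  }
  list(image = img, truth = truth)
}

# separable truncated-Gaussian smoothing; reflective padding
gaussian_smooth3 <- function(a, sigma) {
  if (sigma <= 0) return(a)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- exp(-(-r:r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  smooth_axis <- function(a, axis) {
    d <- dim(a)
    perm <- c(axis, setdiff(1:3, axis))
    ap <- aperm(a, perm)
    m <- matrix(ap, d[axis])
    n <- nrow(m)
    idx <- outer(seq_len(n), -r:r, "+")
    if (n > 1) {                      # reflect into [1, n], any overshoot
      j <- (idx - 1) %% (2 * n - 2)
      j[j >= n] <- 2 * n - 2 - j[j >= n]
      idx <- j + 1
    } else idx[] <- 1L
    out <- matrix(0, n, ncol(m))
    for (t in seq_along(k)) out <- out + k[t] * m[idx[, t], , drop = FALSE]
    aperm(array(out, d[perm]), order(perm))
  }
  for (ax in 1:3) if (dim(a)[ax] > 1) a <- smooth_axis(a, ax)
  a
}
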
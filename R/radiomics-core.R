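#' Gray-level discretization of a masked image region
#'
#' Texture matrices operate on discretized gray levels 1..Ng. Two policies:
#' `fixed_bin_count` assigns level = min(Ng, 1 + floor(Ng (x - min)/(max -
#' min))) (a constant region maps to level 1, effective level count 1);
#' `fixed_bin_width` assigns level = 1 + floor((x - min)/w).
#'
#' @param image `image_volume`
#' @param roi mask name
#' @param policy "fixed_bin_count" (default) or "fixed_bin_width"
#' @param n_bins bin count Ng (fixed_bin_count; default 32)
#' @param bin_width bin width w (fixed_bin_width)
#' @return object of class `discretized_roi`: `levels` (integer array, NA
#'   outside the ROI), `ng` (max usable level), `ng_effective`, `spacing`,
#'   `voxel_volume`, `roi`, `policy`
#' @export
discretize <- function(image, roi = "roi", policy = "fixed_bin_count",
                       n_bins = 32, bin_width = NULL) {
  policy <- match.arg(policy, c("fixed_bin_count", "fixed_bin_width"))
  mask <- get_mask(image, roi)
  x <- image$voxels[mask]
  lo <- min(x); hi <- max(x)
  if (policy == "fixed_bin_count") {
    stop_if_not(n_bins >= 1, "n_bins must be >= 1")
    lev <- if (hi > lo)
      pmin(n_bins, 1L + as.integer(floor(n_bins * (x - lo) / (hi - lo))))
    else rep(1L, length(x))
    ng <- n_bins
  } else {
    stop_if_not(!is.null(bin_width) && bin_width > 0,
                "bin_width must be positive")
    lev <- 1L + as.integer(floor((x - lo) / bin_width))
    ng <- max(lev)
  }
  levels <- array(NA_integer_, dim(image$voxels))
  levels[mask] <- lev
  structure(list(levels = levels, ng = max(lev), ng_effective = length(unique(lev)),
                 spacing = image$spacing, voxel_volume = voxel_volume(image),
                 roi = roi,
                 policy = list(name = policy, n_bins = n_bins,
                               bin_width = bin_width, min = lo, max = hi)),
            class = "discretized_roi")
}

#' First-order intensity features
#'
#' Mean, Minimum, RMS, Energy and Total Energy of the raw (undiscretized)
#' in-mask intensities. Energy = sum((x + c)^2); Total Energy multiplies by the
#' voxel volume. The intensity shift c defaults to 0.
#'
#' @param image `image_volume`
#' @param roi mask name
#' @param shift intensity shift c added before squaring (default 0)
#' @return named list: Mean, Minimum, RMS, Energy, `Total Energy`
#' @export
first_order <- function(image, roi = "roi", shift = 0) {
  x <- image$voxels[get_mask(image, roi)] + shift
  energy <- sum(x^2)
  list(Mean = mean(x), Minimum = min(x), RMS = sqrt(mean(x^2)),
       Energy = energy, `Total Energy` = voxel_volume(image) * energy)
}

# the 13 unique 3-D offsets at Chebyshev distance 1 (positive lexicographic
# half of the 26-neighbourhood)
unique_offsets_3d <- function() {
  o <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  keep <- o[, 3] > 0 | (o[, 3] == 0 & o[, 2] > 0) |
    (o[, 3] == 0 & o[, 2] == 0 & o[, 1] > 0)
  unname(o[keep, , drop = FALSE])
}

# index range along one axis such that both v and v + dd stay in-grid
axis_range <- function(n, dd) {
  lo <- max(1, 1 - dd); hi <- min(n, n - dd)
  if (lo > hi) integer(0) else lo:hi
}

# aligned voxel pairs (a = level at v, b = level at v + offset), both in-grid;
# returns the two level vectors with NA where out of mask
offset_pairs <- function(levels, off) {
  d <- dim(levels)
  xs <- axis_range(d[1], off[1]); ys <- axis_range(d[2], off[2])
  zs <- axis_range(d[3], off[3])
  if (!length(xs) || !length(ys) || !length(zs))
    return(list(a = integer(0), b = integer(0)))
  a <- levels[xs, ys, zs, drop = FALSE]
  b <- levels[xs + off[1], ys + off[2], zs + off[3], drop = FALSE]
  list(a = as.integer(a), b = as.integer(b))
}
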
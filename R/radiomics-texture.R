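#' Gray-level co-occurrence features
#'
#' Co-occurrence is counted for the 13 unique 3-D offsets at Chebyshev
#' distance 1, symmetrized and normalized per offset; each feature is computed
#' per offset and then averaged over offsets with at least one pair. A
#' single-voxel ROI yields no pairs: all features are defined 0 and flagged.
#'
#' @param disc `discretized_roi`
#' @return named list: Contrast, ClusterProminence, ClusterShade,
#'   DifferenceAverage, DifferenceVariance, and `flagged` (TRUE when no voxel
#'   pairs exist)
#' @export
glcm_features <- function(disc) {
  ng <- disc$ng
  offs <- unique_offsets_3d()
  acc <- list(Contrast = c(), ClusterProminence = c(), ClusterShade = c(),
              DifferenceAverage = c(), DifferenceVariance = c())
  for (r in seq_len(nrow(offs))) {
    pr <- offset_pairs(disc$levels, offs[r, ])
    ok <- !is.na(pr$a) & !is.na(pr$b)
    if (!any(ok)) next
    cnt <- matrix(tabulate((pr$a[ok] - 1L) * ng + pr$b[ok], nbins = ng * ng),
                  ng, ng, byrow = TRUE)
    P <- cnt + t(cnt)                       # symmetrize
    p <- P / sum(P)
    i <- row(p); j <- col(p)
    mux <- sum(i * p); muy <- sum(j * p)
    k <- 0:(ng - 1)
    pxy <- vapply(k, function(kk) sum(p[abs(i - j) == kk]), numeric(1))
    da <- sum(k * pxy)
    acc$Contrast <- c(acc$Contrast, sum((i - j)^2 * p))
    acc$ClusterShade <- c(acc$ClusterShade, sum((i + j - mux - muy)^3 * p))
    acc$ClusterProminence <- c(acc$ClusterProminence,
                               sum((i + j - mux - muy)^4 * p))
    acc$DifferenceAverage <- c(acc$DifferenceAverage, da)
    acc$DifferenceVariance <- c(acc$DifferenceVariance,
                                sum((k - da)^2 * pxy))
  }
  if (!length(acc$Contrast))
    return(list(Contrast = 0, ClusterProminence = 0, ClusterShade = 0,
                DifferenceAverage = 0, DifferenceVariance = 0, flagged = TRUE))
  out <- lapply(acc, mean)
  out$flagged <- FALSE
  out
}

# enumerate maximal runs of equal level along one direction; returns a
# two-column matrix (level, run length)
enumerate_runs <- function(levels, off) {
  d <- dim(levels)
  grid <- which(!is.na(levels), arr.ind = TRUE)
  if (nrow(grid) == 0) return(matrix(0L, 0, 2))
  q <- sum(off^2)
  s <- grid %*% off                                   # step parameter (x q)
  key <- paste(grid[, 1] * q - s * off[1],
               grid[, 2] * q - s * off[2],
               grid[, 3] * q - s * off[3])
  lev <- levels[grid]
  o <- order(key, s)
  key <- key[o]; s <- s[o]; lev <- lev[o]
  n <- length(s)
  if (n == 1) return(cbind(lev, 1L))
  newrun <- c(TRUE, key[-1] != key[-n] | (s[-1] - s[-n]) != q |
                lev[-1] != lev[-n])
  rid <- cumsum(newrun)
  len <- tabulate(rid)
  cbind(lev[newrun], len)
}

#' Gray-level run-length features
#'
#' Run matrices P(i, j) (level i, run length j) are built for each of the 13
#' unique directions from maximal runs of equal level, interrupted by the mask;
#' features are computed per direction and averaged.
#'
#' @param disc `discretized_roi`
#' @return named list: GLN, RLN, HGLRE, SRHGLE, LRHGLE
#' @export
glrlm_features <- function(disc) {
  offs <- unique_offsets_3d()
  acc <- NULL
  for (r in seq_len(nrow(offs))) {
    runs <- enumerate_runs(disc$levels, offs[r, ])
    if (nrow(runs) == 0) next
    nr <- nrow(runs)
    i <- runs[, 1]; j <- runs[, 2]
    gl_tot <- tapply(rep(1, nr), i, sum)             # sum_j P(i, .)
    rl_tot <- tapply(rep(1, nr), j, sum)             # sum_i P(., j)
    f <- c(GLN = sum(gl_tot^2) / nr,
           RLN = sum(rl_tot^2) / nr,
           HGLRE = sum(i^2) / nr,
           SRHGLE = sum(i^2 / j^2) / nr,
           LRHGLE = sum(i^2 * j^2) / nr)
    acc <- rbind(acc, f)
  }
  stop_if_not(!is.null(acc), "empty ROI: no runs in any direction")
  as.list(colMeans(acc))
}

# 26-connected zones of equal gray level; returns matrix (level, zone size)
enumerate_zones <- function(levels) {
  idx <- which(!is.na(levels))
  if (!length(idx)) return(matrix(0L, 0, 2))
  remap <- integer(length(levels))
  remap[idx] <- seq_along(idx)
  edges <- NULL
  offs <- unique_offsets_3d()
  d <- dim(levels)
  for (r in seq_len(nrow(offs))) {
    off <- offs[r, ]
    xs <- axis_range(d[1], off[1]); ys <- axis_range(d[2], off[2])
    zs <- axis_range(d[3], off[3])
    if (!length(xs) || !length(ys) || !length(zs)) next
    lin <- array(seq_along(levels), d)
    a <- as.integer(lin[xs, ys, zs])
    b <- as.integer(lin[xs + off[1], ys + off[2], zs + off[3]])
    ok <- !is.na(levels[a]) & !is.na(levels[b]) & levels[a] == levels[b]
    if (any(ok)) edges <- rbind(edges, cbind(remap[a[ok]], remap[b[ok]]))
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (!is.null(edges)) g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)
  lev_of_zone <- levels[idx][match(seq_len(comp$no), comp$membership)]
  cbind(lev_of_zone, comp$csize)
}

#' Gray-level size-zone features
#'
#' Zones are 26-connected components of equal level; P(i, j) counts zones of
#' level i and size j.
#'
#' @param disc `discretized_roi`
#' @return named list: SZN, GLN, GLV, HGLZE, SAHGLE
#' @export
glszm_features <- function(disc) {
  z <- enumerate_zones(disc$levels)
  stop_if_not(nrow(z) > 0, "empty ROI: no zones")
  nz <- nrow(z)
  i <- z[, 1]; j <- z[, 2]
  sz_tot <- tapply(rep(1, nz), j, sum)
  gl_tot <- tapply(rep(1, nz), i, sum)
  mu <- mean(i)                                      # sum p(i,j) * i
  list(SZN = sum(sz_tot^2) / nz,
       GLN = sum(gl_tot^2) / nz,
       GLV = mean((i - mu)^2),
       HGLZE = sum(i^2) / nz,
       SAHGLE = sum(i^2 / j^2) / nz)
}

# per-voxel count of 26-neighbours in mask satisfying |level diff| <= alpha,
# plus neighbourhood level sums/counts (for NGTDM)
neighbour_stats <- function(levels, alpha = 0) {
  d <- dim(levels)
  lin <- array(seq_along(levels), d)
  dep <- array(0L, d)
  nsum <- array(0, d)
  ncnt <- array(0L, d)
  offs <- unique_offsets_3d()
  offs <- rbind(offs, -offs)                         # all 26
  for (r in seq_len(nrow(offs))) {
    off <- offs[r, ]
    xs <- axis_range(d[1], off[1]); ys <- axis_range(d[2], off[2])
    zs <- axis_range(d[3], off[3])
    if (!length(xs) || !length(ys) || !length(zs)) next
    a <- as.integer(lin[xs, ys, zs])
    b <- as.integer(lin[xs + off[1], ys + off[2], zs + off[3]])
    ok <- !is.na(levels[a]) & !is.na(levels[b])
    aa <- a[ok]; bb <- b[ok]
    dep[aa] <- dep[aa] + as.integer(abs(levels[aa] - levels[bb]) <= alpha)
    nsum[aa] <- nsum[aa] + levels[bb]
    ncnt[aa] <- ncnt[aa] + 1L
  }
  list(dependence = dep, nbr_sum = nsum, nbr_count = ncnt)
}

#' Gray-level dependence features
#'
#' For each in-mask voxel the dependence j = 1 + number of in-mask
#' 26-neighbours whose level differs by at most `alpha`; P(i, j) counts voxels
#' of level i with dependence j.
#'
#' @param disc `discretized_roi`
#' @param alpha dependence tolerance (default 0)
#' @return named list: DN, DNN, GLN, HGLE, SDHGLE
#' @export
gldm_features <- function(disc, alpha = 0) {
  ns <- neighbour_stats(disc$levels, alpha)
  inm <- !is.na(disc$levels)
  i <- disc$levels[inm]
  j <- 1L + ns$dependence[inm]
  n <- length(i)
  dep_tot <- tapply(rep(1, n), j, sum)
  gl_tot <- tapply(rep(1, n), i, sum)
  dn <- sum(dep_tot^2) / n
  list(DN = dn, DNN = dn / n,
       GLN = sum(gl_tot^2) / n,
       HGLE = sum(as.numeric(i)^2) / n,
       SDHGLE = sum(as.numeric(i)^2 / as.numeric(j)^2) / n)
}

#' Neighbourhood gray-tone difference features
#'
#' For level i, n_i counts in-mask voxels of level i having at least one
#' in-mask 26-neighbour, p_i = n_i / Nvp, and s_i sums |i - mean neighbourhood
#' level| over those voxels. Degenerate denominators take documented
#' sentinels: Coarseness 1e6 when sum(p_i s_i) = 0; Strength 0 when
#' sum(s_i) = 0.
#'
#' @param disc `discretized_roi`
#' @return named list: Coarseness, Complexity, Strength
#' @export
ngtdm_features <- function(disc) {
  ns <- neighbour_stats(disc$levels)
  valid <- !is.na(disc$levels) & ns$nbr_count > 0
  i <- disc$levels[valid]
  nbar <- ns$nbr_sum[valid] / ns$nbr_count[valid]
  ng <- disc$ng
  n_i <- tabulate(i, nbins = ng)
  s_i <- numeric(ng)
  agg <- tapply(abs(i - nbar), i, sum)
  s_i[as.integer(names(agg))] <- as.numeric(agg)
  nvp <- sum(n_i)
  stop_if_not(nvp > 0, "no voxels with a valid neighbourhood")
  p_i <- n_i / nvp
  present <- which(p_i > 0)
  coarse_den <- sum(p_i * s_i)
  coarseness <- if (coarse_den > 0) min(1 / coarse_den, 1e6) else 1e6
  complexity <- 0; strength <- 0
  for (a in present) for (b in present) {
    complexity <- complexity +
      abs(a - b) * (p_i[a] * s_i[a] + p_i[b] * s_i[b]) / (p_i[a] + p_i[b])
    strength <- strength + (p_i[a] + p_i[b]) * (a - b)^2
  }
  complexity <- complexity / nvp
  s_tot <- sum(s_i)
  strength <- if (s_tot > 0) strength / s_tot else 0
  list(Coarseness = coarseness, Complexity = complexity, Strength = strength)
}

#' Extract the full supported radiomic feature vector
#'
#' One named vector per ROI, covering the first-order and texture features the
#' package supports, using the field's published short names (e.g. `GLDM.DN`,
#' `GLRLM.GLN`, `NGTDM.Complexity`, `Total Energy`). Metadata records the
#' discretization and aggregation policy.
#'
#' @param image `image_volume`
#' @param rois mask names (default the two wall ROIs)
#' @param policy,n_bins,bin_width passed to [discretize()]
#' @param alpha GLDM dependence tolerance
#' @param shift first-order intensity shift c
#' @return list with one named numeric vector per ROI plus `meta`
#' @export
extract_feature_vector <- function(image,
                                   rois = c("wall_free_of_IST",
                                            "wall_next_to_IST"),
                                   policy = "fixed_bin_count", n_bins = 32,
                                   bin_width = NULL, alpha = 0, shift = 0) {
  for (roi in rois)
    stop_if_not(roi %in% names(image$masks), "missing ROI '%s'", roi)
  out <- list()
  for (roi in rois) {
    fo <- first_order(image, roi, shift = shift)
    disc <- discretize(image, roi, policy = policy, n_bins = n_bins,
                       bin_width = bin_width)
    glcm <- glcm_features(disc)
    glrlm <- glrlm_features(disc)
    glszm <- glszm_features(disc)
    gldm <- gldm_features(disc, alpha = alpha)
    ngtdm <- ngtdm_features(disc)
    v <- c(Mean = fo$Mean, Minimum = fo$Minimum, RMS = fo$RMS,
           Energy = fo$Energy, `Total Energy` = fo$`Total Energy`,
           Contrast = glcm$Contrast, CP = glcm$ClusterProminence,
           CS = glcm$ClusterShade, GLCM.DA = glcm$DifferenceAverage,
           GLCM.DV = glcm$DifferenceVariance,
           GLRLM.GLN = glrlm$GLN, GLRLM.RLN = glrlm$RLN,
           GLRLM.HGLRE = glrlm$HGLRE, GLRLM.SRHGLE = glrlm$SRHGLE,
           GLRLM.LRHGLE = glrlm$LRHGLE,
           GLSZM.SZN = glszm$SZN, GLSZM.GLN = glszm$GLN,
           GLSZM.GLV = glszm$GLV, GLSZM.HGLZE = glszm$HGLZE,
           GLSZM.SAHGLE = glszm$SAHGLE,
           GLDM.DN = gldm$DN, GLDM.DNN = gldm$DNN, GLDM.GLN = gldm$GLN,
           GLDM.HGLE = gldm$HGLE, GLDM.SDHGLE = gldm$SDHGLE,
           NGTDM.Coarseness = ngtdm$Coarseness,
           NGTDM.Complexity = ngtdm$Complexity,
           NGTDM.Strength = ngtdm$Strength)
    out[[roi]] <- v
  }
  out$meta <- list(policy = policy, n_bins = n_bins, bin_width = bin_width,
                   alpha = alpha, shift = shift,
                   aggregation = "average over 13 unique directions")
  out
}
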
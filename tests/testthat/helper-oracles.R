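# Independent brute-force oracles. Deliberately written as plain nested loops
# over voxels/cells, sharing no code with the package's vectorized paths.

offsets13 <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
offsets13 <- offsets13[offsets13[, 3] > 0 |
                         (offsets13[, 3] == 0 & offsets13[, 2] > 0) |
                         (offsets13[, 3] == 0 & offsets13[, 2] == 0 &
                            offsets13[, 1] > 0), , drop = FALSE]
offsets26 <- rbind(offsets13, -offsets13)

in_grid <- function(v, d) all(v >= 1) && all(v <= d)

# ---- GLCM oracle ----------------------------------------------------------
oracle_glcm <- function(levels, ng) {
  d <- dim(levels)
  feats <- NULL
  for (r in seq_len(nrow(offsets13))) {
    off <- offsets13[r, ]
    P <- matrix(0, ng, ng)
    for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
      a <- levels[x, y, z]
      if (is.na(a)) next
      for (sgn in c(1, -1)) {
        v <- c(x, y, z) + sgn * off
        if (!in_grid(v, d)) next
        b <- levels[v[1], v[2], v[3]]
        if (is.na(b)) next
        P[a, b] <- P[a, b] + 1
      }
    }
    if (sum(P) == 0) next
    p <- P / sum(P)
    mux <- 0; muy <- 0
    for (i in 1:ng) for (j in 1:ng) { mux <- mux + i * p[i, j]
                                      muy <- muy + j * p[i, j] }
    contrast <- cs <- cp <- 0
    pxy <- numeric(ng)
    for (i in 1:ng) for (j in 1:ng) {
      contrast <- contrast + (i - j)^2 * p[i, j]
      cs <- cs + (i + j - mux - muy)^3 * p[i, j]
      cp <- cp + (i + j - mux - muy)^4 * p[i, j]
      pxy[abs(i - j) + 1] <- pxy[abs(i - j) + 1] + p[i, j]
    }
    da <- sum((0:(ng - 1)) * pxy)
    dv <- sum(((0:(ng - 1)) - da)^2 * pxy)
    feats <- rbind(feats, c(Contrast = contrast, ClusterProminence = cp,
                            ClusterShade = cs, DifferenceAverage = da,
                            DifferenceVariance = dv))
  }
  as.list(colMeans(feats))
}

# ---- GLRLM oracle ---------------------------------------------------------
oracle_glrlm <- function(levels) {
  d <- dim(levels)
  feats <- NULL
  for (r in seq_len(nrow(offsets13))) {
    off <- offsets13[r, ]
    runs_i <- integer(0); runs_j <- integer(0)
    for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
      a <- levels[x, y, z]
      if (is.na(a)) next
      prev <- c(x, y, z) - off
      if (in_grid(prev, d)) {
        pl <- levels[prev[1], prev[2], prev[3]]
        if (!is.na(pl) && pl == a) next      # not a run start
      }
      len <- 0L
      v <- c(x, y, z)
      while (in_grid(v, d) && !is.na(levels[v[1], v[2], v[3]]) &&
             levels[v[1], v[2], v[3]] == a) {
        len <- len + 1L
        v <- v + off
      }
      runs_i <- c(runs_i, a); runs_j <- c(runs_j, len)
    }
    nr <- length(runs_i)
    if (nr == 0) next
    gln <- sum(table(runs_i)^2) / nr
    rln <- sum(table(runs_j)^2) / nr
    feats <- rbind(feats, c(GLN = gln, RLN = rln,
                            HGLRE = sum(runs_i^2) / nr,
                            SRHGLE = sum(runs_i^2 / runs_j^2) / nr,
                            LRHGLE = sum(runs_i^2 * runs_j^2) / nr))
  }
  as.list(colMeans(feats))
}

# ---- GLSZM oracle (stack-based flood fill, 26-connectivity) ---------------
oracle_glszm <- function(levels) {
  d <- dim(levels)
  visited <- array(FALSE, d)
  zi <- integer(0); zj <- integer(0)
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    if (is.na(levels[x, y, z]) || visited[x, y, z]) next
    lev <- levels[x, y, z]
    stack <- list(c(x, y, z))
    visited[x, y, z] <- TRUE
    size <- 0L
    while (length(stack)) {
      v <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      size <- size + 1L
      for (r in seq_len(nrow(offsets26))) {
        w <- v + offsets26[r, ]
        if (!in_grid(w, d)) next
        if (visited[w[1], w[2], w[3]]) next
        lw <- levels[w[1], w[2], w[3]]
        if (is.na(lw) || lw != lev) next
        visited[w[1], w[2], w[3]] <- TRUE
        stack[[length(stack) + 1L]] <- w
      }
    }
    zi <- c(zi, lev); zj <- c(zj, size)
  }
  nz <- length(zi)
  mu <- mean(zi)
  list(SZN = sum(table(zj)^2) / nz, GLN = sum(table(zi)^2) / nz,
       GLV = mean((zi - mu)^2), HGLZE = sum(zi^2) / nz,
       SAHGLE = sum(zi^2 / zj^2) / nz)
}

# ---- GLDM oracle ----------------------------------------------------------
oracle_gldm <- function(levels, alpha = 0) {
  d <- dim(levels)
  vi <- integer(0); vj <- integer(0)
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    a <- levels[x, y, z]
    if (is.na(a)) next
    dep <- 1L
    for (r in seq_len(nrow(offsets26))) {
      w <- c(x, y, z) + offsets26[r, ]
      if (!in_grid(w, d)) next
      b <- levels[w[1], w[2], w[3]]
      if (!is.na(b) && abs(a - b) <= alpha) dep <- dep + 1L
    }
    vi <- c(vi, a); vj <- c(vj, dep)
  }
  n <- length(vi)
  dn <- sum(table(vj)^2) / n
  list(DN = dn, DNN = dn / n, GLN = sum(table(vi)^2) / n,
       HGLE = sum(vi^2) / n, SDHGLE = sum(vi^2 / vj^2) / n)
}

# ---- NGTDM oracle ---------------------------------------------------------
oracle_ngtdm <- function(levels, ng) {
  d <- dim(levels)
  lev <- integer(0); diffs <- numeric(0)
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    a <- levels[x, y, z]
    if (is.na(a)) next
    nb <- numeric(0)
    for (r in seq_len(nrow(offsets26))) {
      w <- c(x, y, z) + offsets26[r, ]
      if (!in_grid(w, d)) next
      b <- levels[w[1], w[2], w[3]]
      if (!is.na(b)) nb <- c(nb, b)
    }
    if (length(nb) == 0) next
    lev <- c(lev, a)
    diffs <- c(diffs, abs(a - mean(nb)))
  }
  nvp <- length(lev)
  n_i <- s_i <- numeric(ng)
  for (t in seq_along(lev)) {
    n_i[lev[t]] <- n_i[lev[t]] + 1
    s_i[lev[t]] <- s_i[lev[t]] + diffs[t]
  }
  p_i <- n_i / nvp
  den <- sum(p_i * s_i)
  coarse <- if (den > 0) min(1 / den, 1e6) else 1e6
  cx <- 0; st <- 0
  for (a in which(p_i > 0)) for (b in which(p_i > 0)) {
    cx <- cx + abs(a - b) * (p_i[a] * s_i[a] + p_i[b] * s_i[b]) /
      (p_i[a] + p_i[b])
    st <- st + (p_i[a] + p_i[b]) * (a - b)^2
  }
  list(Coarseness = coarse, Complexity = cx / nvp,
       Strength = if (sum(s_i) > 0) st / sum(s_i) else 0)
}

# ---- brute-force Q per cell (solve-based, separate from adjugate path) ----
oracle_q_mask <- function(mesh, velocity, threshold = 0) {
  m <- nrow(mesh$tets)
  out <- logical(m)
  for (c in seq_len(m)) {
    v <- mesh$tets[c, ]
    D <- cbind(mesh$points[v[2], ] - mesh$points[v[1], ],
               mesh$points[v[3], ] - mesh$points[v[1], ],
               mesh$points[v[4], ] - mesh$points[v[1], ])
    U <- cbind(velocity[v[2], ] - velocity[v[1], ],
               velocity[v[3], ] - velocity[v[1], ],
               velocity[v[4], ] - velocity[v[1], ])
    A <- U %*% solve(D)
    S <- (A + t(A)) / 2
    W <- (A - t(A)) / 2
    out[c] <- (sum(W^2) - sum(S^2)) / 2 > threshold
  }
  out
}

# random masked test image: values on a small grid, random mask
random_test_roi <- function(shape, ng, seed, mask_frac = 0.8) {
  set.seed(seed)
  vox <- array(stats::runif(prod(shape), 0, 10), shape)
  mask <- array(stats::runif(prod(shape)) < mask_frac, shape)
  if (!any(mask)) mask[1] <- TRUE
  img <- image_volume(vox, c(1, 1, 1), list(roi = mask))
  discretize(img, "roi", n_bins = ng)
}

# Fisher-z 95% CI for a Spearman rho estimate at sample size n
fisher_ci <- function(rho_hat, n) {
  z <- atanh(rho_hat)
  se <- 1 / sqrt(n - 3)
  tanh(c(z - 1.96 * se, z + 1.96 * se))
}
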
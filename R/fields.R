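#' Time-resolved vector field on a fixed mesh
#'
#' Per-point 3-vectors over P phases of one cardiac cycle. WSS fields live on a
#' `surface_mesh` (Pa); velocity fields on a `volume_mesh` (m/s). The
#' convention follows transient CFD post-processing: P phases equally sampled
#' from the last simulated cycle (default P = 20 over T = 1 s).
#'
#' @param mesh `surface_mesh` or `volume_mesh`
#' @param values numeric array n_points x 3 x P
#' @param phase_times strictly increasing times (s), `phase_times[1] >= 0` and
#'   `phase_times[P] < period`
#' @param period cycle duration T (s)
#' @param units unit string ("Pa" or "m/s")
#' @return object of class `field_series`
#' @export
field_series <- function(mesh, values, phase_times = NULL, period = 1,
                         units = "Pa") {
  stop_if_not(inherits(mesh, "surface_mesh") || inherits(mesh, "volume_mesh"),
              "mesh must be a surface_mesh or volume_mesh")
  values <- as.array(values)
  stop_if_not(length(dim(values)) == 3 && dim(values)[2] == 3,
              "values must be n x 3 x P")
  stop_if_not(dim(values)[1] == nrow(mesh$points),
              "values rows must match mesh points")
  p <- dim(values)[3]
  stop_if_not(p >= 2, "need at least 2 phases")
  if (is.null(phase_times)) phase_times <- period * (seq_len(p) - 1) / p
  stop_if_not(length(phase_times) == p, "phase_times length must equal P")
  stop_if_not(all(diff(phase_times) > 0), "phase_times must be increasing")
  stop_if_not(phase_times[1] >= 0 && phase_times[p] < period,
              "phase_times must lie in [0, period)")
  stop_if_not(all(is.finite(values)), "non-finite field values")
  structure(list(mesh = mesh, values = values, phase_times = phase_times,
                 period = period, units = units),
            class = "field_series")
}

#' @export
print.field_series <- function(x, ...) {
  cat(sprintf("<field_series> %d points x %d phases [%s], T = %g s\n",
              dim(x$values)[1], dim(x$values)[3], x$units, x$period))
  invisible(x)
}

n_phases <- function(field) dim(field$values)[3]

#' Synthetic pulsatile WSS series with planted OSI/TAWSS
#'
#' Within each region every point shares a fixed unit direction d and a
#' positive magnitude waveform m(t); a fraction f of the P phases carries the
#' reversed vector -m(t) d. For constant m this gives the closed forms
#' OSI = (1 - |1 - 2 f|)/2 and TAWSS = mean m(t), which the WSS module must
#' recover exactly. Requested f is rounded to k/P (k = round(P f)); the truth
#' records the achieved fraction.
#'
#' @param mesh `surface_mesh`
#' @param regions integer/factor of length n_points assigning each point to a
#'   region (default: single region)
#' @param magnitude waveform: a single positive number (constant, Pa), a
#'   numeric vector of length P, or a function of time returning Pa
#' @param reversal_fraction f per region, each in [0, 0.5]
#' @param phases number of phases P (paper convention 20)
#' @param period cycle duration (s)
#' @param seed RNG seed (used only to draw the per-region directions)
#' @return list(field = `field_series`, truth = list with per-region
#'   direction, achieved f, planted OSI and TAWSS, per-point maps)
#' @export
make_pulsatile_wss_series <- function(mesh, regions = NULL, magnitude = 2,
                                      reversal_fraction = 0, phases = 20,
                                      period = 1, seed = 1) {
  stop_if_not(inherits(mesh, "surface_mesh"), "mesh must be a surface_mesh")
  stop_if_not(phases >= 2, "need at least 2 phases")
  n <- nrow(mesh$points)
  if (is.null(regions)) regions <- rep(1L, n)
  stop_if_not(length(regions) == n, "regions must have one entry per point")
  regions <- as.integer(factor(regions))
  nr <- max(regions)
  f <- rep_len(reversal_fraction, nr)
  stop_if_not(all(f >= 0 & f <= 0.5), "reversal fractions must be in [0, 0.5]")

  tt <- period * (seq_len(phases) - 1) / phases
  m <- if (is.function(magnitude)) magnitude(tt)
       else rep_len(magnitude, phases)
  stop_if_not(all(is.finite(m) & m > 0), "magnitudes must be positive finite")

  set.seed(seed)
  dirs <- matrix(stats::rnorm(3 * nr), nr, 3)
  dirs <- dirs / vec_norm(dirs)

  values <- array(0, c(n, 3, phases))
  f_actual <- osi_true <- tawss_true <- numeric(nr)
  signs_by_region <- vector("list", nr)
  for (r in seq_len(nr)) {
    k <- round(phases * f[r])
    f_actual[r] <- k / phases
    s <- rep(1, phases)
    if (k > 0) s[seq_len(k)] <- -1    # reverse the first k phases
    signs_by_region[[r]] <- s
    tawss_true[r] <- mean(m)
    osi_true[r] <- 0.5 * (1 - abs(sum(s * m)) / sum(m))
    pts <- which(regions == r)
    for (p in seq_len(phases))
      values[pts, , p] <- rep(s[p] * m[p] * dirs[r, ], each = length(pts))
  }
  field <- field_series(mesh, values, phase_times = tt, period = period,
                        units = "Pa")
  truth <- list(generator = "make_pulsatile_wss_series",
                parameters = list(reversal_fraction = f, phases = phases,
                                  period = period, seed = seed),
                regions = regions, directions = dirs,
                f_actual = f_actual, signs = signs_by_region,
                osi = osi_true, tawss = tawss_true,
                osi_map = osi_true[regions], tawss_map = tawss_true[regions])
  list(field = field, truth = truth)
}

#' Synthetic swirling-velocity series with known vortex blobs
#'
#' Superposition of Gaussian-enveloped rigid rotations,
#' u_k(x, t) = omega_k (a_k x (x - c_k(t))) exp(-|x - c_k(t)|^2 / (2 sigma_k^2)),
#' emulating recirculation zones that shift, break and merge over a cardiac
#' cycle. The truth records each blob's centre path and sigma so expected core
#' locations/counts are known; phases where two blob supports (3 sigma)
#' intersect are flagged since the expected core count is then ambiguous.
#'
#' The truth also records a `suggested_q_threshold`: the exact Q > 0 region of
#' a Gaussian-enveloped rotation includes weak toroidal side lobes (amplitude
#' below about 1 percent of the core peak Q = omega^2), so core-count ground
#' truth is stated at threshold 0.01 * min(omega^2), which separates cores
#' from lobes by two orders of magnitude on either side.
#'
#' @param mesh `volume_mesh`
#' @param blobs list of specs: each `list(center = length-3 vector or P x 3
#'   matrix or function(t), sigma = mm, omega = rad/s scalar or length-P
#'   vector (0 switches the blob off at that phase), axis = length-3)`
#' @param phases number of phases P
#' @param period cycle duration (s)
#' @return list(field = `field_series` (m/s at mesh points), truth)
#' @export
make_vortex_velocity_series <- function(mesh, blobs, phases = 20, period = 1) {
  stop_if_not(inherits(mesh, "volume_mesh"), "mesh must be a volume_mesh")
  stop_if_not(length(blobs) >= 1, "need at least one blob")
  tt <- period * (seq_len(phases) - 1) / phases
  n <- nrow(mesh$points)
  nb <- length(blobs)
  centers <- array(0, c(nb, 3, phases))
  sig <- numeric(nb)
  omg <- matrix(0, nb, phases)
  axes <- matrix(0, nb, 3)
  for (b in seq_len(nb)) {
    sp <- blobs[[b]]
    stop_if_not(is.numeric(sp$sigma) && sp$sigma > 0, "sigma must be > 0")
    sig[b] <- sp$sigma
    omg[b, ] <- rep_len(if (is.null(sp$omega)) 1 else sp$omega, phases)
    axes[b, ] <- normalize(if (is.null(sp$axis)) c(0, 0, 1) else sp$axis)
    cen <- sp$center
    if (is.function(cen)) cen <- t(vapply(tt, cen, numeric(3)))
    if (is.null(dim(cen))) cen <- matrix(cen, phases, 3, byrow = TRUE)
    stop_if_not(nrow(cen) == phases && ncol(cen) == 3,
                "blob center path must be P x 3")
    centers[b, , ] <- t(cen)
  }
  values <- array(0, c(n, 3, phases))
  for (p in seq_len(phases)) {
    up <- matrix(0, n, 3)
    for (b in seq_len(nb)) {
      if (omg[b, p] == 0) next
      d <- sweep(mesh$points, 2, centers[b, , p])
      env <- exp(-rowSums(d * d) / (2 * sig[b]^2))
      rot <- row_cross(matrix(axes[b, ], n, 3, byrow = TRUE), d)
      up <- up + omg[b, p] * rot * env
    }
    values[, , p] <- up
  }
  overlap_flag <- logical(phases)
  if (nb > 1) {
    for (p in seq_len(phases)) {
      act <- which(omg[, p] != 0)
      if (length(act) < 2) next
      for (b1 in act[-length(act)]) for (b2 in act[act > b1]) {
        d <- sqrt(sum((centers[b1, , p] - centers[b2, , p])^2))
        if (d < 3 * (sig[b1] + sig[b2])) overlap_flag[p] <- TRUE
      }
    }
  }
  field <- field_series(mesh, values, phase_times = tt, period = period,
                        units = "m/s")
  active <- omg != 0
  truth <- list(generator = "make_vortex_velocity_series",
                parameters = list(phases = phases, period = period),
                centers = centers, sigma = sig, omega = omg, axes = axes,
                support_overlap = overlap_flag,
                expected_noc = colSums(active),
                suggested_q_threshold = 0.01 * min(omg[active]^2))
  list(field = field, truth = truth)
}
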
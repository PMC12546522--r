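#' Wall-shear-stress derived wall metrics
#'
#' Per-point metrics from a time-resolved WSS vector field tau(t) on the sac
#' surface, sampled at P phases of one cardiac cycle:
#' \itemize{
#'   \item TAWSS = (1/T) integral |tau| dt — time-averaged WSS magnitude (Pa)
#'   \item OSI = (1 - ||integral tau dt|| / integral |tau| dt) / 2 in [0, 0.5]
#'   \item ECAP = OSI / TAWSS (1/Pa) — endothelial cell activation potential
#'   \item RRT = 1 / ((1 - 2 OSI) TAWSS) (1/Pa) — relative residence time
#' }
#' Integrals are discretised as phase means (rectangle rule), exact for equal
#' sampling of a periodic cycle; a trapezoid option covers non-uniform
#' phase_times. Points where a denominator falls below `eps` (1e-12 Pa) get a
#' non-finite sentinel and are flagged; zero-WSS points get OSI = 0 (no
#' oscillation evidence) and are flagged.
#'
#' @name wss_metrics
NULL

# phase weights: rectangle (equal, exact for uniform periodic sampling) or
# periodic trapezoid for non-uniform phase_times
phase_weights <- function(field, rule = c("rectangle", "trapezoid")) {
  rule <- match.arg(rule)
  p <- n_phases(field)
  if (rule == "rectangle") return(rep(1 / p, p))
  tt <- field$phase_times
  gaps <- diff(c(tt, tt[1] + field$period))      # cyclic gaps
  w <- (gaps + c(gaps[p], gaps[-p])) / 2
  w / field$period
}

#' Time-averaged WSS per point
#'
#' @param field `field_series` on a `surface_mesh`
#' @param rule integration rule, "rectangle" (default) or "trapezoid"
#' @return non-negative numeric vector, Pa
#' @export
time_average_wss <- function(field, rule = "rectangle") {
  stop_if_not(inherits(field$mesh, "surface_mesh"),
              "WSS field must live on a surface mesh")
  bad <- which(!is.finite(field$values), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("non-finite WSS vector at point %d, phase %d",
                 bad[1, 1], bad[1, 3]), call. = FALSE)
  w <- phase_weights(field, rule)
  mags <- apply(field$values, 3, vec_norm)       # n x P
  as.numeric(mags %*% w)
}

#' Oscillatory shear index per point
#'
#' @inheritParams time_average_wss
#' @return list(osi = values in [0, 0.5], flagged = indices of zero-WSS points,
#'   clamped = count of round-off clamps)
#' @export
oscillatory_shear_index <- function(field, rule = "rectangle") {
  stop_if_not(inherits(field$mesh, "surface_mesh"),
              "WSS field must live on a surface mesh")
  w <- phase_weights(field, rule)
  p <- n_phases(field)
  mean_vec <- matrix(0, nrow(field$mesh$points), 3)
  for (k in seq_len(p)) mean_vec <- mean_vec + w[k] * field$values[, , k]
  mean_mag <- as.numeric(apply(field$values, 3, vec_norm) %*% w)
  osi <- rep(0, length(mean_mag))
  ok <- mean_mag > .EPS_PA
  osi[ok] <- 0.5 * (1 - vec_norm(mean_vec[ok, , drop = FALSE]) / mean_mag[ok])
  clamped <- sum(osi < 0 | osi > 0.5)
  osi <- pmin(pmax(osi, 0), 0.5)
  list(osi = osi, flagged = which(!ok), clamped = clamped)
}

#' Endothelial cell activation potential
#'
#' @param osi per-point OSI
#' @param tawss per-point TAWSS (Pa)
#' @param eps singularity guard (Pa)
#' @return list(ecap = OSI/TAWSS with NaN where TAWSS < eps, flagged = indices)
#' @export
ecap <- function(osi, tawss, eps = .EPS_PA) {
  stop_if_not(length(osi) == length(tawss), "length mismatch")
  stop_if_not(all(tawss >= 0), "TAWSS must be non-negative")
  out <- rep(NaN, length(osi))
  ok <- tawss >= eps
  out[ok] <- osi[ok] / tawss[ok]
  list(ecap = out, flagged = which(!ok))
}

#' Relative residence time
#'
#' RRT = 1 / ((1 - 2 OSI) TAWSS); singular as OSI -> 0.5 or TAWSS -> 0.
#'
#' @inheritParams ecap
#' @return list(rrt = values with NaN at singular points, flagged = indices)
#' @export
relative_residence_time <- function(osi, tawss, eps = .EPS_PA) {
  stop_if_not(length(osi) == length(tawss), "length mismatch")
  den <- (1 - 2 * osi) * tawss
  out <- rep(NaN, length(osi))
  ok <- den >= eps
  out[ok] <- 1 / den[ok]
  list(rrt = out, flagged = which(!ok))
}

#' Compute the full wall-metric field
#'
#' @param field `field_series` of WSS vectors on a `surface_mesh`
#' @param rule integration rule
#' @return object of class `wall_metrics`: per-point `tawss`, `osi`, `ecap`,
#'   `rrt`, flag indices, and the mesh reference
#' @export
wall_metrics <- function(field, rule = "rectangle") {
  tawss <- time_average_wss(field, rule)
  o <- oscillatory_shear_index(field, rule)
  e <- ecap(o$osi, tawss)
  r <- relative_residence_time(o$osi, tawss)
  structure(list(mesh = field$mesh, tawss = tawss, osi = o$osi,
                 ecap = e$ecap, rrt = r$rrt,
                 flags = list(osi_zero_wss = o$flagged, ecap = e$flagged,
                              rrt = r$flagged, osi_clamped = o$clamped)),
            class = "wall_metrics")
}

#' Sac-level summaries of wall metrics
#'
#' Area-weighted (default) means of OSI/ECAP/RRT over the sac, plus max and
#' mean TAWSS. Weights are the lumped point areas of the mesh. Flagged
#' (non-finite) ECAP/RRT points are excluded and their count reported. Whether
#' published "Average OSI" values are area-weighted is typically unstated;
#' uniform weighting is available for sensitivity analysis.
#'
#' @param metrics `wall_metrics`
#' @param weighting "area" (default) or "uniform"
#' @return named list: avg_osi, avg_ecap, avg_rrt, max_tawss, mean_tawss,
#'   n_excluded_ecap, n_excluded_rrt, weighting
#' @export
summarize_wall_metrics <- function(metrics, weighting = c("area", "uniform")) {
  weighting <- match.arg(weighting)
  w <- if (weighting == "area") metrics$mesh$point_areas
       else rep(1, length(metrics$tawss))
  wmean <- function(x, w) {
    ok <- is.finite(x)
    stop_if_not(any(ok), "all points flagged; no summary possible")
    sum(x[ok] * w[ok]) / sum(w[ok])
  }
  list(avg_osi = wmean(metrics$osi, w),
       avg_ecap = wmean(metrics$ecap, w),
       avg_rrt = wmean(metrics$rrt, w),
       max_tawss = max(metrics$tawss),
       mean_tawss = wmean(metrics$tawss, w),
       n_excluded_ecap = sum(!is.finite(metrics$ecap)),
       n_excluded_rrt = sum(!is.finite(metrics$rrt)),
       weighting = weighting)
}
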
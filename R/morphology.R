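#' Aneurysm sac morphometrics
#'
#' Six metrics from a triangulated sac surface plus a neck-plane and
#' inflow-direction specification: volume, surface area, height (max distance
#' from the neck plane), width (max caliper extent perpendicular to the inflow
#' direction), aspect ratio (height/width), and size ratio (height/parent
#' vessel diameter). The neck cut is accepted as input; no automatic neck
#' detection is attempted.
#'
#' @name morphology
NULL

#' Surface area of a triangulated mesh
#'
#' Sum of triangle areas (cross-product formula). Degenerate triangles warn
#' and contribute zero.
#'
#' @param mesh `surface_mesh`
#' @return mm^2
#' @export
surface_area <- function(mesh) {
  a <- triangle_areas(mesh$points, mesh$triangles)
  if (any(a <= 0)) warning("degenerate triangles contribute zero area")
  sum(a[a > 0])
}

#' Volume enclosed by a closed surface
#'
#' Divergence-theorem sum of signed tetrahedra against the origin; the result
#' is origin-independent for a closed, consistently oriented surface, and the
#' absolute value is returned so either global orientation is accepted.
#'
#' @param mesh `surface_mesh`, must be closed
#' @return mm^3
#' @export
enclosed_volume <- function(mesh) {
  bec <- boundary_edge_count(mesh$triangles)
  stop_if_not(bec == 0L,
              "surface is not closed (%d boundary edges)", bec)
  a <- mesh$points[mesh$triangles[, 1], , drop = FALSE]
  b <- mesh$points[mesh$triangles[, 2], , drop = FALSE]
  c <- mesh$points[mesh$triangles[, 3], , drop = FALSE]
  abs(sum(rowSums(row_cross(a, b) * c)) / 6)
}

#' Sac height, width and aspect ratio
#'
#' Height is the maximum signed distance of sac vertices above the neck plane.
#' Width is the maximum caliper extent of the vertices measured perpendicular
#' to the inflow direction: vertices are projected onto the plane orthogonal to
#' the inflow direction and the diameter of the projected point set (max
#' pairwise distance via the convex hull) is taken.
#'
#' @param sac `surface_mesh` of the isolated sac
#' @param neck_point a point on the neck plane (mm)
#' @param neck_normal neck-plane normal, pointing into the dome
#' @param inflow_direction unit vector of flow entering the aneurysm (defaults
#'   to the neck normal)
#' @param tol tolerance band (mm) allowed below the plane
#' @return list(height, width, aspect_ratio) in mm / dimensionless
#' @export
sac_metrics <- function(sac, neck_point, neck_normal,
                        inflow_direction = neck_normal, tol = 1e-8) {
  nrm <- normalize(neck_normal)
  inflow <- normalize(inflow_direction)
  used <- sort(unique(as.integer(sac$triangles)))   # ignore orphan vertices
  pts <- sac$points[used, , drop = FALSE]
  d <- as.numeric(sweep(pts, 2, neck_point) %*% nrm)
  stop_if_not(any(d > 0), "all vertices lie below the neck plane")
  if (min(d) < -max(tol, 1e-6 * max(abs(d))))
    warning(sprintf("%d vertices below the neck plane beyond tolerance",
                    sum(d < -tol)))
  height <- max(d)
  # orthonormal basis of the plane perpendicular to the inflow direction
  ref <- if (abs(inflow[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- normalize(pracma_cross(inflow, ref))
  e2 <- pracma_cross(inflow, e1)
  proj <- cbind(pts %*% e1, pts %*% e2)
  width <- caliper_diameter(proj)
  stop_if_not(width > 0, "degenerate (zero-width) projection")
  list(height = height, width = width, aspect_ratio = height / width)
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# diameter of a 2-D point set: max pairwise distance over convex hull vertices
caliper_diameter <- function(xy) {
  h <- unique(grDevices::chull(xy))
  p <- xy[h, , drop = FALSE]
  if (nrow(p) < 2) return(0)
  max(stats::dist(p))
}

#' Size ratio
#'
#' Sac height relative to the parent-vessel diameter.
#'
#' @param height sac height (mm)
#' @param parent_diameter parent vessel diameter (mm), > 0
#' @return dimensionless ratio
#' @export
size_ratio <- function(height, parent_diameter) {
  stop_if_not(parent_diameter > 0, "parent diameter must be positive")
  height / parent_diameter
}

#' All six sac morphometrics
#'
#' @inheritParams sac_metrics
#' @param parent_diameter parent vessel diameter (mm)
#' @return data.frame with volume, surface_area, height, width, aspect_ratio,
#'   parent_diameter, size_ratio
#' @export
morphology_metrics <- function(sac, neck_point, neck_normal,
                               inflow_direction = neck_normal,
                               parent_diameter) {
  sm <- sac_metrics(sac, neck_point, neck_normal, inflow_direction)
  vol <- if (sac$closed) enclosed_volume(sac) else NA_real_
  data.frame(volume = vol,
             surface_area = surface_area(sac),
             height = sm$height, width = sm$width,
             aspect_ratio = sm$aspect_ratio,
             parent_diameter = parent_diameter,
             size_ratio = size_ratio(sm$height, parent_diameter))
}
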
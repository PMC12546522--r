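#' Triangulated surface mesh
#'
#' Container for a triangulated surface (aneurysm sac or vessel wall).
#' Coordinates are in millimetres. Point areas are lumped one-third triangle
#' areas, the weights used for area-weighted wall-metric summaries.
#'
#' @param points numeric n x 3 matrix of vertex coordinates (mm)
#' @param triangles integer m x 3 matrix of 1-based vertex indices
#' @return object of class `surface_mesh` with elements `points`, `triangles`,
#'   `point_areas` (mm^2), `closed` (logical: no boundary edges)
#' @export
surface_mesh <- function(points, triangles) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  stop_if_not(ncol(points) == 3, "points must be n x 3")
  stop_if_not(ncol(triangles) == 3, "triangles must be m x 3")
  stop_if_not(all(is.finite(points)), "non-finite vertex coordinates")
  stop_if_not(min(triangles) >= 1 && max(triangles) <= nrow(points),
              "triangle indices out of range")
  ta <- triangle_areas(points, triangles)
  if (any(ta <= 0))
    warning(sprintf("%d degenerate triangle(s) with zero area", sum(ta <= 0)))
  pa <- numeric(nrow(points))
  for (k in 1:3) {
    s <- tapply(ta / 3, triangles[, k], sum)
    idx <- as.integer(names(s))
    pa[idx] <- pa[idx] + as.numeric(s)
  }
  structure(list(points = points, triangles = triangles,
                 point_areas = pa,
                 closed = boundary_edge_count(triangles) == 0L),
            class = "surface_mesh")
}

triangle_areas <- function(points, triangles) {
  a <- points[triangles[, 1], , drop = FALSE]
  b <- points[triangles[, 2], , drop = FALSE]
  c <- points[triangles[, 3], , drop = FALSE]
  0.5 * vec_norm(row_cross(b - a, c - a))
}

#' Count boundary edges of a triangulation
#'
#' An edge is a boundary edge when it belongs to exactly one triangle. A closed
#' surface has zero boundary edges.
#'
#' @param triangles m x 3 index matrix
#' @return integer count
#' @export
boundary_edge_count <- function(triangles) {
  e <- rbind(triangles[, c(1, 2)], triangles[, c(2, 3)], triangles[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  sum(table(key) == 1L)
}

#' Icosphere surface
#'
#' Subdivided icosahedron projected onto a sphere: the standard closed,
#' consistently oriented test surface. Area and enclosed volume converge to
#' 4*pi*r^2 and 4/3*pi*r^3 with subdivision level.
#'
#' @param radius sphere radius (mm), > 0
#' @param subdivisions number of 4-way triangle subdivisions (>= 0)
#' @return `surface_mesh`
#' @export
make_sphere_surface <- function(radius = 1, subdivisions = 2) {
  stop_if_not(radius > 0, "radius must be positive")
  stop_if_not(subdivisions >= 0, "subdivisions must be >= 0")
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  v <- v / sqrt(rowSums(v * v))
  if (subdivisions > 0) {
    for (s in seq_len(subdivisions)) {
      nv <- nrow(v)
      edges <- unique(rbind(
        cbind(pmin(f[, 1], f[, 2]), pmax(f[, 1], f[, 2])),
        cbind(pmin(f[, 2], f[, 3]), pmax(f[, 2], f[, 3])),
        cbind(pmin(f[, 3], f[, 1]), pmax(f[, 3], f[, 1]))))
      mid <- (v[edges[, 1], ] + v[edges[, 2], ]) / 2
      mid <- mid / sqrt(rowSums(mid * mid))
      midx <- nv + seq_len(nrow(edges))
      lookup <- new.env(hash = TRUE)
      keys <- paste(edges[, 1], edges[, 2])
      for (i in seq_along(keys)) assign(keys[i], midx[i], envir = lookup)
      getmid <- function(a, b)
        get(paste(pmin(a, b), pmax(a, b)), envir = lookup)
      v <- rbind(v, mid)
      nf <- matrix(0L, nrow(f) * 4, 3)
      for (i in seq_len(nrow(f))) {
        a <- f[i, 1]; b <- f[i, 2]; c <- f[i, 3]
        ab <- getmid(a, b); bc <- getmid(b, c); ca <- getmid(c, a)
        nf[(i - 1) * 4 + 1:4, ] <- rbind(
          c(a, ab, ca), c(b, bc, ab), c(c, ca, bc), c(ab, bc, ca))
      }
      f <- nf
    }
  }
  surface_mesh(v * radius, f)
}

#' Tetrahedral volume mesh
#'
#' @param points n x 3 vertex coordinates (mm)
#' @param tets m x 4 1-based index matrix; orientation is fixed so all signed
#'   volumes are positive
#' @return object of class `volume_mesh` with `points`, `tets`,
#'   `cell_volumes` (mm^3)
#' @export
volume_mesh <- function(points, tets) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  tets <- as.matrix(tets)
  storage.mode(tets) <- "integer"
  stop_if_not(ncol(points) == 3 && ncol(tets) == 4, "bad shapes")
  stop_if_not(min(tets) >= 1 && max(tets) <= nrow(points),
              "tet indices out of range")
  sv <- tet_signed_volumes(points, tets)
  neg <- sv < 0
  if (any(neg)) {            # swap two vertices to flip orientation
    tmp <- tets[neg, 3]
    tets[neg, 3] <- tets[neg, 4]
    tets[neg, 4] <- tmp
    sv <- abs(sv)
  }
  stop_if_not(all(sv > 0), "degenerate tetrahedra (zero volume) present")
  structure(list(points = points, tets = tets, cell_volumes = sv),
            class = "volume_mesh")
}

tet_signed_volumes <- function(points, tets) {
  a <- points[tets[, 1], , drop = FALSE]
  d1 <- points[tets[, 2], , drop = FALSE] - a
  d2 <- points[tets[, 3], , drop = FALSE] - a
  d3 <- points[tets[, 4], , drop = FALSE] - a
  rowSums(row_cross(d1, d2) * d3) / 6
}

#' Tetrahedralized ball
#'
#' Deterministic "spherified cube" mesh: a regular grid on the bounding cube is
#' split into six tetrahedra per cell (Kuhn decomposition, conforming across
#' cells) and every vertex is mapped radially onto the ball. Boundary vertices
#' land exactly on the sphere, so the total volume converges O(h^2) to
#' 4/3*pi*r^3.
#'
#' @param radius ball radius (mm)
#' @param target_edge requested grid edge length (mm), 0 < target_edge < radius
#' @return `volume_mesh`
#' @export
make_tet_ball <- function(radius = 1, target_edge = radius / 8) {
  stop_if_not(radius > 0, "radius must be positive")
  stop_if_not(target_edge > 0 && target_edge < radius,
              "need 0 < target_edge < radius")
  n <- max(2L, as.integer(ceiling(2 * radius / target_edge)))
  g <- seq(-1, 1, length.out = n + 1L)
  pts <- as.matrix(expand.grid(x = g, y = g, z = g))
  # radial cube -> ball map, blended: identity deep inside (keeps interior
  # cells undistorted for gradient accuracy), full spherification at the
  # boundary (|.|_inf shell -> |.|_2 shell) so boundary vertices lie exactly
  # on the sphere
  linf <- pmax(abs(pts[, 1]), abs(pts[, 2]), abs(pts[, 3]))
  l2 <- sqrt(rowSums(pts * pts))
  w <- linf^2
  fac <- ifelse(l2 > 0, (1 - w) + w * linf / l2, 1)
  pts <- pts * fac * radius
  # grid (i,j,k) 1-based -> linear index (x varies fastest in expand.grid)
  idx <- function(i, j, k) i + (n + 1L) * (j - 1L) + (n + 1L)^2 * (k - 1L)
  base <- expand.grid(i = 1:n, j = 1:n, k = 1:n)
  v000 <- idx(base$i,     base$j,     base$k)
  v100 <- idx(base$i + 1L, base$j,     base$k)
  v010 <- idx(base$i,     base$j + 1L, base$k)
  v110 <- idx(base$i + 1L, base$j + 1L, base$k)
  v001 <- idx(base$i,     base$j,     base$k + 1L)
  v101 <- idx(base$i + 1L, base$j,     base$k + 1L)
  v011 <- idx(base$i,     base$j + 1L, base$k + 1L)
  v111 <- idx(base$i + 1L, base$j + 1L, base$k + 1L)
  # Kuhn: six tets around the main diagonal v000 -> v111
  tets <- rbind(
    cbind(v000, v100, v110, v111),
    cbind(v000, v110, v010, v111),
    cbind(v000, v010, v011, v111),
    cbind(v000, v011, v001, v111),
    cbind(v000, v001, v101, v111),
    cbind(v000, v101, v100, v111))
  volume_mesh(pts, tets)
}

#' Total volume of a tetrahedral mesh
#' @param mesh `volume_mesh`
#' @return mm^3
#' @export
total_volume <- function(mesh) sum(mesh$cell_volumes)

#' Face-adjacency graph of a tetrahedral mesh
#'
#' Two cells are adjacent when they share a triangular face. Used for counting
#' connected vortex-core regions.
#'
#' @param mesh `volume_mesh`
#' @return two-column integer matrix of adjacent cell index pairs
#' @export
cell_face_adjacency <- function(mesh) {
  tets <- mesh$tets
  m <- nrow(tets)
  faces <- rbind(tets[, c(2, 3, 4)], tets[, c(1, 3, 4)],
                 tets[, c(1, 2, 4)], tets[, c(1, 2, 3)])
  faces <- t(apply(faces, 1, sort))
  cell <- rep(seq_len(m), 4)
  key <- paste(faces[, 1], faces[, 2], faces[, 3])
  o <- order(key)
  key <- key[o]; cell <- cell[o]
  same <- which(key[-1] == key[-length(key)])
  cbind(cell[same], cell[same + 1L])
}
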
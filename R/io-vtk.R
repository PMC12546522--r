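#' VTK XML file support
#'
#' ASCII VTK XML writers/readers for triangulated surfaces (PolyData, .vtp)
#' and tetrahedral meshes (UnstructuredGrid, .vtu), with named point/cell data
#' arrays. Enough of the format for round-tripping the package's own outputs
#' and loading them into ParaView; not a general-purpose VTK parser.
#'
#' @name vtk_io
NULL

fmt_nums <- function(x, per_line = 6) {
  x <- signif(as.numeric(t(x)), 17)
  paste(formatC(x, format = "g", digits = 17), collapse = " ")
}

data_array_xml <- function(name, values, ncomp) {
  sprintf(
    '<DataArray type="Float64" Name="%s" NumberOfComponents="%d" format="ascii">\n%s\n</DataArray>',
    name, ncomp, fmt_nums(values))
}

#' Write a surface mesh as VTK XML PolyData (.vtp)
#'
#' @param mesh `surface_mesh`
#' @param file output path
#' @param point_data named list of per-point scalars (vectors) or n x 3
#'   matrices
#' @export
write_vtp <- function(mesh, file, point_data = list()) {
  n <- nrow(mesh$points); m <- nrow(mesh$triangles)
  pd <- paste(vapply(names(point_data), function(nm) {
    v <- point_data[[nm]]
    data_array_xml(nm, v, if (is.matrix(v)) ncol(v) else 1L)
  }, character(1)), collapse = "\n")
  conn <- paste(as.integer(t(mesh$triangles)) - 1L, collapse = " ")
  offs <- paste(seq_len(m) * 3L, collapse = " ")
  xml <- sprintf(
'<?xml version="1.0"?>
<VTKFile type="PolyData" version="0.1" byte_order="LittleEndian">
<PolyData>
<Piece NumberOfPoints="%d" NumberOfPolys="%d">
<PointData>
%s
</PointData>
<Points>
%s
</Points>
<Polys>
<DataArray type="Int64" Name="connectivity" format="ascii">
%s
</DataArray>
<DataArray type="Int64" Name="offsets" format="ascii">
%s
</DataArray>
</Polys>
</Piece>
</PolyData>
</VTKFile>', n, m, pd, data_array_xml("Points", mesh$points, 3L), conn, offs)
  writeLines(xml, file)
  invisible(file)
}

parse_data_array <- function(node, ncomp) {
  vals <- as.numeric(strsplit(trimws(xml2::xml_text(node)), "\\s+")[[1]])
  if (ncomp > 1) matrix(vals, ncol = ncomp, byrow = TRUE) else vals
}

#' Read a VTK XML PolyData file written by [write_vtp()]
#' @param file path
#' @return list(mesh = `surface_mesh`, point_data = named list)
#' @export
read_vtp <- function(file) {
  doc <- xml2::read_xml(file)
  piece <- xml2::xml_find_first(doc, ".//Piece")
  pts_node <- xml2::xml_find_first(piece, "./Points/DataArray")
  pts <- parse_data_array(pts_node, 3L)
  conn <- as.integer(strsplit(trimws(xml2::xml_text(
    xml2::xml_find_first(piece, './Polys/DataArray[@Name="connectivity"]'))),
    "\\s+")[[1]]) + 1L
  tris <- matrix(conn, ncol = 3, byrow = TRUE)
  pd <- list()
  for (node in xml2::xml_find_all(piece, "./PointData/DataArray")) {
    nm <- xml2::xml_attr(node, "Name")
    nc <- as.integer(xml2::xml_attr(node, "NumberOfComponents"))
    pd[[nm]] <- parse_data_array(node, nc)
  }
  list(mesh = surface_mesh(pts, tris), point_data = pd)
}

#' Write a tetrahedral mesh as VTK XML UnstructuredGrid (.vtu)
#'
#' @param mesh `volume_mesh`
#' @param file output path
#' @param point_data,cell_data named lists of arrays
#' @export
write_vtu <- function(mesh, file, point_data = list(), cell_data = list()) {
  n <- nrow(mesh$points); m <- nrow(mesh$tets)
  mk <- function(lst) paste(vapply(names(lst), function(nm) {
    v <- lst[[nm]]
    data_array_xml(nm, v, if (is.matrix(v)) ncol(v) else 1L)
  }, character(1)), collapse = "\n")
  xml <- sprintf(
'<?xml version="1.0"?>
<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">
<UnstructuredGrid>
<Piece NumberOfPoints="%d" NumberOfCells="%d">
<PointData>
%s
</PointData>
<CellData>
%s
</CellData>
<Points>
%s
</Points>
<Cells>
<DataArray type="Int64" Name="connectivity" format="ascii">
%s
</DataArray>
<DataArray type="Int64" Name="offsets" format="ascii">
%s
</DataArray>
<DataArray type="UInt8" Name="types" format="ascii">
%s
</DataArray>
</Cells>
</Piece>
</UnstructuredGrid>
</VTKFile>', n, m, mk(point_data), mk(cell_data),
    data_array_xml("Points", mesh$points, 3L),
    paste(as.integer(t(mesh$tets)) - 1L, collapse = " "),
    paste(seq_len(m) * 4L, collapse = " "),
    paste(rep(10L, m), collapse = " "))   # VTK_TETRA = 10
  writeLines(xml, file)
  invisible(file)
}

#' Read a VTK XML UnstructuredGrid file written by [write_vtu()]
#' @param file path
#' @return list(mesh = `volume_mesh`, point_data, cell_data)
#' @export
read_vtu <- function(file) {
  doc <- xml2::read_xml(file)
  piece <- xml2::xml_find_first(doc, ".//Piece")
  pts <- parse_data_array(xml2::xml_find_first(piece, "./Points/DataArray"), 3L)
  conn <- as.integer(strsplit(trimws(xml2::xml_text(
    xml2::xml_find_first(piece, './Cells/DataArray[@Name="connectivity"]'))),
    "\\s+")[[1]]) + 1L
  tets <- matrix(conn, ncol = 4, byrow = TRUE)
  grab <- function(xpath) {
    out <- list()
    for (node in xml2::xml_find_all(piece, xpath)) {
      nm <- xml2::xml_attr(node, "Name")
      nc <- as.integer(xml2::xml_attr(node, "NumberOfComponents"))
      out[[nm]] <- parse_data_array(node, nc)
    }
    out
  }
  list(mesh = volume_mesh(pts, tets),
       point_data = grab("./PointData/DataArray"),
       cell_data = grab("./CellData/DataArray"))
}

#' Write a surface mesh as ASCII STL
#' @param mesh `surface_mesh`
#' @param file path
#' @export
write_stl <- function(mesh, file) {
  a <- mesh$points[mesh$triangles[, 1], , drop = FALSE]
  b <- mesh$points[mesh$triangles[, 2], , drop = FALSE]
  c <- mesh$points[mesh$triangles[, 3], , drop = FALSE]
  nrm <- row_cross(b - a, c - a)
  len <- pmax(vec_norm(nrm), 1e-300)
  nrm <- nrm / len
  con <- file(file, "w")
  on.exit(close(con))
  writeLines("solid aneuhemo", con)
  for (i in seq_len(nrow(a))) {
    writeLines(c(
      sprintf(" facet normal %.9g %.9g %.9g", nrm[i, 1], nrm[i, 2], nrm[i, 3]),
      "  outer loop",
      sprintf("   vertex %.9g %.9g %.9g", a[i, 1], a[i, 2], a[i, 3]),
      sprintf("   vertex %.9g %.9g %.9g", b[i, 1], b[i, 2], b[i, 3]),
      sprintf("   vertex %.9g %.9g %.9g", c[i, 1], c[i, 2], c[i, 3]),
      "  endloop",
      " endfacet"), con)
  }
  writeLines("endsolid aneuhemo", con)
  invisible(file)
}

#' Read an ASCII STL surface
#' @param file path
#' @return `surface_mesh` (duplicate vertices merged)
#' @export
read_stl <- function(file) {
  lines <- readLines(file)
  vl <- grep("^\\s*vertex", lines, value = TRUE)
  stop_if_not(length(vl) %% 3 == 0, "malformed STL: vertex count not x3")
  nums <- t(vapply(strsplit(trimws(vl), "\\s+"),
                   function(p) as.numeric(p[2:4]), numeric(3)))
  key <- apply(nums, 1, paste, collapse = ",")
  uk <- !duplicated(key)
  pts <- nums[uk, , drop = FALSE]
  idx <- match(key, key[uk])
  surface_mesh(pts, matrix(idx, ncol = 3, byrow = TRUE))
}
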
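#' Field-series I/O
#'
#' A time-resolved field is stored as one VTK file per phase plus a JSON index
#' (`series.json`) recording the phase files, phase times, cycle period and
#' units. A plain CSV route (`point_id, phase, vx, vy, vz`) is provided as a
#' text fallback; both routes must load identically.
#'
#' @name series_io
NULL

#' Write a field series to a directory
#'
#' @param field `field_series`
#' @param dir output directory (created if needed)
#' @param format "vtk" (default; .vtp or .vtu per mesh kind) or "csv"
#' @return path of the series index JSON
#' @export
write_field_series <- function(field, dir, format = c("vtk", "csv")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- n_phases(field)
  on_surface <- inherits(field$mesh, "surface_mesh")
  files <- character(p)
  if (format == "vtk") {
    ext <- if (on_surface) "vtp" else "vtu"
    for (k in seq_len(p)) {
      files[k] <- sprintf("phase_%03d.%s", k, ext)
      path <- file.path(dir, files[k])
      if (on_surface)
        write_vtp(field$mesh, path,
                  point_data = list(field = field$values[, , k]))
      else
        write_vtu(field$mesh, path,
                  point_data = list(field = field$values[, , k]))
    }
  } else {
    files <- "field.csv"
    n <- dim(field$values)[1]
    df <- do.call(rbind, lapply(seq_len(p), function(k)
      data.frame(point_id = seq_len(n), phase = k,
                 vx = field$values[, 1, k], vy = field$values[, 2, k],
                 vz = field$values[, 3, k])))
    utils::write.csv(df, file.path(dir, "field.csv"), row.names = FALSE)
    mesh_file <- if (on_surface) "mesh.vtp" else "mesh.vtu"
    if (on_surface) write_vtp(field$mesh, file.path(dir, mesh_file))
    else write_vtu(field$mesh, file.path(dir, mesh_file))
    files <- c(files, mesh_file)
  }
  idx <- list(format = format, files = files, phase_times = field$phase_times,
              period = field$period, units = field$units,
              mesh_kind = if (on_surface) "surface" else "volume")
  jsonlite::write_json(idx, file.path(dir, "series.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(file.path(dir, "series.json"))
}

#' Read a field series written by [write_field_series()]
#'
#' @param dir directory containing `series.json`
#' @return `field_series`
#' @export
read_field_series <- function(dir) {
  idx_path <- file.path(dir, "series.json")
  stop_if_not(file.exists(idx_path), "no series.json in %s", dir)
  idx <- jsonlite::read_json(idx_path, simplifyVector = TRUE)
  if (idx$format == "vtk") {
    missing <- idx$files[!file.exists(file.path(dir, idx$files))]
    stop_if_not(length(missing) == 0, "missing phase files: %s",
                paste(missing, collapse = ", "))
    first <- NULL
    vals <- NULL
    for (k in seq_along(idx$files)) {
      obj <- if (idx$mesh_kind == "surface")
        read_vtp(file.path(dir, idx$files[k]))
      else read_vtu(file.path(dir, idx$files[k]))
      if (is.null(first)) {
        first <- obj$mesh
        vals <- array(0, c(nrow(first$points), 3, length(idx$files)))
      } else {
        same <- isTRUE(all.equal(first$points, obj$mesh$points)) &&
          identical(if (idx$mesh_kind == "surface") first$triangles
                    else first$tets,
                    if (idx$mesh_kind == "surface") obj$mesh$triangles
                    else obj$mesh$tets)
        stop_if_not(same, "mesh topology mismatch between phase 1 and %d", k)
      }
      vals[, , k] <- obj$point_data$field
    }
    mesh <- first
  } else {
    mesh_file <- idx$files[2]
    mesh <- if (idx$mesh_kind == "surface")
      read_vtp(file.path(dir, mesh_file))$mesh
    else read_vtu(file.path(dir, mesh_file))$mesh
    df <- utils::read.csv(file.path(dir, idx$files[1]))
    p <- max(df$phase)
    n <- nrow(mesh$points)
    vals <- array(0, c(n, 3, p))
    for (k in seq_len(p)) {
      sub <- df[df$phase == k, ]
      sub <- sub[order(sub$point_id), ]
      stop_if_not(nrow(sub) == n, "phase %d has %d rows, expected %d",
                  k, nrow(sub), n)
      vals[, , k] <- as.matrix(sub[, c("vx", "vy", "vz")])
    }
  }
  field_series(mesh, vals, phase_times = idx$phase_times,
               period = idx$period, units = idx$units)
}

#' Write an `image_volume` (and its masks) as NIfTI files
#'
#' @param image `image_volume`
#' @param dir output directory
#' @return paths written
#' @export
write_image_volume <- function(image, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, "image.nii")
  write_nifti(image$voxels, paths, spacing = image$spacing)
  for (nm in names(image$masks)) {
    p <- file.path(dir, sprintf("mask_%s.nii", nm))
    write_nifti(image$masks[[nm]], p, spacing = image$spacing,
                datatype = "uint8")
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Read an `image_volume` written by [write_image_volume()]
#' @param dir directory
#' @return `image_volume`
#' @export
read_image_volume <- function(dir) {
  img <- read_nifti(file.path(dir, "image.nii"))
  mask_files <- list.files(dir, pattern = "^mask_.*\\.nii$")
  masks <- list()
  for (f in mask_files) {
    nm <- sub("^mask_", "", sub("\\.nii$", "", f))
    masks[[nm]] <- read_nifti(file.path(dir, f))$voxels > 0
  }
  image_volume(img$voxels, img$spacing, masks)
}
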
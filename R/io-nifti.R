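#' Minimal NIfTI-1 image I/O
#'
#' Reads and writes uncompressed single-file NIfTI-1 (.nii) volumes with
#' float32 (images) or uint8 (masks) data, little-endian, identity-style
#' affine built from the voxel spacing. Sufficient for exchanging image
#' volumes and wall masks with standard neuroimaging tools; no full NIfTI R
#' package is assumed.
#'
#' @name nifti_io
NULL

#' Write a 3-D array as NIfTI-1
#'
#' @param voxels numeric or logical 3-D array
#' @param file output path (.nii)
#' @param spacing voxel spacing, mm per axis
#' @param datatype "float32" (default) or "uint8"
#' @export
write_nifti <- function(voxels, file, spacing = c(1, 1, 1),
                        datatype = c("float32", "uint8")) {
  datatype <- match.arg(datatype)
  voxels <- as.array(voxels)
  stop_if_not(length(dim(voxels)) == 3, "voxels must be 3-D")
  con <- file(file, "wb")
  on.exit(close(con))
  writeBin(348L, con, size = 4, endian = "little")         # sizeof_hdr
  writeBin(raw(36), con)                                   # unused
  dims <- as.integer(c(3, dim(voxels), 1, 1, 1, 1))
  writeBin(dims, con, size = 2, endian = "little")         # dim[8]
  writeBin(raw(14), con)                                   # intent etc.
  dtcode <- if (datatype == "float32") 16L else 2L
  bitpix <- if (datatype == "float32") 32L else 8L
  writeBin(c(dtcode, bitpix, 0L), con, size = 2, endian = "little")
  writeBin(as.numeric(c(1, spacing, 1, 1, 1, 1)), con, size = 4,
           endian = "little")                              # pixdim[8]
  writeBin(352, con, size = 4, endian = "little")          # vox_offset
  writeBin(c(1, 0), con, size = 4, endian = "little")      # scl_slope/inter
  writeBin(raw(2 + 1 + 1), con)                            # slice_end..xyzt
  writeBin(c(0, 0), con, size = 4, endian = "little")      # cal_max/min
  writeBin(raw(16), con)                  # slice_duration toffset glmax glmin
  writeBin(raw(80 + 24), con)                              # descrip+aux_file
  writeBin(c(0L, 1L), con, size = 2, endian = "little")    # qform=0 sform=1
  writeBin(rep(0, 6), con, size = 4, endian = "little")    # quatern
  srow <- rbind(c(spacing[1], 0, 0, 0), c(0, spacing[2], 0, 0),
                c(0, 0, spacing[3], 0))
  writeBin(as.numeric(t(srow)), con, size = 4, endian = "little")
  writeBin(raw(16), con)                                   # intent_name
  writeChar("n+1", con, nchars = 3, eos = NULL)
  writeBin(raw(1 + 4), con)                                # magic pad + ext
  if (datatype == "float32")
    writeBin(as.numeric(voxels), con, size = 4, endian = "little")
  else
    writeBin(as.raw(as.integer(voxels)), con)
  invisible(file)
}

#' Read a NIfTI-1 volume written by [write_nifti()]
#' @param file path
#' @return list(voxels = 3-D array, spacing = mm per axis)
#' @export
read_nifti <- function(file) {
  con <- file(file, "rb")
  on.exit(close(con))
  hdr_size <- readBin(con, integer(), 1, size = 4, endian = "little")
  stop_if_not(hdr_size == 348L, "not a NIfTI-1 file (sizeof_hdr != 348)")
  readBin(con, raw(), 36)
  dims <- readBin(con, integer(), 8, size = 2, endian = "little")
  stop_if_not(dims[1] == 3L, "only 3-D volumes supported")
  shape <- dims[2:4]
  readBin(con, raw(), 14)
  dt <- readBin(con, integer(), 3, size = 2, endian = "little")
  pixdim <- readBin(con, numeric(), 8, size = 4, endian = "little")
  vox_offset <- readBin(con, numeric(), 1, size = 4, endian = "little")
  seek(con, vox_offset)
  n <- prod(shape)
  vox <- if (dt[1] == 16L)
    readBin(con, numeric(), n, size = 4, endian = "little")
  else if (dt[1] == 2L)
    as.numeric(readBin(con, integer(), n, size = 1, signed = FALSE))
  else stop("unsupported NIfTI datatype code ", dt[1], call. = FALSE)
  list(voxels = array(vox, shape), spacing = pixdim[2:4])
}
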
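# Minimal NIfTI-1 I/O.
#
# The pipeline only needs single-file .nii / .nii.gz volumes with a plain
# voxel grid (identity orientation), which this reader/writer covers: 3-D
# arrays of uint8 / int16 / int32 / float32 / float64, little- or big-endian
# on read, little-endian on write, with pixdim carried through. Anything a
# full neuroimaging stack would add (orientations, extensions, .hdr/.img
# pairs) is out of scope and rejected loudly rather than guessed at.

NIFTI_DT <- list(uint8 = 2L, int16 = 4L, int32 = 8L, float32 = 16L,
                 float64 = 64L)

#' Write a 3-D array as a NIfTI-1 volume
#'
#' @param x 3-D numeric, integer, or logical array.
#' @param path Output file; a `.gz` suffix triggers gzip compression.
#' @param pixdim Voxel size in mm along each axis (length 3).
#' @param datatype One of `"uint8"`, `"int16"`, `"int32"`, `"float32"`,
#'   `"float64"`, or `NULL` to choose from the storage mode of `x`
#'   (logical -> uint8, integer -> int32, double -> float64).
#' @return `path`, invisibly.
#' @export
write_nifti <- function(x, path, pixdim = c(1, 1, 1), datatype = NULL) {
  if (length(dim(x)) != 3) stop_fm("write_nifti() expects a 3-D array")
  stopifnot(length(pixdim) == 3, all(pixdim > 0))
  if (is.null(datatype)) {
    datatype <- if (is.logical(x)) "uint8" else if (is.integer(x)) "int32"
    else "float64"
  }
  code <- NIFTI_DT[[datatype]]
  if (is.null(code)) stop_fm("unsupported datatype '%s'", datatype)
  bitpix <- c(`2` = 8L, `4` = 16L, `8` = 32L, `16` = 32L, `64` = 64L)[[as.character(code)]]

  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  w_i32 <- function(v) writeBin(as.integer(v), con, size = 4, endian = "little")
  w_i16 <- function(v) writeBin(as.integer(v), con, size = 2, endian = "little")
  w_f32 <- function(v) writeBin(as.double(v), con, size = 4, endian = "little")
  w_raw <- function(n) writeBin(raw(n), con)

  w_i32(348)                          # sizeof_hdr
  w_raw(28)                           # data_type, db_name
  w_i32(0); w_i16(0)                  # extents, session_error
  writeBin(charToRaw("r"), con); w_raw(1)  # regular, dim_info
  w_i16(c(3L, dim(x), 1L, 1L, 1L, 1L))     # dim[8]
  w_f32(c(0, 0, 0)); w_i16(0)         # intent_p*, intent_code
  w_i16(code); w_i16(bitpix); w_i16(0)
  w_f32(c(1, pixdim, 1, 1, 1, 1))     # pixdim[8] (qfac = 1)
  w_f32(352)                          # vox_offset
  w_f32(1); w_f32(0)                  # scl_slope, scl_inter
  w_i16(0); w_raw(1)                  # slice_end, slice_code
  writeBin(as.raw(2L), con)           # xyzt_units: mm
  w_f32(c(0, 0, 0, 0))                # cal_max, cal_min, slice_dur, toffset
  w_i32(c(0, 0))                      # glmax, glmin
  w_raw(80 + 24)                      # descrip, aux_file
  w_i16(0); w_i16(1)                  # qform_code, sform_code
  w_f32(rep(0, 6))                    # quatern, qoffset
  w_f32(c(pixdim[1], 0, 0, 0))        # srow_x
  w_f32(c(0, pixdim[2], 0, 0))        # srow_y
  w_f32(c(0, 0, pixdim[3], 0))        # srow_z
  w_raw(16)                           # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0)), con)  # magic
  w_raw(4)                            # extension flag

  vals <- as.vector(x)
  if (datatype %in% c("uint8", "int16", "int32")) {
    writeBin(as.integer(vals), con, size = bitpix / 8, endian = "little")
  } else {
    writeBin(as.double(vals), con, size = bitpix / 8, endian = "little")
  }
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' @param path A `.nii` or `.nii.gz` file.
#' @return A list with `data` (array), `pixdim` (voxel sizes, mm) and
#'   `datatype` (storage name).
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop_fm("NIfTI file not found: %s", path)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rb") else file(path, "rb")
  raw_all <- readBin(con, "raw", n = 512 * 1024^2)
  close(con)
  parse <- function(endian) {
    rc <- rawConnection(raw_all)
    on.exit(close(rc))
    r_i32 <- function(n) readBin(rc, "integer", n, size = 4, endian = endian)
    r_i16 <- function(n) readBin(rc, "integer", n, size = 2, endian = endian)
    r_f32 <- function(n) readBin(rc, "double", n, size = 4, endian = endian)
    hdr <- list()
    hdr$sizeof_hdr <- r_i32(1)
    if (!identical(hdr$sizeof_hdr, 348L)) return(NULL)
    invisible(readBin(rc, "raw", 36))  # data_type..dim_info
    hdr$dim <- r_i16(8)
    invisible(r_f32(3)); invisible(r_i16(1))
    hdr$datatype <- r_i16(1)
    hdr$bitpix <- r_i16(1)
    invisible(r_i16(1))
    hdr$pixdim <- r_f32(8)
    hdr$vox_offset <- r_f32(1)
    hdr$scl_slope <- r_f32(1)
    hdr$scl_inter <- r_f32(1)
    hdr$endian <- endian
    hdr
  }
  hdr <- parse("little")
  if (is.null(hdr)) hdr <- parse("big")
  if (is.null(hdr)) stop_fm("%s is not a NIfTI-1 file (bad header size)", path)
  ndim <- hdr$dim[1]
  if (ndim < 3 || any(hdr$dim[5:8] > 1))
    stop_fm("only 3-D volumes are supported (dim = %s)",
            paste(hdr$dim, collapse = ","))
  shape <- hdr$dim[2:4]
  nvox <- prod(shape)
  dt_name <- names(NIFTI_DT)[match(hdr$datatype, unlist(NIFTI_DT))]
  if (is.na(dt_name)) stop_fm("unsupported NIfTI datatype code %d", hdr$datatype)
  off <- as.integer(round(hdr$vox_offset))
  rc <- rawConnection(raw_all)
  on.exit(close(rc))
  invisible(readBin(rc, "raw", off))
  vals <- switch(dt_name,
    uint8   = as.integer(readBin(rc, "integer", nvox, size = 1, signed = FALSE)),
    int16   = readBin(rc, "integer", nvox, size = 2, endian = hdr$endian),
    int32   = readBin(rc, "integer", nvox, size = 4, endian = hdr$endian),
    float32 = readBin(rc, "double", nvox, size = 4, endian = hdr$endian),
    float64 = readBin(rc, "double", nvox, size = 8, endian = hdr$endian))
  if (length(vals) != nvox) stop_fm("truncated NIfTI data in %s", path)
  slope <- hdr$scl_slope
  if (is.finite(slope) && slope != 0 && !(slope == 1 && hdr$scl_inter == 0))
    vals <- vals * slope + hdr$scl_inter
  list(data = array(vals, dim = shape),
       pixdim = hdr$pixdim[2:4],
       datatype = dt_name)
}
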
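# Minimal NIfTI-1 (.nii, uncompressed, single-file) reader/writer.
#
# The pre-installed R stack carries no NIfTI package, so the small subset of
# the format this pipeline needs is implemented directly: 3-D/4-D arrays,
# float32/float64/int16/int32/uint8 data, pixdim carrying the voxel size,
# diagonal sform. No extensions, no qform rotation support.

.NIFTI_HDR_SIZE <- 348L
.NIFTI_VOX_OFFSET <- 352

#' Write an array as a NIfTI-1 volume
#'
#' @param img 3-D or 4-D numeric array.
#' @param path output file name (`.nii`, uncompressed).
#' @param voxel_size voxel edge lengths in mm (3 values).
#' @param time_step spacing of the 4th dimension (written to `pixdim[4]`);
#'   sampling times themselves live in the sidecar table, see
#'   [write_volume()].
#' @param datatype `"float32"` (default) or `"float64"`.
#' @param descrip short description string (<= 79 bytes).
#' @return `path`, invisibly.
#' @export
write_nifti <- function(img, path, voxel_size = c(1, 1, 1), time_step = 1,
                        datatype = c("float32", "float64"),
                        descrip = "relaxomap") {
  datatype <- match.arg(datatype)
  d <- dim(img)
  if (is.null(d) || !(length(d) %in% c(3L, 4L)))
    stop("img must be a 3-D or 4-D array")
  ndim <- length(d)
  dim8 <- c(ndim, d, rep(1L, 7L - length(d)))
  pixdim8 <- c(1, voxel_size, if (ndim == 4L) time_step else 1,
               rep(0, 3))
  dtcode <- if (datatype == "float32") 16L else 64L
  bitpix <- if (datatype == "float32") 32L else 64L

  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size,
                                   endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wc <- function(s, len) {
    raw <- charToRaw(s)
    if (length(raw) > len) raw <- raw[seq_len(len)]
    writeBin(c(raw, raw(len - length(raw))), con)
  }
  wi(.NIFTI_HDR_SIZE, 4)            # sizeof_hdr
  wc("", 10); wc("", 18)            # data_type, db_name (unused)
  wi(0, 4); wi(0, 2)                # extents, session_error
  writeBin(charToRaw("r"), con)     # regular
  writeBin(as.raw(0), con)          # dim_info
  wi(dim8, 2)                       # dim[8]
  wf(c(0, 0, 0))                    # intent_p1..p3
  wi(0, 2)                          # intent_code
  wi(dtcode, 2); wi(bitpix, 2)      # datatype, bitpix
  wi(0, 2)                          # slice_start
  wf(pixdim8)                       # pixdim[8]
  wf(.NIFTI_VOX_OFFSET)             # vox_offset
  wf(1); wf(0)                      # scl_slope, scl_inter
  wi(0, 2)                          # slice_end
  writeBin(as.raw(c(0, 10)), con)   # slice_code, xyzt_units (mm | sec)
  wf(c(0, 0, 0, 0))                 # cal_max, cal_min, slice_duration, toffset
  wi(0, 4); wi(0, 4)                # glmax, glmin
  wc(descrip, 80); wc("", 24)       # descrip, aux_file
  wi(0, 2); wi(1, 2)                # qform_code = 0, sform_code = 1
  wf(rep(0, 6))                     # quatern_b/c/d, qoffset_x/y/z
  wf(c(voxel_size[1], 0, 0, 0))     # srow_x
  wf(c(0, voxel_size[2], 0, 0))     # srow_y
  wf(c(0, 0, voxel_size[3], 0))     # srow_z
  wc("", 16)                        # intent_name
  writeBin(c(charToRaw("n+1"), raw(1)), con)  # magic
  writeBin(raw(4), con)             # extension flag: none
  writeBin(as.numeric(img), con, size = bitpix %/% 8L, endian = "little")
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' @param path `.nii` file written by [write_nifti()] or any uncompressed
#'   single-file NIfTI-1 volume with a supported datatype.
#' @return list with `data` (array), `voxel_size` (mm), `time_step`, `dim`.
#' @export
read_nifti <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  endian <- "little"
  sizeof_hdr <- readBin(con, "integer", 1, size = 4, endian = endian)
  if (sizeof_hdr != .NIFTI_HDR_SIZE) {
    endian <- "big"
    seek(con, 0)
    sizeof_hdr <- readBin(con, "integer", 1, size = 4, endian = endian)
    if (sizeof_hdr != .NIFTI_HDR_SIZE)
      stop("not a NIfTI-1 file: ", path)
  }
  seek(con, 40)
  dim8 <- readBin(con, "integer", 8, size = 2, endian = endian)
  seek(con, 70)
  dtcode <- readBin(con, "integer", 1, size = 2, endian = endian)
  seek(con, 76)
  pixdim8 <- readBin(con, "numeric", 8, size = 4, endian = endian)
  vox_offset <- readBin(con, "numeric", 1, size = 4, endian = endian)
  scl_slope <- readBin(con, "numeric", 1, size = 4, endian = endian)
  scl_inter <- readBin(con, "numeric", 1, size = 4, endian = endian)
  seek(con, 344)
  magic <- rawToChar(readBin(con, "raw", 3))
  if (!magic %in% c("n+1", "ni1"))
    stop("not a NIfTI-1 file (bad magic): ", path)

  ndim <- dim8[1]
  if (!(ndim %in% c(3L, 4L))) stop("only 3-D/4-D volumes are supported")
  d <- dim8[2:(1 + ndim)]
  nvox <- prod(d)
  seek(con, vox_offset)
  data <- switch(as.character(dtcode),
    "2"  = readBin(con, "integer", nvox, size = 1, signed = FALSE,
                   endian = endian),
    "4"  = readBin(con, "integer", nvox, size = 2, endian = endian),
    "8"  = readBin(con, "integer", nvox, size = 4, endian = endian),
    "16" = readBin(con, "numeric", nvox, size = 4, endian = endian),
    "64" = readBin(con, "numeric", nvox, size = 8, endian = endian),
    stop("unsupported NIfTI datatype code: ", dtcode))
  data <- as.numeric(data)
  if (scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    data <- data * scl_slope + scl_inter
  list(data = array(data, dim = d),
       voxel_size = pixdim8[2:4],
       time_step = if (ndim == 4L) pixdim8[5] else NA_real_,
       dim = d)
}
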
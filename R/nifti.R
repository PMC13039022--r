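# Minimal single-file NIfTI-1 input/output.
#
# Implemented directly over readBin/writeBin because no NIfTI reader is
# available in the dependency set. Supports .nii and .nii.gz, data types
# uint8, int16, int32, float32, float64, scl_slope/scl_inter scaling and
# the pixdim spacing fields. The in-memory array order (z, y, x) with z
# fastest maps to the on-disk (i, j, k) order unchanged; spacing and origin
# follow the same axis order (pixdim[1:3], srow offsets).

NIFTI_TYPES <- list(`2` = list(what = "integer", size = 1, signed = FALSE),
                    `4` = list(what = "integer", size = 2, signed = TRUE),
                    `8` = list(what = "integer", size = 4, signed = TRUE),
                    `16` = list(what = "double", size = 4, signed = TRUE),
                    `64` = list(what = "double", size = 8, signed = TRUE))

nifti_connection <- function(path, open) {
  if (grepl("\\.gz$", path)) gzfile(path, open) else file(path, open)
}

#' Read a NIfTI-1 volume
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return a [volume3d()]; integer-typed files yield integer arrays.
#' @export
read_nifti <- function(path) {
  con <- nifti_connection(path, "rb")
  on.exit(close(con))
  sizeof_hdr <- readBin(con, "integer", 1, 4)
  endian <- if (sizeof_hdr == 348L) .Platform$endian else "swap"
  rb <- function(what, n, size) readBin(con, what, n, size, endian = endian)
  readBin(con, "raw", 36)                       # unused header fields
  dims <- rb("integer", 8, 2)
  ndim <- dims[1]
  if (ndim < 3 || any(dims[2:4] < 1)) stop("not a 3D NIfTI volume: ", path)
  if (ndim > 3 && any(dims[5:(1 + ndim)] > 1))
    stop("only single-frame 3D volumes are supported: ", path)
  rb("double", 3, 4)                            # intent_p1..p3
  rb("integer", 1, 2)                           # intent_code
  datatype <- rb("integer", 1, 2)
  rb("integer", 1, 2)                           # bitpix
  rb("integer", 1, 2)                           # slice_start
  pixdim <- rb("double", 8, 4)
  vox_offset <- rb("double", 1, 4)
  scl_slope <- rb("double", 1, 4)
  scl_inter <- rb("double", 1, 4)
  readBin(con, "raw", 132)                      # slice_end..aux_file
  rb("integer", 1, 2)                           # qform_code
  rb("integer", 1, 2)                           # sform_code
  rb("double", 6, 4)                            # quaternions
  srow <- matrix(rb("double", 12, 4), 3, 4, byrow = TRUE)
  readBin(con, "raw", 16 + 4)                   # intent_name + magic
  ty <- NIFTI_TYPES[[as.character(datatype)]]
  if (is.null(ty)) stop("unsupported NIfTI datatype code ", datatype)
  skip <- vox_offset - 348
  if (skip > 0) readBin(con, "raw", skip)
  n <- prod(dims[2:4])
  vals <- readBin(con, ty$what, n, ty$size, signed = ty$signed,
                  endian = endian)
  if (!is.na(scl_slope) && scl_slope != 0 &&
      !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  arr <- array(vals, dims[2:4])
  origin <- srow[, 4]
  volume3d(arr, spacing = pixdim[2:4], origin = origin)
}

#' Write a NIfTI-1 volume
#'
#' Integer arrays are stored as uint8 when their range fits, int16/int32
#' otherwise; numeric arrays as float32 (`float64 = TRUE` for double
#' precision).
#'
#' @param vol a [volume3d()].
#' @param path output path; `.gz` suffix enables gzip compression.
#' @param float64 store numeric data in double precision.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(vol, path, float64 = FALSE) {
  stopifnot(inherits(vol, "volume3d"))
  data <- vol$data
  if (is.logical(data)) data <- array(as.integer(data), dim(data))
  if (is.integer(data) || all(data == round(data))) {
    r <- range(data)
    if (r[1] >= 0 && r[2] <= 255) { code <- 2L; size <- 1L }
    else if (r[1] >= -32768 && r[2] <= 32767) { code <- 4L; size <- 2L }
    else { code <- 8L; size <- 4L }
    store <- as.integer(data)
    what <- "integer"
  } else {
    code <- if (float64) 64L else 16L
    size <- if (float64) 8L else 4L
    store <- as.numeric(data)
    what <- "double"
  }
  con <- nifti_connection(path, "wb")
  on.exit(close(con))
  wb <- function(x, size) writeBin(x, con, size = size)
  d <- dim(data)
  wb(348L, 4)
  writeBin(raw(36), con)
  wb(as.integer(c(3, d, 1, 1, 1, 1)), 2)        # dim[8]
  wb(numeric(3), 4)                             # intent_p1..p3
  wb(0L, 2)                                     # intent_code
  wb(code, 2)
  wb(size * 8L, 2)                              # bitpix
  wb(0L, 2)                                     # slice_start
  wb(c(1, vol$spacing, 0, 0, 0, 0), 4)          # pixdim
  wb(352, 4)                                    # vox_offset
  wb(c(1, 0), 4)                                # scl_slope, scl_inter
  writeBin(raw(4), con)                         # slice_end, slice_code, xyzt
  wb(numeric(3), 4)                             # cal_max, cal_min, slice_dur
  wb(0, 4)                                      # toffset
  wb(integer(2), 4)                             # glmax, glmin
  writeBin(raw(80 + 24), con)                   # descrip + aux_file
  wb(0L, 2)                                     # qform_code
  wb(1L, 2)                                     # sform_code
  wb(numeric(6), 4)                             # quaternions
  srow <- rbind(c(vol$spacing[1], 0, 0, vol$origin[1]),
                c(0, vol$spacing[2], 0, vol$origin[2]),
                c(0, 0, vol$spacing[3], vol$origin[3]))
  wb(as.numeric(t(srow)), 4)
  writeBin(raw(16), con)                        # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0)), con) # magic
  writeBin(raw(4), con)                         # extension flag
  writeBin(store, con, size = size)
  invisible(path)
}
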
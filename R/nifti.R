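# Minimal NIfTI-1 I/O.
#
# No NIfTI package is assumed to be available, so the pipeline carries its
# own reader/writer for the small subset of the format it produces and
# consumes: single-file (.nii / .nii.gz) little-endian volumes, datatypes
# uint8 / int16 / int32 / float32 / float64, dims up to 4, scl_slope /
# scl_inter honoured on read. Byte-swapped (big-endian) files are detected
# and swapped on read. Everything else (extensions, qform/sform rotations,
# RGB or complex datatypes) is out of scope.

NIFTI_DATATYPES <- list(
  uint8   = list(code = 2L,  bitpix = 8L,  what = "integer", size = 1L, signed = FALSE),
  int16   = list(code = 4L,  bitpix = 16L, what = "integer", size = 2L, signed = TRUE),
  int32   = list(code = 8L,  bitpix = 32L, what = "integer", size = 4L, signed = TRUE),
  float32 = list(code = 16L, bitpix = 32L, what = "double",  size = 4L, signed = TRUE),
  float64 = list(code = 64L, bitpix = 64L, what = "double",  size = 8L, signed = TRUE)
)

nifti_connection <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

#' Write an array as a NIfTI-1 volume
#'
#' Writes a single-file little-endian NIfTI-1 image (`.nii`, or `.nii.gz`
#' when the path ends in `.gz`). Data are stored unscaled
#' (`scl_slope = 1`, `scl_inter = 0`).
#'
#' @param data numeric or logical array, 2 to 4 dimensions (logical is
#'   stored as `uint8`).
#' @param path output file path; compressed when it ends in `.gz`.
#' @param pixdim voxel sizes per dimension (mm; fourth entry free units),
#'   recycled/padded to the array rank.
#' @param datatype one of `"uint8"`, `"int16"`, `"int32"`, `"float32"`,
#'   `"float64"`. Defaults to `"uint8"` for logical input, `"float32"`
#'   otherwise.
#' @param description up to 79 characters stored in the header descrip field.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(data, path, pixdim = NULL, datatype = NULL,
                        description = "") {
  if (is.logical(data)) {
    if (is.null(datatype)) datatype <- "uint8"
    storage.mode(data) <- "integer"
  }
  if (is.null(datatype)) datatype <- "float32"
  dt <- NIFTI_DATATYPES[[datatype]]
  if (is.null(dt)) stop("unsupported NIfTI datatype: ", datatype, call. = FALSE)
  dims <- dim(data)
  if (is.null(dims)) dims <- length(data)
  ndim <- length(dims)
  if (ndim < 1 || ndim > 4) stop("only 1-4 dimensional volumes supported", call. = FALSE)
  if (is.null(pixdim)) pixdim <- rep(1, ndim)
  pixdim <- c(pixdim, rep(1, max(0, ndim - length(pixdim))))[seq_len(ndim)]

  dim_field <- rep(1L, 8)
  dim_field[1] <- ndim
  dim_field[1 + seq_len(ndim)] <- as.integer(dims)
  pixdim_field <- rep(1, 8)
  pixdim_field[1 + seq_len(ndim)] <- pixdim

  le <- function(x, size, what = "integer") {
    writeBin(if (what == "integer") as.integer(x) else as.double(x),
             raw(), size = size, endian = "little")
  }
  desc <- charToRaw(substr(description, 1, 79))
  hdr <- c(
    le(348L, 4),                        # 0   sizeof_hdr
    raw(36),                            # 4   data_type..dim_info (unused)
    le(dim_field, 2),                   # 40  dim[8]
    raw(14),                            # 56  intent_p1..intent_code
    le(dt$code, 2),                     # 70  datatype
    le(dt$bitpix, 2),                   # 72  bitpix
    le(0L, 2),                          # 74  slice_start
    le(pixdim_field, 4, "double"),      # 76  pixdim[8]
    le(352, 4, "double"),               # 108 vox_offset
    le(c(1, 0), 4, "double"),           # 112 scl_slope, scl_inter
    raw(4),                             # 120 slice_end, slice_code, xyzt_units
    le(c(0, 0), 4, "double"),           # 124 cal_max, cal_min
    raw(16),                            # 132 slice_duration, toffset, glmax/glmin
    c(desc, raw(80 - length(desc))),    # 148 descrip
    raw(24),                            # 228 aux_file
    raw(76),                            # 252 qform/sform codes, quaternion, srows (all 0)
    raw(16),                            # 328 intent_name
    charToRaw("n+1"), raw(1),           # 344 magic
    raw(4)                              # 348 extension flag
  )
  stopifnot(length(hdr) == 352)
  con <- nifti_connection(path, "wb")
  on.exit(close(con))
  writeBin(hdr, con)
  vals <- as.vector(data)
  if (dt$what == "integer") {
    vals <- as.integer(round(vals))
    writeBin(vals, con, size = dt$size, endian = "little")
  } else {
    writeBin(as.double(vals), con, size = dt$size, endian = "little")
  }
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' Reads single-file NIfTI-1 images written by [write_nifti()] or by other
#' tools, honouring `scl_slope`/`scl_inter` and detecting byte order.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return A list with elements `data` (numeric array), `pixdim` (voxel
#'   sizes for the stored dimensions) and `datatype` (storage type name).
#' @export
read_nifti <- function(path) {
  con <- nifti_connection(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 348)
  if (length(hdr) < 348) stop("truncated NIfTI header in ", path, call. = FALSE)
  endian <- "little"
  size_hdr <- readBin(hdr[1:4], "integer", size = 4, endian = endian)
  if (size_hdr != 348L) {
    endian <- "big"
    size_hdr <- readBin(hdr[1:4], "integer", size = 4, endian = endian)
    if (size_hdr != 348L) stop(path, " is not a NIfTI-1 file", call. = FALSE)
  }
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1")) {
    stop(path, " has an unrecognised NIfTI magic string", call. = FALSE)
  }
  dim_field <- readBin(hdr[41:56], "integer", n = 8, size = 2, endian = endian)
  ndim <- dim_field[1]
  if (ndim < 1 || ndim > 7) stop("bad dim[0] in ", path, call. = FALSE)
  dims <- pmax(dim_field[1 + seq_len(ndim)], 1L)
  datatype_code <- readBin(hdr[71:72], "integer", n = 1, size = 2, endian = endian)
  idx <- which(vapply(NIFTI_DATATYPES, function(d) d$code == datatype_code, logical(1)))
  if (length(idx) != 1) {
    stop("unsupported NIfTI datatype code ", datatype_code, " in ", path, call. = FALSE)
  }
  dt <- NIFTI_DATATYPES[[idx]]
  pixdim_field <- readBin(hdr[77:108], "double", n = 8, size = 4, endian = endian)
  vox_offset <- readBin(hdr[109:112], "double", n = 1, size = 4, endian = endian)
  scl_slope <- readBin(hdr[113:116], "double", n = 1, size = 4, endian = endian)
  scl_inter <- readBin(hdr[117:120], "double", n = 1, size = 4, endian = endian)
  if (vox_offset > 348) readBin(con, "raw", n = vox_offset - 348)
  n_vox <- prod(dims)
  vals <- readBin(con, dt$what, n = n_vox, size = dt$size,
                  signed = dt$signed, endian = endian)
  if (length(vals) < n_vox) stop("truncated NIfTI data in ", path, call. = FALSE)
  vals <- as.double(vals)
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0)) {
    vals <- vals * scl_slope + scl_inter
  }
  list(
    data = array(vals, dim = dims),
    pixdim = pixdim_field[1 + seq_len(ndim)],
    datatype = names(NIFTI_DATATYPES)[idx]
  )
}
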
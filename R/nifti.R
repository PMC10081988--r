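# Minimal NIfTI-1 single-file (.nii / .nii.gz) reader and writer.
#
# Only what volumetric density maps need: 3-d volumes, isotropic spacing in
# pixdim, float32/float64/int16/int32/uint8 storage, scl_slope/scl_inter,
# either byte order.  Orientation handling is deliberately absent: volumes
# are treated as already co-registered arrays (voxel coordinates are
# 0-based array indices), so only the voxel size is carried.

nii_con <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

#' Read a NIfTI volume
#'
#' @param path a `.nii` or `.nii.gz` file containing a 3-d volume.
#' @return A [volume_grid()]; `spacing_mm` is taken from `pixdim`.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- nii_con(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 348L)
  if (length(hdr) < 348L)
    stop("malformed NIfTI file (truncated header): ", path)
  endian <- "little"
  sz <- readBin(hdr[1:4], "integer", 1L, size = 4L, endian = endian)
  if (sz != 348L) {
    endian <- "big"
    sz <- readBin(hdr[1:4], "integer", 1L, size = 4L, endian = endian)
    if (sz != 348L) stop("malformed NIfTI file (bad sizeof_hdr): ", path)
  }
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1"))
    stop("malformed NIfTI file (bad magic): ", path)
  if (magic == "ni1")
    stop("two-file (.hdr/.img) NIfTI is not supported: ", path)
  rd <- function(off, what, n, size)
    readBin(hdr[(off + 1):(off + n * size)], what, n, size = size,
            endian = endian)
  dims <- rd(40, "integer", 8L, 2L)
  nd <- dims[1]
  shape <- dims[2:(1 + max(nd, 1))]
  # trailing singleton dimensions are tolerated, anything else is not 3-d
  real <- shape[shape > 1L]
  if (nd < 3L || length(real) != 3L || any(shape[1:3] <= 1L))
    stop("expected a 3-d volume in ", path, " but dim = (",
         paste(shape, collapse = ", "), ")")
  datatype <- rd(70, "integer", 1L, 2L)
  pixdim <- rd(76, "numeric", 8L, 4L)
  vox_offset <- rd(108, "numeric", 1L, 4L)
  scl_slope <- rd(112, "numeric", 1L, 4L)
  scl_inter <- rd(116, "numeric", 1L, 4L)
  n <- prod(shape[1:3])
  # skip from end of header to the data offset
  if (vox_offset > 348)
    readBin(con, "raw", as.integer(vox_offset) - 348L)
  x <- switch(as.character(datatype),
    "2" = as.numeric(readBin(con, "integer", n, size = 1L, signed = FALSE)),
    "4" = as.numeric(readBin(con, "integer", n, size = 2L, endian = endian)),
    "8" = as.numeric(readBin(con, "integer", n, size = 4L, endian = endian)),
    "16" = readBin(con, "numeric", n, size = 4L, endian = endian),
    "64" = readBin(con, "numeric", n, size = 8L, endian = endian),
    stop("unsupported NIfTI datatype ", datatype, " in ", path))
  if (length(x) < n) stop("malformed NIfTI file (truncated data): ", path)
  if (is.finite(scl_slope) && scl_slope != 0 &&
      !(scl_slope == 1 && scl_inter == 0))
    x <- x * scl_slope + scl_inter
  dim(x) <- shape[1:3]
  volume_grid(x, spacing_mm = pixdim[2])
}

#' Write a NIfTI volume
#'
#' @param vol a [volume_grid()].
#' @param path output `.nii` or `.nii.gz` path.
#' @param dtype `"float64"` (lossless for R doubles, the default) or
#'   `"float32"`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, dtype = c("float64", "float32")) {
  stopifnot(inherits(vol, "volume_grid"))
  dtype <- match.arg(dtype)
  datatype <- if (dtype == "float64") 64L else 16L
  bitpix <- if (dtype == "float64") 64L else 32L
  d <- dim(vol$data)
  sp <- as.numeric(vol$spacing_mm)
  con <- nii_con(path, "wb")
  on.exit(close(con))
  w_int <- function(x, size) writeBin(as.integer(x), con, size = size,
                                      endian = "little")
  w_flt <- function(x) writeBin(as.numeric(x), con, size = 4L,
                                endian = "little")
  w_raw <- function(n) writeBin(raw(n), con)
  w_int(348L, 4L)                      # sizeof_hdr
  w_raw(10L + 18L + 4L + 2L + 1L + 1L) # data_type..dim_info
  w_int(c(3L, d, 1L, 1L, 1L, 1L), 2L)  # dim[8]
  w_flt(c(0, 0, 0))                    # intent_p1..p3
  w_int(0L, 2L)                        # intent_code
  w_int(datatype, 2L)
  w_int(bitpix, 2L)
  w_int(0L, 2L)                        # slice_start
  w_flt(c(1, sp, sp, sp, 0, 0, 0, 0))  # pixdim
  w_flt(352)                           # vox_offset
  w_flt(1); w_flt(0)                   # scl_slope, scl_inter
  w_int(0L, 2L); w_raw(1L)             # slice_end, slice_code
  writeBin(as.raw(10L), con)           # xyzt_units: mm | s
  w_flt(c(0, 0, 0, 0))                 # cal_max..toffset
  w_int(c(0L, 0L), 4L)                 # glmax, glmin
  w_raw(80L + 24L)                     # descrip, aux_file
  w_int(0L, 2L)                        # qform_code
  w_int(1L, 2L)                        # sform_code
  w_flt(c(0, 0, 0, 0, 0, 0))           # quatern, qoffset
  w_flt(c(sp, 0, 0, 0))                # srow_x
  w_flt(c(0, sp, 0, 0))                # srow_y
  w_flt(c(0, 0, sp, 0))                # srow_z
  w_raw(16L)                           # intent_name
  writeBin(c(charToRaw("n+1"), raw(1)), con)  # magic
  w_raw(4L)                            # extension flag
  writeBin(as.numeric(vol$data), con, size = bitpix %/% 8L,
           endian = "little")
  invisible(path)
}
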
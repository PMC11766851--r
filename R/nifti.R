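# Minimal NIfTI-1 reader/writer.
#
# No NIfTI package is available in this R stack, so the single-file NIfTI-1
# format (348-byte header + voxel block, optionally gzipped) is implemented
# directly.  Arrays are exchanged in NIfTI's native (x, y, z[, t]) axis
# order; callers handle any reordering.  Supported on read: uint8, int8,
# int16, uint16, int32, float32, float64, both endiannesses, scl_slope/inter
# scaling, sform/qform affines.  Written files use sform (code 1), magic
# "n+1", vox_offset 352.

nifti_open <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

nifti_dtypes <- list(
  uint8 = list(code = 2L, bitpix = 8L),
  int16 = list(code = 4L, bitpix = 16L),
  int32 = list(code = 8L, bitpix = 32L),
  float32 = list(code = 16L, bitpix = 32L),
  float64 = list(code = 64L, bitpix = 64L)
)

#' Read a NIfTI-1 volume
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return List with `data` (numeric array in x,y,z\[,t\] order), `spacing`
#'   (mm per x,y,z axis), `affine` (4x4 voxel-to-world map, 0-based voxel
#'   indices) and `datatype` (storage type name).
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop("NIfTI file does not exist: ", path)
  con <- nifti_open(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 348L)
  if (length(hdr) < 348L) stop("truncated NIfTI header in ", path)
  rd <- function(what, n, off, size, endian) {
    readBin(hdr[(off + 1L):length(hdr)], what, n = n, size = size,
            endian = endian, signed = TRUE)
  }
  endian <- "little"
  if (rd("integer", 1L, 0L, 4L, endian) != 348L) {
    endian <- "big"
    if (rd("integer", 1L, 0L, 4L, endian) != 348L) {
      stop("not a NIfTI-1 file (sizeof_hdr != 348): ", path)
    }
  }
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1")) stop("unsupported NIfTI magic '", magic, "' in ", path)
  dims <- rd("integer", 8L, 40L, 2L, endian)
  ndim <- dims[1]
  if (ndim < 1L || ndim > 7L) stop("bad NIfTI dim[0] = ", ndim, " in ", path)
  shape <- dims[2:(1L + ndim)]
  datatype <- rd("integer", 1L, 70L, 2L, endian)
  pixdim <- rd("double", 8L, 76L, 4L, endian)
  vox_offset <- rd("double", 1L, 108L, 4L, endian)
  scl_slope <- rd("double", 1L, 112L, 4L, endian)
  scl_inter <- rd("double", 1L, 116L, 4L, endian)
  qform_code <- rd("integer", 1L, 252L, 2L, endian)
  sform_code <- rd("integer", 1L, 254L, 2L, endian)
  n <- prod(shape)
  # skip any extension bytes between header and voxel data
  skip <- as.integer(vox_offset) - 348L
  if (magic == "n+1" && skip > 0L) readBin(con, "raw", skip)
  data <- switch(as.character(datatype),
    "2" = as.numeric(readBin(con, "integer", n, size = 1L, signed = FALSE)),
    "256" = as.numeric(readBin(con, "integer", n, size = 1L, signed = TRUE)),
    "4" = as.numeric(readBin(con, "integer", n, size = 2L, endian = endian)),
    "512" = {
      v <- readBin(con, "integer", n, size = 2L, signed = FALSE, endian = endian)
      as.numeric(v)
    },
    "8" = as.numeric(readBin(con, "integer", n, size = 4L, endian = endian)),
    "16" = readBin(con, "double", n, size = 4L, endian = endian),
    "64" = readBin(con, "double", n, size = 8L, endian = endian),
    stop("unsupported NIfTI datatype code ", datatype, " in ", path)
  )
  if (length(data) < n) stop("truncated voxel data in ", path)
  if (scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0)) {
    data <- data * scl_slope + scl_inter
  }
  dim(data) <- shape
  affine <- if (sform_code > 0L) {
    rbind(rd("double", 4L, 280L, 4L, endian),
          rd("double", 4L, 296L, 4L, endian),
          rd("double", 4L, 312L, 4L, endian),
          c(0, 0, 0, 1))
  } else if (qform_code > 0L) {
    b <- rd("double", 1L, 256L, 4L, endian)
    cq <- rd("double", 1L, 260L, 4L, endian)
    d <- rd("double", 1L, 264L, 4L, endian)
    off <- c(rd("double", 1L, 268L, 4L, endian),
             rd("double", 1L, 272L, 4L, endian),
             rd("double", 1L, 276L, 4L, endian))
    a <- sqrt(max(0, 1 - b^2 - cq^2 - d^2))
    R <- matrix(c(
      a^2 + b^2 - cq^2 - d^2, 2 * (b * cq - a * d), 2 * (b * d + a * cq),
      2 * (b * cq + a * d), a^2 + cq^2 - b^2 - d^2, 2 * (cq * d - a * b),
      2 * (b * d - a * cq), 2 * (cq * d + a * b), a^2 + d^2 - b^2 - cq^2
    ), 3, 3, byrow = TRUE)
    qfac <- if (pixdim[1] == 0) 1 else pixdim[1]
    S <- diag(c(pixdim[2], pixdim[3], qfac * pixdim[4]))
    rbind(cbind(R %*% S, off), c(0, 0, 0, 1))
  } else {
    diag(c(pixdim[2:4], 1))
  }
  list(data = data, spacing = pixdim[2:4], affine = affine,
       datatype = names(nifti_dtypes)[vapply(nifti_dtypes, function(d)
         d$code == datatype, logical(1))][1] %||% paste0("code", datatype))
}

#' Write a NIfTI-1 volume
#'
#' @param data 3D or 4D numeric array in x,y,z\[,t\] order.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param spacing mm per x,y,z axis.
#' @param affine Optional 4x4 voxel-to-world map; defaults to
#'   `diag(c(spacing, 1))`.
#' @param datatype Storage type: `"float64"` (default, lossless for R
#'   doubles), `"float32"`, `"int16"` or `"uint8"`.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(data, path, spacing = c(1, 1, 1), affine = NULL,
                        datatype = "float64") {
  stopifnot(is.array(data), length(dim(data)) %in% c(3L, 4L))
  dt <- nifti_dtypes[[datatype]]
  if (is.null(dt)) stop("unsupported write datatype: ", datatype)
  if (is.null(affine)) affine <- diag(c(spacing, 1))
  stopifnot(all(dim(affine) == c(4L, 4L)))
  nd <- length(dim(data))
  dims <- integer(8)
  dims[1] <- nd
  dims[2:(1L + nd)] <- dim(data)
  dims[(2L + nd):8] <- 1L
  pixdim <- c(1, spacing, rep(1, 4))
  con <- nifti_open(path, "wb")
  on.exit(close(con))
  wint <- function(x, size) writeBin(as.integer(x), con, size = size, endian = "little")
  wflt <- function(x) writeBin(as.double(x), con, size = 4L, endian = "little")
  wint(348L, 4L)                          # sizeof_hdr
  writeBin(raw(36L), con)                 # data_type, db_name, extents, session_error, regular, dim_info
  wint(dims, 2L)                          # dim
  writeBin(raw(14L), con)                 # intent_p1..3, intent_code
  wint(dt$code, 2L)                       # datatype
  wint(dt$bitpix, 2L)                     # bitpix
  wint(0L, 2L)                            # slice_start
  wflt(pixdim)                            # pixdim
  wflt(352)                               # vox_offset
  wflt(1); wflt(0)                        # scl_slope, scl_inter
  writeBin(raw(3L), con)                  # slice_end, slice_code
  writeBin(as.raw(0L), con)               # xyzt_units
  wflt(0); wflt(0); wflt(0)               # cal_max, cal_min, slice_duration
  wflt(0)                                 # toffset
  wint(c(0L, 0L), 4L)                     # glmax, glmin
  writeBin(raw(104L), con)                # descrip(80) + aux_file(24)
  wint(0L, 2L)                            # qform_code
  wint(1L, 2L)                            # sform_code
  wflt(rep(0, 6))                         # quatern_b/c/d, qoffset_x/y/z
  wflt(affine[1, ]); wflt(affine[2, ]); wflt(affine[3, ])
  writeBin(raw(16L), con)                 # intent_name
  writeBin(charToRaw("n+1"), con); writeBin(raw(1L), con)  # magic
  writeBin(raw(4L), con)                  # extender
  v <- as.vector(data)
  switch(datatype,
    float64 = writeBin(v, con, size = 8L, endian = "little"),
    float32 = writeBin(v, con, size = 4L, endian = "little"),
    int16 = writeBin(as.integer(round(v)), con, size = 2L, endian = "little"),
    uint8 = writeBin(as.integer(round(v)), con, size = 1L)
  )
  invisible(path)
}
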
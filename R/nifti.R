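# Minimal NIfTI-1 (.nii, single-file, little-endian) reader/writer.
# No NIfTI package is available in the target library, so the subset of the
# format this pipeline needs (3-D volumes, diagonal affine) is implemented
# directly. Data are written as float32 with an sform recording voxel size.

NII_HDR_SIZE <- 348L
NII_VOX_OFFSET <- 352

#' Write a 3-D volume to a NIfTI-1 file
#'
#' @param vol numeric 3-D array.
#' @param path output file path (conventionally `.nii`).
#' @param voxel_size voxel edge length in mm (scalar or length-3).
#' @param datatype `"float32"` (the fMRI convention) or `"float64"`
#'   (lossless for R doubles, used by the cohort store).
#' @return `path`, invisibly.
#' @export
write_nifti <- function(vol, path, voxel_size = 3,
                        datatype = c("float32", "float64")) {
  stopifnot(is.array(vol), length(dim(vol)) == 3L)
  datatype <- match.arg(datatype)
  dt_code <- if (datatype == "float32") 16L else 64L
  dt_size <- if (datatype == "float32") 4L else 8L
  voxel_size <- rep_len(as.numeric(voxel_size), 3L)
  con <- file(path, "wb")
  on.exit(close(con))
  w_i32 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  w_i16 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  w_f32 <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  w_raw <- function(n) writeBin(raw(n), con)

  w_i32(NII_HDR_SIZE)                     # sizeof_hdr
  w_raw(35L)                              # data_type, db_name, extents, session_error, regular
  writeBin(as.raw(0L), con)               # dim_info
  w_i16(c(3L, dim(vol), 1L, 1L, 1L, 1L))  # dim[8]
  w_f32(c(0, 0, 0))                       # intent_p1..p3
  w_i16(0L)                               # intent_code
  w_i16(dt_code)                          # datatype
  w_i16(8L * dt_size)                     # bitpix
  w_i16(0L)                               # slice_start
  w_f32(c(1, voxel_size, 1, 1, 1, 1))     # pixdim[8] (qfac = 1)
  w_f32(NII_VOX_OFFSET)                   # vox_offset
  w_f32(1); w_f32(0)                      # scl_slope, scl_inter
  w_i16(0L); writeBin(as.raw(c(0L, 2L)), con)  # slice_end, slice_code, xyzt_units = mm
  w_f32(c(0, 0, 0))                       # cal_max, cal_min, slice_duration
  w_f32(0)                                # toffset
  w_i32(c(0L, 0L))                        # glmax, glmin
  w_raw(80L + 24L)                        # descrip, aux_file
  w_i16(0L); w_i16(1L)                    # qform_code = 0, sform_code = 1
  w_f32(rep(0, 6))                        # quaterns b,c,d + qoffsets x,y,z
  w_f32(c(voxel_size[1], 0, 0, 0))        # srow_x
  w_f32(c(0, voxel_size[2], 0, 0))        # srow_y
  w_f32(c(0, 0, voxel_size[3], 0))        # srow_z
  w_raw(16L)                              # intent_name
  writeBin(c(charToRaw("n+1"), raw(1L)), con)  # magic
  w_raw(4L)                               # extension flag
  writeBin(as.numeric(vol), con, size = dt_size, endian = "little")
  invisible(path)
}

#' Read a NIfTI-1 volume written as a single `.nii` file
#'
#' Supports the little-endian, uncompressed subset used by this package
#' plus the common integer/float datatypes; applies the scaling slope and
#' intercept when present.
#'
#' @param path path to a `.nii` file.
#' @return list with `data` (numeric array), `dim`, and `voxel_size`.
#' @export
read_nifti <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  r_i32 <- function(n = 1L) readBin(con, "integer", n, size = 4L, endian = "little")
  r_i16 <- function(n = 1L) readBin(con, "integer", n, size = 2L, endian = "little")
  r_f32 <- function(n = 1L) readBin(con, "double", n, size = 4L, endian = "little")
  hdr_size <- r_i32()
  if (!identical(hdr_size, NII_HDR_SIZE))
    stop("not a little-endian NIfTI-1 file: ", path)
  invisible(readBin(con, "raw", 36L))
  dims <- r_i16(8L)
  ndim <- dims[1L]
  if (ndim < 3L) stop("expected a 3-D volume in ", path)
  shape <- dims[2:(1L + ndim)]
  if (ndim > 3L && any(shape[4:ndim] != 1L))
    stop("only 3-D volumes are supported: ", path)
  shape <- shape[1:3]
  invisible(r_f32(3L)); invisible(r_i16(1L))
  datatype <- r_i16(); invisible(r_i16(2L))
  pixdim <- r_f32(8L)
  vox_offset <- r_f32()
  scl_slope <- r_f32(); scl_inter <- r_f32()
  seek(con, vox_offset)
  n <- prod(shape)
  data <- switch(as.character(datatype),
    "2"  = as.numeric(readBin(con, "integer", n, size = 1L, signed = FALSE)),
    "4"  = as.numeric(readBin(con, "integer", n, size = 2L, endian = "little")),
    "8"  = as.numeric(readBin(con, "integer", n, size = 4L, endian = "little")),
    "16" = readBin(con, "double", n, size = 4L, endian = "little"),
    "64" = readBin(con, "double", n, size = 8L, endian = "little"),
    stop("unsupported NIfTI datatype ", datatype, " in ", path)
  )
  if (!is.na(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    data <- data * scl_slope + scl_inter
  list(data = array(data, dim = shape), dim = shape, voxel_size = pixdim[2:4])
}
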
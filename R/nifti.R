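# Minimal NIfTI-1 single-file (.nii / .nii.gz) reader and writer.
#
# No NIfTI package is available in the target environment, so the subset of
# the format this pipeline needs is implemented here: 3D volumes, datatypes
# uint8 / int16 / int32 / float32 / float64, little- or big-endian read,
# little-endian write, scl_slope/scl_inter honoured on read. Volumes are
# exposed as arrays [slice, row, col]; on disk, x = column, y = row,
# z = slice with x fastest, and pixdim = (dx, dy, dz) = (col, row, slice)
# spacing in mm.

.nifti_dt <- list(uint8 = list(code = 2L, bitpix = 8L, what = "integer",
                               size = 1L, signed = FALSE),
                  int16 = list(code = 4L, bitpix = 16L, what = "integer",
                               size = 2L, signed = TRUE),
                  int32 = list(code = 8L, bitpix = 32L, what = "integer",
                               size = 4L, signed = TRUE),
                  float32 = list(code = 16L, bitpix = 32L, what = "double",
                                 size = 4L, signed = TRUE),
                  float64 = list(code = 64L, bitpix = 64L, what = "double",
                                 size = 8L, signed = TRUE))

#' Write a 3D volume as a NIfTI-1 file
#'
#' @param vol 3D array indexed `[slice, row, col]`.
#' @param path Output path; `.nii` or `.nii.gz`.
#' @param pixel_spacing_mm (row, col) spacing in mm.
#' @param slice_thickness_mm Slice spacing in mm.
#' @param datatype One of `"uint8"`, `"int16"`, `"int32"`, `"float32"`,
#'   `"float64"`.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(vol, path, pixel_spacing_mm = c(1, 1),
                        slice_thickness_mm = 1, datatype = "float64") {
  stopifnot(is.array(vol), length(dim(vol)) == 3L)
  dt <- .nifti_dt[[datatype]]
  if (is.null(dt)) stopf("unsupported NIfTI datatype '%s'", datatype)
  d <- dim(vol)                      # (slice, row, col)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size,
                                   endian = "little")
  wf <- function(x) writeBin(as.double(x), con, size = 4L, endian = "little")
  wc <- function(s, len) {
    r <- charToRaw(s)
    writeBin(c(r, raw(len - length(r))), con)
  }
  wi(348L, 4)                                   # sizeof_hdr
  writeBin(raw(36), con)                        # data_type..regular+dim_info
  wi(c(3L, d[3], d[2], d[1], 1L, 1L, 1L, 1L), 2)  # dim[8]: x=col,y=row,z=slice
  wf(c(0, 0, 0)); wi(0L, 2)                     # intent_p1-3, intent_code
  wi(dt$code, 2); wi(dt$bitpix, 2); wi(0L, 2)   # datatype, bitpix, slice_start
  wf(c(1, pixel_spacing_mm[2], pixel_spacing_mm[1], slice_thickness_mm,
       0, 0, 0, 0))                             # pixdim
  wf(352); wf(1); wf(0)                         # vox_offset, scl_slope/inter
  wi(0L, 2); writeBin(as.raw(c(0L, 2L)), con)   # slice_end, slice_code, units=mm
  wf(c(0, 0, 0, 0))                             # cal_max/min, slice_dur, toffset
  wi(c(0L, 0L), 4)                              # glmax, glmin
  wc("", 80); wc("", 24)                        # descrip, aux_file
  wi(c(0L, 0L), 2)                              # qform_code, sform_code
  wf(rep(0, 6))                                 # quatern, qoffset
  wf(c(pixel_spacing_mm[2], 0, 0, 0))           # srow_x (informational)
  wf(c(0, pixel_spacing_mm[1], 0, 0))           # srow_y
  wf(c(0, 0, slice_thickness_mm, 0))            # srow_z
  wc("", 16)                                    # intent_name
  writeBin(c(charToRaw("n+1"), raw(1)), con)    # magic
  writeBin(raw(4), con)                         # extension flag
  dat <- as.vector(aperm(vol, c(3L, 2L, 1L)))   # x fastest
  if (dt$what == "integer")
    writeBin(as.integer(round(dat)), con, size = dt$size, endian = "little")
  else
    writeBin(as.double(dat), con, size = dt$size, endian = "little")
  invisible(path)
}

#' Read a NIfTI-1 file as a volume
#'
#' @param path `.nii` or `.nii.gz` file.
#' @return A list with `vol` (array `[slice, row, col]`), `pixel_spacing_mm`
#'   (row, col) and `slice_thickness_mm`.
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stopf("cannot read NIfTI file '%s'", path)
  open_con <- function() {
    con <- if (grepl("\\.gz$", path)) gzfile(path, "rb") else file(path, "rb")
    con
  }
  con <- open_con()
  on.exit(close(con))
  endian <- "little"
  hdr_sz <- readBin(con, "integer", 1, 4, endian = endian)
  if (!identical(hdr_sz, 348L)) {
    close(con); on.exit()
    con <- open_con(); on.exit(close(con))
    endian <- "big"
    hdr_sz <- readBin(con, "integer", 1, 4, endian = endian)
    if (!identical(hdr_sz, 348L))
      stopf("'%s' is not a NIfTI-1 file (bad header size)", path)
  }
  readBin(con, "raw", 36)
  dims <- readBin(con, "integer", 8, 2, endian = endian)
  ndim <- dims[1]
  if (!ndim %in% 2:4 || any(dims[2:(ndim + 1)] < 1))
    stopf("'%s': unsupported NIfTI dimensionality %d", path, ndim)
  if (ndim == 4 && dims[5] != 1)
    stopf("'%s': 4D NIfTI with multiple volumes is not supported", path)
  readBin(con, "raw", 14)                        # intent fields
  dtcode <- readBin(con, "integer", 1, 2, endian = endian)
  readBin(con, "integer", 2, 2, endian = endian) # bitpix, slice_start
  pixdim <- readBin(con, "double", 8, 4, endian = endian)
  vox_offset <- readBin(con, "double", 1, 4, endian = endian)
  scl_slope <- readBin(con, "double", 1, 4, endian = endian)
  scl_inter <- readBin(con, "double", 1, 4, endian = endian)
  dt <- NULL
  for (nm in names(.nifti_dt))
    if (.nifti_dt[[nm]]$code == dtcode) dt <- .nifti_dt[[nm]]
  if (is.null(dt)) stopf("'%s': unsupported NIfTI datatype code %d", path,
                         dtcode)
  # header cursor is now at byte 120; skip to vox_offset
  readBin(con, "raw", as.integer(round(vox_offset)) - 120L)
  nx <- dims[2]; ny <- if (ndim >= 2) dims[3] else 1L
  nz <- if (ndim >= 3) dims[4] else 1L
  n <- as.double(nx) * ny * nz
  dat <- readBin(con, dt$what, n, dt$size, signed = dt$signed,
                 endian = endian)
  if (length(dat) != n) stopf("'%s': truncated NIfTI data", path)
  dat <- as.double(dat)
  if (is.finite(scl_slope) && scl_slope != 0 &&
      !(scl_slope == 1 && scl_inter == 0))
    dat <- dat * scl_slope + scl_inter
  vol <- aperm(array(dat, c(nx, ny, nz)), c(3L, 2L, 1L))
  list(vol = vol,
       pixel_spacing_mm = c(pixdim[3], pixdim[2]),
       slice_thickness_mm = pixdim[4])
}
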
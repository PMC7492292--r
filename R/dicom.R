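# Minimal DICOM (Explicit VR Little Endian) writer and reader for
# single-frame grayscale Secondary Capture-like objects. Covers exactly what
# the pipeline exchanges: 8-bit binary masks (bit-exact round trip) and
# 16-bit quantitative maps with RescaleSlope/Intercept. One file per slice.

.sf_sc_sop_class <- "1.2.840.10008.5.1.4.1.1.7"   # Secondary Capture
.sf_ts_explicit_le <- "1.2.840.10008.1.2.1"
.sf_impl_uid <- "1.2.826.0.1.3680043.9.7365.1"

.sf_uid_counter <- local({i <- 0L; function() {i <<- i + 1L; i}})

make_uid <- function() {
  sprintf("%s.%.0f.%d.%d", .sf_impl_uid,
          as.numeric(Sys.time()) * 1000 %% 1e12, Sys.getpid() %% 100000L,
          .sf_uid_counter())
}

dcm_element <- function(group, elem, vr, value_raw) {
  if (length(value_raw) %% 2L == 1L) {
    pad <- if (vr %in% c("UI", "OB")) as.raw(0L) else charToRaw(" ")
    value_raw <- c(value_raw, pad)
  }
  head <- writeBin(c(as.integer(group), as.integer(elem)), raw(),
                   size = 2L, endian = "little")
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
    c(head, charToRaw(vr), raw(2),
      writeBin(length(value_raw), raw(), size = 4L, endian = "little"),
      value_raw)
  } else {
    c(head, charToRaw(vr),
      writeBin(length(value_raw), raw(), size = 2L, endian = "little"),
      value_raw)
  }
}

dcm_str <- function(group, elem, vr, s) dcm_element(group, elem, vr,
                                                    charToRaw(as.character(s)))
dcm_us <- function(group, elem, v)
  dcm_element(group, elem, "US",
              writeBin(as.integer(v), raw(), size = 2L, endian = "little"))

# Write one grayscale slice. `data` is an integer matrix [row, col] already
# quantized; bits = 8 (uint8) or 16 (uint16); slope/intercept map stored
# values back to physical units.
write_dicom_slice <- function(data, path, instance_number,
                              bits = 8L, slope = 1, intercept = 0,
                              pixel_spacing_mm = c(1, 1),
                              slice_thickness_mm = 1,
                              patient_id = "anon",
                              series_uid = make_uid()) {
  stopifnot(is.matrix(data))
  sop_uid <- make_uid()
  pix <- as.integer(round(t(data)))               # row-major pixel order
  pr <- writeBin(pix, raw(), size = bits %/% 8L, endian = "little")

  meta <- c(dcm_element(0x0002, 0x0001, "OB", as.raw(c(0L, 1L))),
            dcm_str(0x0002, 0x0002, "UI", .sf_sc_sop_class),
            dcm_str(0x0002, 0x0003, "UI", sop_uid),
            dcm_str(0x0002, 0x0010, "UI", .sf_ts_explicit_le),
            dcm_str(0x0002, 0x0012, "UI", .sf_impl_uid))
  grouplen <- dcm_element(0x0002, 0x0000, "UL",
                          writeBin(length(meta), raw(), size = 4L,
                                   endian = "little"))
  ds <- c(dcm_str(0x0008, 0x0016, "UI", .sf_sc_sop_class),
          dcm_str(0x0008, 0x0018, "UI", sop_uid),
          dcm_str(0x0008, 0x0060, "CS", "OT"),
          dcm_str(0x0010, 0x0010, "PN", patient_id),
          dcm_str(0x0010, 0x0020, "LO", patient_id),
          dcm_str(0x0018, 0x0050, "DS", format(slice_thickness_mm)),
          dcm_str(0x0020, 0x000E, "UI", series_uid),
          dcm_str(0x0020, 0x0013, "IS", as.integer(instance_number)),
          dcm_us(0x0028, 0x0002, 1L),
          dcm_str(0x0028, 0x0004, "CS", "MONOCHROME2"),
          dcm_us(0x0028, 0x0010, nrow(data)),
          dcm_us(0x0028, 0x0011, ncol(data)),
          dcm_str(0x0028, 0x0030, "DS",
                  sprintf("%g\\%g", pixel_spacing_mm[1], pixel_spacing_mm[2])),
          dcm_us(0x0028, 0x0100, bits),
          dcm_us(0x0028, 0x0101, bits),
          dcm_us(0x0028, 0x0102, bits - 1L),
          dcm_us(0x0028, 0x0103, 0L),
          dcm_str(0x0028, 0x1052, "DS", format(intercept)),
          dcm_str(0x0028, 0x1053, "DS", format(slope)),
          dcm_element(0x7FE0, 0x0010, if (bits == 8L) "OB" else "OW", pr))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(grouplen, meta, ds), con)
  invisible(path)
}

# Read one slice written by write_dicom_slice (or any uncompressed
# Explicit VR Little Endian single-frame grayscale object).
read_dicom_slice <- function(path) {
  raw_all <- readBin(path, "raw", file.info(path)$size)
  if (length(raw_all) < 132 ||
      !identical(rawToChar(raw_all[129:132]), "DICM"))
    stopf("'%s' is not a DICOM part-10 file", path)
  pos <- 133L
  u16 <- function(i) as.integer(raw_all[i]) + 256L * as.integer(raw_all[i + 1L])
  u32 <- function(i) u16(i) + 65536 * u16(i + 2L)
  tags <- list()
  n <- length(raw_all)
  while (pos + 7L <= n) {
    group <- u16(pos); elem <- u16(pos + 2L)
    vr <- rawToChar(raw_all[(pos + 4L):(pos + 5L)])
    if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
      len <- u32(pos + 8L); vstart <- pos + 12L
    } else {
      len <- u16(pos + 6L); vstart <- pos + 8L
    }
    key <- sprintf("%04x%04x", group, elem)
    tags[[key]] <- list(vr = vr, start = vstart, len = len)
    pos <- vstart + len
    if (group == 0x7FE0 && elem == 0x0010) break
  }
  getv <- function(key) tags[[key]]
  str_at <- function(t) {
    if (t$len == 0) return("")
    trimws(rawToChar(raw_all[t$start:(t$start + t$len - 1L)]))
  }
  need <- function(key, what) {
    t <- getv(key)
    if (is.null(t)) stopf("'%s': missing DICOM tag %s (%s)", path, key, what)
    t
  }
  rows <- u16(need("00280010", "Rows")$start)
  cols <- u16(need("00280011", "Columns")$start)
  bits <- u16(need("00280100", "BitsAllocated")$start)
  pd <- need("7fe00010", "PixelData")
  nbytes <- rows * cols * (bits %/% 8L)
  if (pd$len < nbytes) stopf("'%s': truncated pixel data", path)
  pix <- readBin(raw_all[pd$start:(pd$start + nbytes - 1L)], "integer",
                 n = rows * cols, size = bits %/% 8L, signed = FALSE,
                 endian = "little")
  slope <- 1; intercept <- 0
  t <- getv("00281053"); if (!is.null(t)) slope <- as.numeric(str_at(t))
  t <- getv("00281052"); if (!is.null(t)) intercept <- as.numeric(str_at(t))
  inst <- getv("00200013")
  spacing <- c(1, 1)
  t <- getv("00280030")
  if (!is.null(t))
    spacing <- as.numeric(strsplit(str_at(t), "\\\\")[[1]])
  thick <- 1
  t <- getv("00180050"); if (!is.null(t)) thick <- as.numeric(str_at(t))
  list(data = t(matrix(pix, nrow = cols, ncol = rows)) * slope + intercept,
       instance_number = if (is.null(inst)) NA_integer_
                         else as.integer(str_at(inst)),
       pixel_spacing_mm = spacing, slice_thickness_mm = thick)
}

# Write a 3D volume [slice, row, col] as a DICOM series directory.
# For float data a 16-bit quantization with slope/intercept is used; integer
# data in [0, 65535] is stored losslessly (slope 1). Binary masks should be
# written with bits = 8.
write_dicom_series <- function(vol, dir, pixel_spacing_mm = c(1, 1),
                               slice_thickness_mm = 1, patient_id = "anon",
                               bits = 16L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  su <- make_uid()
  vmax <- max(vol); vmin <- min(vol)
  integral <- all(vol == round(vol))
  if (bits == 8L) {
    if (!integral || vmin < 0 || vmax > 255)
      stopf("8-bit DICOM export requires integer data in [0, 255]")
    slope <- 1; intercept <- 0
    q <- vol
  } else if (integral && vmin >= 0 && vmax <= 65535) {
    slope <- 1; intercept <- 0
    q <- vol
  } else {
    intercept <- vmin
    slope <- if (vmax > vmin) (vmax - vmin) / 65535 else 1
    q <- round((vol - intercept) / slope)
  }
  paths <- character(dim(vol)[1])
  for (s in seq_len(dim(vol)[1])) {
    paths[s] <- file.path(dir, sprintf("slice_%03d.dcm", s))
    write_dicom_slice(q[s, , ], paths[s], instance_number = s, bits = bits,
                      slope = slope, intercept = intercept,
                      pixel_spacing_mm = pixel_spacing_mm,
                      slice_thickness_mm = slice_thickness_mm,
                      patient_id = patient_id, series_uid = su)
  }
  invisible(paths)
}

# Read a DICOM series directory back into a volume [slice, row, col],
# ordering slices by InstanceNumber (fallback: filename).
read_dicom_series_dir <- function(dir) {
  files <- list.files(dir, pattern = "\\.dcm$", full.names = TRUE)
  if (length(files) == 0) stopf("no DICOM files found in '%s'", dir)
  slices <- lapply(sort(files), read_dicom_slice)
  inst <- vapply(slices, function(s) s$instance_number, integer(1))
  if (!anyNA(inst)) slices <- slices[order(inst)]
  dims <- vapply(slices, function(s) dim(s$data), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stopf("geometry mismatch: inconsistent slice sizes in '%s'", dir)
  vol <- array(0, c(length(slices), dims[1, 1], dims[2, 1]))
  for (s in seq_along(slices)) vol[s, , ] <- slices[[s]]$data
  list(vol = vol, pixel_spacing_mm = slices[[1]]$pixel_spacing_mm,
       slice_thickness_mm = slices[[1]]$slice_thickness_mm)
}
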
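#' Read a four-channel Dixon/IDEAL series
#'
#' Assembles a [dixon_series()] from either four NIfTI volumes (filename
#' suffixes `_water`, `_fat`, `_ff`, `_r2s`) in one directory, or four DICOM
#' series subdirectories (`water/`, `fat/`, `ff/`, `r2s/`). All channels must
#' be geometrically consistent; the fat-fraction map is clipped to
#' `[0, 100]` percent on read (the package stores fat fraction in percent
#' everywhere).
#'
#' @param path Directory containing the channel files/subdirectories.
#' @param layout `"auto"` (default), `"nifti"` or `"dicom"`.
#' @param subject_id Subject identifier; defaults to the directory name.
#' @return A [dixon_series()].
#' @export
read_dixon_series <- function(path, layout = c("auto", "nifti", "dicom"),
                              subject_id = basename(normalizePath(path))) {
  layout <- match.arg(layout)
  if (!dir.exists(path)) stopf("series directory '%s' does not exist", path)
  suffix <- c(water = "_water", fat = "_fat", fat_fraction = "_ff",
              r2star = "_r2s")
  if (layout == "auto") {
    layout <- if (length(list.files(path, pattern = "\\.nii(\\.gz)?$")) > 0)
      "nifti" else "dicom"
  }
  chans <- list()
  geom <- NULL
  for (nm in names(suffix)) {
    if (layout == "nifti") {
      f <- list.files(path, pattern = paste0(suffix[[nm]], "\\.nii(\\.gz)?$"),
                      full.names = TRUE)
      if (length(f) == 0) stopf("incomplete series: %s", nm)
      r <- read_nifti(f[1])
    } else {
      d <- file.path(path, sub("^_", "", suffix[[nm]]))
      if (!dir.exists(d)) stopf("incomplete series: %s", nm)
      r <- read_dicom_series_dir(d)
    }
    chans[[nm]] <- r$vol
    if (is.null(geom)) geom <- r
    else if (!identical(dim(r$vol), dim(geom$vol)))
      stopf("geometry mismatch: channel '%s' has shape %s, expected %s", nm,
            paste(dim(r$vol), collapse = "x"),
            paste(dim(geom$vol), collapse = "x"))
  }
  dixon_series(subject_id, chans$water, chans$fat, chans$fat_fraction,
               chans$r2star, pixel_spacing_mm = geom$pixel_spacing_mm,
               slice_thickness_mm = geom$slice_thickness_mm)
}

#' Write a Dixon series to disk
#'
#' Inverse of [read_dixon_series()]. NIfTI layout writes four `.nii` files
#' (`<subject>_water.nii`, ...); DICOM layout writes four series
#' subdirectories. NIfTI round-trips are exact (float64 storage); DICOM
#' channels are stored as 16-bit with RescaleSlope/Intercept and are exact
#' only for integer-valued data within `[0, 65535]`.
#'
#' @param series A [dixon_series()].
#' @param dir Output directory (created if needed).
#' @param layout `"nifti"` or `"dicom"`.
#' @return The output directory, invisibly.
#' @export
write_dixon_series <- function(series, dir, layout = c("nifti", "dicom")) {
  layout <- match.arg(layout)
  stopifnot(inherits(series, "dixon_series"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  chans <- list(water = series$water, fat = series$fat,
                ff = series$fat_fraction, r2s = series$r2star)
  for (nm in names(chans)) {
    if (layout == "nifti") {
      write_nifti(chans[[nm]],
                  file.path(dir, sprintf("%s_%s.nii", series$subject_id, nm)),
                  pixel_spacing_mm = series$pixel_spacing_mm,
                  slice_thickness_mm = series$slice_thickness_mm,
                  datatype = "float64")
    } else {
      write_dicom_series(chans[[nm]], file.path(dir, nm),
                         pixel_spacing_mm = series$pixel_spacing_mm,
                         slice_thickness_mm = series$slice_thickness_mm,
                         patient_id = series$subject_id, bits = 16L)
    }
  }
  invisible(dir)
}

#' Write a binary mask volume
#'
#' Masks are written so that a round-trip through [read_mask_volume()] is
#' bit-exact: NIfTI as a single uint8 file, DICOM as an 8-bit series
#' directory (one Secondary Capture object per slice), PNG as a directory of
#' 8-bit grayscale files (0/255).
#'
#' @param mask A binary [mask_volume()]. Probability masks must be
#'   binarized first (see [binarize()]).
#' @param template The [dixon_series()] supplying geometry metadata.
#' @param dest Output file (`nifti`) or directory (`dicom`, `png_stack`).
#' @param format One of `"nifti"`, `"dicom"`, `"png_stack"`.
#' @return The written path(s), invisibly.
#' @export
write_mask_volume <- function(mask, template, dest,
                              format = c("nifti", "dicom", "png_stack")) {
  format <- match.arg(format)
  stopifnot(inherits(mask, "mask_volume"))
  if (mask$kind != "binary")
    stopf("binarize first: write_mask_volume() accepts only binary masks")
  if (!is.null(template)) {
    check_same_shape(mask, template, "mask and template")
    sp <- template$pixel_spacing_mm; th <- template$slice_thickness_mm
    pid <- template$subject_id
  } else {
    sp <- c(1, 1); th <- 1; pid <- "anon"
  }
  if (format == "nifti") {
    write_nifti(mask$data, dest, pixel_spacing_mm = sp,
                slice_thickness_mm = th, datatype = "uint8")
    return(invisible(dest))
  }
  if (format == "dicom") {
    return(invisible(write_dicom_series(mask$data, dest,
                                        pixel_spacing_mm = sp,
                                        slice_thickness_mm = th,
                                        patient_id = pid, bits = 8L)))
  }
  dir.create(dest, recursive = TRUE, showWarnings = FALSE)
  paths <- character(dim(mask$data)[1])
  for (s in seq_len(dim(mask$data)[1])) {
    paths[s] <- file.path(dest, sprintf("mask_%03d.png", s))
    png::writePNG(mask$data[s, , ], paths[s])
  }
  invisible(paths)
}

#' Read a binary mask volume
#'
#' Accepts the output of [write_mask_volume()] in any supported format.
#' Stored values are coerced to \{0, 1\}: any nonzero value becomes 1.
#'
#' @param src Mask file (NIfTI) or directory (DICOM series / PNG stack).
#' @param template Optional [dixon_series()] (or 3D shape) the mask must
#'   match; a shape difference raises a "geometry mismatch" error.
#' @return A binary [mask_volume()].
#' @export
read_mask_volume <- function(src, template = NULL) {
  if (dir.exists(src)) {
    pngs <- list.files(src, pattern = "\\.png$", full.names = TRUE)
    if (length(pngs) > 0) {
      slices <- lapply(sort(pngs), function(p) {
        m <- png::readPNG(p)
        if (length(dim(m)) == 3L) m <- m[, , 1]
        m
      })
      dims <- vapply(slices, dim, integer(2))
      if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
        stopf("geometry mismatch: inconsistent slice sizes in '%s'", src)
      vol <- array(0, c(length(slices), dims[1, 1], dims[2, 1]))
      for (s in seq_along(slices)) vol[s, , ] <- slices[[s]]
    } else {
      vol <- read_dicom_series_dir(src)$vol
    }
  } else if (file.exists(src)) {
    vol <- read_nifti(src)$vol
  } else {
    stopf("mask source '%s' does not exist", src)
  }
  vol <- (vol != 0) * 1
  if (!is.null(template)) {
    td <- if (inherits(template, "dixon_series")) dim(template) else template
    if (!identical(dim(vol), as.integer(td)))
      stopf("geometry mismatch: mask is %s but template is %s",
            paste(dim(vol), collapse = "x"), paste(td, collapse = "x"))
  }
  mask_volume(vol, "binary")
}
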
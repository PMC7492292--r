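#' Four-channel water-fat (Dixon/IDEAL) series
#'
#' Container for one subject's co-registered IDEAL-derived maps: water and fat
#' signal (arbitrary units), fat fraction (percent) and R2* (1/s). Arrays are
#' indexed `[slice, row, col]` in the package's canonical orientation: slices
#' run left to right through the sagittal stack, rows run superior to
#' inferior, columns run anterior to posterior. A typical lumbar protocol
#' yields 20 slices of 256 x 256 pixels with vertebrae visible on 5-7
#' mid-sagittal slices.
#'
#' @param subject_id Character identifier.
#' @param water,fat 3D arrays of signal intensity (arbitrary units, >= 0).
#' @param fat_fraction 3D array, percent; values are clipped to `[0, 100]`.
#' @param r2star 3D array, 1/s (>= 0).
#' @param pixel_spacing_mm Length-2 numeric, (row, col) spacing in mm.
#' @param slice_thickness_mm Slice thickness in mm.
#' @return An object of class `dixon_series`.
#' @export
dixon_series <- function(subject_id, water, fat, fat_fraction, r2star,
                         pixel_spacing_mm = c(1.375, 1.375),
                         slice_thickness_mm = 4) {
  chans <- list(water = water, fat = fat, fat_fraction = fat_fraction,
                r2star = r2star)
  for (nm in names(chans)) {
    if (!is.array(chans[[nm]]) || length(dim(chans[[nm]])) != 3L)
      stopf("channel '%s' must be a 3D array [slice, row, col]", nm)
  }
  d <- dim(water)
  for (nm in names(chans)) {
    if (!identical(dim(chans[[nm]]), d))
      stopf("geometry mismatch: channel '%s' has shape %s, expected %s",
            nm, paste(dim(chans[[nm]]), collapse = "x"),
            paste(d, collapse = "x"))
  }
  water[water < 0] <- 0
  fat[fat < 0] <- 0
  r2star[r2star < 0] <- 0
  fat_fraction[fat_fraction < 0] <- 0
  fat_fraction[fat_fraction > 100] <- 100
  structure(list(subject_id = as.character(subject_id),
                 water = water, fat = fat, fat_fraction = fat_fraction,
                 r2star = r2star,
                 pixel_spacing_mm = as.numeric(pixel_spacing_mm),
                 slice_thickness_mm = as.numeric(slice_thickness_mm),
                 n_slices = d[1]),
            class = "dixon_series")
}

#' @export
print.dixon_series <- function(x, ...) {
  d <- dim(x$water)
  cat(sprintf("<dixon_series> subject %s: %d slices of %d x %d\n",
              x$subject_id, d[1], d[2], d[3]))
  cat(sprintf("  pixel spacing %.3f x %.3f mm, slice thickness %.1f mm\n",
              x$pixel_spacing_mm[1], x$pixel_spacing_mm[2],
              x$slice_thickness_mm))
  cat(sprintf("  fat fraction range %.1f-%.1f %%\n",
              min(x$fat_fraction), max(x$fat_fraction)))
  invisible(x)
}

#' @export
dim.dixon_series <- function(x) dim(x$water)

#' Stack the four channels of a series into one array
#'
#' Returns the `[H, W, 4, n_slices]` array the U-Net consumes, channels in the
#' fixed order (water, fat, fat_fraction, r2star).
#'
#' @param series A [dixon_series()].
#' @return A 4D numeric array.
#' @export
series_to_input <- function(series) {
  stopifnot(inherits(series, "dixon_series"))
  d <- dim(series$water)
  out <- array(0, c(d[2], d[3], 4L, d[1]))
  for (s in seq_len(d[1])) {
    out[, , 1L, s] <- series$water[s, , ]
    out[, , 2L, s] <- series$fat[s, , ]
    out[, , 3L, s] <- series$fat_fraction[s, , ]
    out[, , 4L, s] <- series$r2star[s, , ]
  }
  out
}

#' Binary or probabilistic segmentation mask volume
#'
#' A per-pixel vertebra labelling aligned to a [dixon_series()], indexed
#' `[slice, row, col]`. Binary masks contain only \{0, 1\}; probability masks
#' values in `[0, 1]`.
#'
#' @param data 3D array.
#' @param kind `"binary"` or `"probability"`.
#' @return An object of class `mask_volume`.
#' @export
mask_volume <- function(data, kind = c("binary", "probability")) {
  kind <- match.arg(kind)
  if (!is.array(data) || length(dim(data)) != 3L)
    stopf("mask data must be a 3D array [slice, row, col]")
  if (kind == "binary") {
    if (!all(data %in% c(0, 1)))
      stopf("binary mask may contain only 0 and 1")
    storage.mode(data) <- "double"
  } else {
    if (any(data < 0 | data > 1))
      stopf("probability mask values must lie in [0, 1]")
  }
  structure(list(data = data, kind = kind), class = "mask_volume")
}

#' @export
print.mask_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<mask_volume> %s, %d slices of %d x %d, %.1f%% positive\n",
              x$kind, d[1], d[2], d[3],
              100 * mean(if (x$kind == "binary") x$data else x$data > 0.5)))
  invisible(x)
}

#' @export
dim.mask_volume <- function(x) dim(x$data)

is_binary_mask <- function(x) inherits(x, "mask_volume") && x$kind == "binary"

check_same_shape <- function(a, b, what = "volumes") {
  da <- if (inherits(a, c("mask_volume"))) dim(a$data) else dim(a)
  db <- if (inherits(b, c("mask_volume", "dixon_series"))) dim(b) else dim(b)
  if (!identical(da, db))
    stopf("geometry mismatch: %s have shapes %s vs %s", what,
          paste(da, collapse = "x"), paste(db, collapse = "x"))
  invisible(TRUE)
}
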
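# Bone-marrow-fat quantification: mean of the fat-fraction map over each
# retained ROI on a slice-by-slice basis, then the unweighted average of the
# slice means per vertebral body.

#' Mean fat fraction of one ROI on one slice
#'
#' Arithmetic mean of the fat-fraction map over a pixel set. Non-finite
#' values (possible after division by near-zero signal in the reconstruction)
#' are excluded and counted.
#'
#' @param ff_slice 2D fat-fraction matrix `[row, col]` in percent.
#' @param pixels Two-column matrix of (row, col) pixel coordinates.
#' @return List with `mean_ff_pct`, `n_pixels` (finite pixels used) and
#'   `n_nonfinite` (excluded).
#' @export
slice_mean_ff <- function(ff_slice, pixels) {
  if (is.null(dim(pixels))) pixels <- matrix(pixels, ncol = 2)
  if (nrow(pixels) == 0) stopf("empty pixel set")
  if (any(pixels[, 1] < 1 | pixels[, 1] > nrow(ff_slice) |
            pixels[, 2] < 1 | pixels[, 2] > ncol(ff_slice)))
    stopf("pixel set out of bounds")
  v <- ff_slice[pixels]
  ok <- is.finite(v)
  if (!any(ok)) stopf("no finite fat-fraction values in ROI")
  list(mean_ff_pct = mean(v[ok]), n_pixels = sum(ok),
       n_nonfinite = sum(!ok))
}

#' Per-vertebra BMF from slice means
#'
#' The unweighted mean of the per-slice means: each retained slice
#' contributes equally, regardless of its pixel count ("averaging for all
#' slices"). The pixel-pooled alternative is available via
#' `weighted = TRUE` but is not the default.
#'
#' @param slice_means Numeric vector of per-slice mean fat fractions.
#' @param n_pixels Optional pixel counts, used only when `weighted = TRUE`.
#' @param weighted Pool pixels across slices instead (non-default).
#' @return Mean BMF in percent, or `NA` if no slices.
#' @export
vertebra_mean_bmf <- function(slice_means, n_pixels = NULL,
                              weighted = FALSE) {
  if (length(slice_means) == 0) return(NA_real_)
  if (weighted) {
    if (is.null(n_pixels)) stopf("weighted mean needs n_pixels")
    return(sum(slice_means * n_pixels) / sum(n_pixels))
  }
  mean(slice_means)
}

#' Quantify per-vertebra bone marrow fat
#'
#' Applies [slice_mean_ff()] over every retained ROI and
#' [vertebra_mean_bmf()] per lumbar level L1-L5.
#'
#' @param series A [dixon_series()] supplying the fat-fraction map.
#' @param roiset A labelled `vertebra_roiset`; if not yet filtered,
#'   [filter_rois_by_area()] is applied first.
#' @param weighted Use the pixel-pooled mean instead of the mean of slice
#'   means (non-default; see [vertebra_mean_bmf()]).
#' @return A `bmf_report`: `$summary` has one row per present level (subject,
#'   level, mean_bmf_pct, n_slices_used, n_pixels, n_nonfinite), `$slices`
#'   the per-slice provenance.
#' @export
quantify_bmf <- function(series, roiset, weighted = FALSE) {
  stopifnot(inherits(series, "dixon_series"),
            inherits(roiset, "vertebra_roiset"))
  if (!roiset$labeled) stopf("roiset must be labelled")
  if (!roiset$filtered) roiset <- filter_rois_by_area(roiset)
  if (!identical(roiset$shape, dim(series)))
    stopf("geometry mismatch: roiset is %s, series is %s",
          paste(roiset$shape, collapse = "x"),
          paste(dim(series), collapse = "x"))
  comps <- roiset$components
  slices <- list(); summ <- list()
  for (lv in intersect(.level_names, unique(comps$level))) {
    sel <- comps[comps$level == lv & comps$retained, , drop = FALSE]
    if (nrow(sel) == 0) next
    sel <- sel[order(sel$slice), , drop = FALSE]
    sm <- lapply(seq_len(nrow(sel)), function(i)
      slice_mean_ff(series$fat_fraction[sel$slice[i], , ],
                    roiset$pixels[[sel$id[i]]]))
    means <- vapply(sm, `[[`, numeric(1), "mean_ff_pct")
    npx <- vapply(sm, `[[`, numeric(1), "n_pixels")
    nnf <- vapply(sm, `[[`, numeric(1), "n_nonfinite")
    slices[[lv]] <- data.frame(subject = series$subject_id, level = lv,
                               slice = sel$slice, mean_ff_pct = means,
                               n_pixels = npx)
    summ[[lv]] <- data.frame(subject = series$subject_id, level = lv,
                             mean_bmf_pct = vertebra_mean_bmf(means, npx,
                                                              weighted),
                             n_slices_used = length(means),
                             n_pixels = sum(npx), n_nonfinite = sum(nnf))
  }
  structure(list(summary = if (length(summ)) do.call(rbind, c(summ, list(
    make.row.names = FALSE))) else data.frame(),
    slices = if (length(slices)) do.call(rbind, c(slices, list(
      make.row.names = FALSE))) else data.frame(),
    subject_id = series$subject_id),
    class = "bmf_report")
}

#' @export
print.bmf_report <- function(x, ...) {
  cat(sprintf("<bmf_report> subject %s\n", x$subject_id))
  if (nrow(x$summary) == 0) {
    cat("  no vertebral levels quantified\n")
    return(invisible(x))
  }
  for (i in seq_len(nrow(x$summary)))
    cat(sprintf("  %s: %.2f%% BMF over %d slice(s), %d pixels\n",
                x$summary$level[i], x$summary$mean_bmf_pct[i],
                x$summary$n_slices_used[i], x$summary$n_pixels[i]))
  invisible(x)
}

#' @export
as.data.frame.bmf_report <- function(x, ...) x$summary
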
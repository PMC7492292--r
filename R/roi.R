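# ROI derivation: connected components per slice, anatomical level assignment
# (L1-L5 top-down, with partially visible border bodies set aside as T12/S1),
# and the half-of-maximum-area inclusion rule.

new_roiset <- function(shape, components, pixels, min_area_px) {
  structure(list(shape = shape, components = components, pixels = pixels,
                 min_area_px = min_area_px, labeled = FALSE,
                 filtered = FALSE, reference_area = NULL),
            class = "vertebra_roiset")
}

#' @export
print.vertebra_roiset <- function(x, ...) {
  cat(sprintf("<vertebra_roiset> %d components on %d slices%s%s\n",
              nrow(x$components), x$shape[1],
              if (x$labeled) sprintf(", levels: %s",
                                     paste(sort(unique(
                                       x$components$level[x$components$level !=
                                                            "unassigned"])),
                                       collapse = " ")) else " (unlabeled)",
              if (x$filtered) sprintf(", %d retained",
                                      sum(x$components$retained)) else ""))
  invisible(x)
}

#' @export
as.data.frame.vertebra_roiset <- function(x, ...) {
  df <- x$components
  df[, c("slice", "level", "area", "centroid_row", "centroid_col",
         "retained", "track")]
}

#' Extract per-slice connected components from a binary mask
#'
#' 8-connectivity labelling per slice; components smaller than `min_area_px`
#' are discarded as binarization speckle.
#'
#' @param mask A binary [mask_volume()].
#' @param min_area_px Minimum component area in pixels (default 20).
#' @return A `vertebra_roiset` with levels unassigned.
#' @export
extract_components <- function(mask, min_area_px = 20L) {
  stopifnot(inherits(mask, "mask_volume"))
  if (mask$kind != "binary")
    stopf("binarize first: extract_components() needs a binary mask")
  d <- dim(mask$data)
  rows <- list(); pixels <- list(); id <- 0L
  for (s in seq_len(d[1])) {
    m <- matrix(as.integer(mask$data[s, , ]), d[2], d[3])
    if (sum(m) == 0) next
    lab <- cpp_label_components(m, 8L)
    for (k in seq_len(attr(lab, "n"))) {
      px <- which(lab == k, arr.ind = TRUE)
      if (nrow(px) < min_area_px) next
      id <- id + 1L
      rows[[id]] <- data.frame(id = id, slice = s, area = nrow(px),
                               centroid_row = mean(px[, 1]),
                               centroid_col = mean(px[, 2]),
                               rmin = min(px[, 1]), rmax = max(px[, 1]),
                               level = "unassigned", track = NA_integer_,
                               retained = NA)
      pixels[[id]] <- px
    }
  }
  comps <- if (id > 0) do.call(rbind, rows)
  else data.frame(id = integer(), slice = integer(), area = integer(),
                  centroid_row = numeric(), centroid_col = numeric(),
                  rmin = integer(), rmax = integer(), level = character(),
                  track = integer(), retained = logical())
  new_roiset(d, comps, pixels, min_area_px)
}

#' Assign anatomical levels L1-L5 to extracted components
#'
#' Per-slice components are merged into body "tracks" by nearest-centroid
#' correspondence across slices. The five largest-by-peak-area tracks fully
#' contained in the image interior are labelled L1-L5 in superior-to-inferior
#' order; tracks touching the superior/inferior image border (partially
#' visible bodies) are labelled T12/S1 and excluded from quantification.
#'
#' @param roiset A `vertebra_roiset` from [extract_components()].
#' @param match_radius_px Maximum centroid displacement between consecutive
#'   slices for two components to belong to one body (default 15).
#' @param max_slice_gap Slices a track may skip and still be continued
#'   (default 1).
#' @return The roiset with `level` and `track` filled in. If fewer than five
#'   interior tracks exist, a warning is raised and the available tracks are
#'   labelled top-down.
#' @export
assign_vertebra_labels <- function(roiset, match_radius_px = 15,
                                   max_slice_gap = 1L) {
  stopifnot(inherits(roiset, "vertebra_roiset"))
  comps <- roiset$components
  if (nrow(comps) == 0) {
    warnf("insufficient vertebrae detected: no components")
    roiset$labeled <- TRUE
    return(roiset)
  }
  comps$track <- NA_integer_
  tracks <- list()   # each: list(last_slice, last_r, last_c, ids)
  for (s in sort(unique(comps$slice))) {
    ci <- which(comps$slice == s)
    open <- which(vapply(tracks, function(t)
      s - t$last_slice <= max_slice_gap + 1L, logical(1)))
    if (length(open) > 0 && length(ci) > 0) {
      dmat <- outer(seq_along(ci), seq_along(open),
                    Vectorize(function(a, b) {
                      tr <- tracks[[open[b]]]
                      sqrt((comps$centroid_row[ci[a]] - tr$last_r)^2 +
                             (comps$centroid_col[ci[a]] - tr$last_c)^2)
                    }))
      repeat {
        mn <- which(dmat == min(dmat), arr.ind = TRUE)[1, , drop = TRUE]
        if (!is.finite(dmat[mn[1], mn[2]]) ||
            dmat[mn[1], mn[2]] > match_radius_px) break
        a <- ci[mn[1]]; b <- open[mn[2]]
        comps$track[a] <- b
        tracks[[b]]$last_slice <- s
        tracks[[b]]$last_r <- comps$centroid_row[a]
        tracks[[b]]$last_c <- comps$centroid_col[a]
        tracks[[b]]$ids <- c(tracks[[b]]$ids, comps$id[a])
        dmat[mn[1], ] <- Inf
        dmat[, mn[2]] <- Inf
        if (all(!is.finite(dmat))) break
      }
    }
    for (a in ci[is.na(comps$track[ci])]) {
      tracks[[length(tracks) + 1L]] <-
        list(last_slice = s, last_r = comps$centroid_row[a],
             last_c = comps$centroid_col[a], ids = comps$id[a])
      comps$track[a] <- length(tracks)
    }
  }
  H <- roiset$shape[2]
  tr_stats <- lapply(seq_along(tracks), function(ti) {
    ids <- tracks[[ti]]$ids
    rows <- comps[comps$id %in% ids, ]
    list(peak_area = max(rows$area),
         mean_row = mean(rows$centroid_row),
         border = any(rows$rmin <= 1L) || any(rows$rmax >= H))
  })
  border <- vapply(tr_stats, `[[`, logical(1), "border")
  peak <- vapply(tr_stats, `[[`, numeric(1), "peak_area")
  mrow <- vapply(tr_stats, `[[`, numeric(1), "mean_row")
  interior <- which(!border)
  n_lab <- min(5L, length(interior))
  if (length(interior) < 5L)
    warnf("insufficient vertebrae detected: %d interior body track(s), 5 expected",
          length(interior))
  main <- interior[order(peak[interior], decreasing = TRUE)][seq_len(n_lab)]
  main <- main[order(mrow[main])]
  level_of_track <- rep("unassigned", length(tracks))
  level_of_track[main] <- .level_names[seq_len(n_lab)]
  for (ti in which(border))
    level_of_track[ti] <- if (mrow[ti] < H / 2) "T12" else "S1"
  comps$level <- level_of_track[comps$track]
  roiset$components <- comps
  roiset$labeled <- TRUE
  roiset
}

#' Apply the half-of-maximum-area inclusion rule
#'
#' For each lumbar level the reference area is the maximum component area
#' over all slices of that body; a slice's ROI is retained for fat
#' quantification iff its area strictly exceeds half the reference area
#' ("more than half the area of the corresponding vertebral body"). T12/S1
#' and unassigned components are never retained. Re-filtering is idempotent.
#'
#' @param roiset A labelled `vertebra_roiset`.
#' @return The roiset with `retained` filled in and per-level
#'   `reference_area` recorded.
#' @export
filter_rois_by_area <- function(roiset) {
  stopifnot(inherits(roiset, "vertebra_roiset"))
  if (!roiset$labeled) stopf("assign levels before filtering")
  comps <- roiset$components
  comps$retained <- FALSE
  refs <- c()
  for (lv in intersect(.level_names, unique(comps$level))) {
    li <- comps$level == lv
    ref <- max(comps$area[li])
    refs[lv] <- ref
    comps$retained[li] <- comps$area[li] > 0.5 * ref
  }
  roiset$components <- comps
  roiset$reference_area <- refs
  roiset$filtered <- TRUE
  roiset
}

#' Build a labelled ROI set directly from phantom ground truth
#'
#' Bypasses extraction/assignment: components and levels are read off the
#' ground-truth label volume. Useful as the "manual segmentation" arm when
#' evaluating the automatic pipeline.
#'
#' @param truth A `ground_truth` from [generate_phantom()].
#' @param filtered Apply [filter_rois_by_area()] before returning
#'   (default TRUE).
#' @return A labelled `vertebra_roiset`.
#' @export
roiset_from_truth <- function(truth, filtered = TRUE) {
  stopifnot(inherits(truth, "ground_truth"))
  d <- dim(truth$labels)
  code_to_level <- names(.level_codes)
  rows <- list(); pixels <- list(); id <- 0L
  for (s in seq_len(d[1])) {
    lab <- matrix(truth$labels[s, , ], d[2], d[3])
    for (code in sort(unique(lab[lab > 0]))) {
      px <- which(lab == code, arr.ind = TRUE)
      id <- id + 1L
      lv <- names(.level_codes)[match(code, .level_codes)]
      rows[[id]] <- data.frame(id = id, slice = s, area = nrow(px),
                               centroid_row = mean(px[, 1]),
                               centroid_col = mean(px[, 2]),
                               rmin = min(px[, 1]), rmax = max(px[, 1]),
                               level = if (is.na(lv)) "unassigned" else lv,
                               track = as.integer(code), retained = NA)
      pixels[[id]] <- px
    }
  }
  rs <- new_roiset(d, do.call(rbind, rows), pixels, 0L)
  rs$labeled <- TRUE
  if (filtered) rs <- filter_rois_by_area(rs)
  rs
}

#' Encode a labelled ROI set as a level-coded mask volume
#'
#' Pixel values encode the level: 1-5 for L1-L5, 11 for T12, 12 for S1,
#' 0 elsewhere (unassigned components are dropped).
#'
#' @param roiset A labelled `vertebra_roiset`.
#' @return An integer 3D array `[slice, row, col]`.
#' @export
roiset_to_labeled_mask <- function(roiset) {
  stopifnot(inherits(roiset, "vertebra_roiset"), roiset$labeled)
  out <- array(0L, roiset$shape)
  comps <- roiset$components
  for (i in seq_len(nrow(comps))) {
    lv <- comps$level[i]
    if (!lv %in% names(.level_codes)) next
    px <- roiset$pixels[[comps$id[i]]]
    out[cbind(comps$slice[i], px[, 1], px[, 2])] <- .level_codes[[lv]]
  }
  out
}
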
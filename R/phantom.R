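#' Specification of a synthetic spine phantom
#'
#' Describes the stated world the generator emulates: a sagittal 4-channel
#' IDEAL stack (default 20 slices of 256 x 256) in which a lordotic column of
#' five lumbar vertebral bodies is visible on a contiguous block of 5-7
#' mid-sagittal slices. Each body is a rounded (superelliptic) block of
#' trabecular marrow surrounded by a dark cortical rim that is excluded from
#' the ground-truth mask; confounder structures (high-FF subcutaneous fat
#' band, low-FF paraspinal muscle, intermediate-FF discs) make segmentation
#' non-trivial. Per-body true fat fractions are drawn from a normal
#' distribution centred at 33.1% (the control-cohort mean the pipeline is
#' anchored to) with SD `ff_sd_pct`, truncated to `[5, 70]`%.
#'
#' @param n_slices Number of sagittal slices (default 20).
#' @param image_size In-plane matrix size (default 256).
#' @param n_vertebrae Number of lumbar bodies, labelled L1 down (default 5).
#' @param visible_slice_range Integer range (min, max) of the number of
#'   mid-sagittal slices on which vertebrae appear (default `c(5, 7)`).
#' @param ff_mean_pct Centre of the per-body true fat fraction distribution,
#'   percent (default 33.1).
#' @param ff_sd_pct Between-body SD of true fat fraction, percent (default 8).
#' @param ff_heterogeneity_pct Within-body FF texture SD, percent; the
#'   texture is centred per body and slice so it never biases the body mean
#'   (default 1.5).
#' @param noise_sd Gaussian noise SD on the water and fat channels, relative
#'   to the mean tissue signal (default 0.05).
#' @param cortical_rim_px Rim thickness in pixels excluded from ground truth
#'   (default 2).
#' @param include_t12_sacrum Insert partially visible T12 and sacrum bodies
#'   touching the stack's superior/inferior image borders (default FALSE).
#' @param lordosis_curvature Relative anterior-posterior bowing of the spinal
#'   column (default 0.06).
#' @param seed Integer seed; the phantom is a deterministic function of the
#'   spec including this seed.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(n_slices = 20L, image_size = 256L, n_vertebrae = 5L,
                         visible_slice_range = c(5L, 7L),
                         ff_mean_pct = 33.1, ff_sd_pct = 8,
                         ff_heterogeneity_pct = 1.5, noise_sd = 0.05,
                         cortical_rim_px = 2L, include_t12_sacrum = FALSE,
                         lordosis_curvature = 0.06, seed = 1L) {
  spec <- list(n_slices = as.integer(n_slices),
               image_size = as.integer(image_size),
               n_vertebrae = as.integer(n_vertebrae),
               visible_slice_range = as.integer(visible_slice_range),
               ff_mean_pct = ff_mean_pct, ff_sd_pct = ff_sd_pct,
               ff_heterogeneity_pct = ff_heterogeneity_pct,
               noise_sd = noise_sd,
               cortical_rim_px = as.integer(cortical_rim_px),
               include_t12_sacrum = isTRUE(include_t12_sacrum),
               lordosis_curvature = lordosis_curvature,
               seed = as.integer(seed))
  class(spec) <- "phantom_spec"
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  v <- spec$visible_slice_range
  if (length(v) != 2L || v[1] > v[2] || v[1] < 1L || v[2] > spec$n_slices)
    stopf("visible_slice_range must lie within [1, n_slices]")
  if (spec$ff_mean_pct - 3 * spec$ff_sd_pct < 0 ||
      spec$ff_mean_pct + 3 * spec$ff_sd_pct > 100)
    stopf("ff_mean_pct +/- 3*ff_sd_pct must lie within [0, 100]")
  if (spec$noise_sd < 0 || spec$ff_heterogeneity_pct < 0)
    stopf("noise_sd and ff_heterogeneity_pct must be nonnegative")
  if (spec$n_vertebrae < 1L || spec$image_size < 32L || spec$n_slices < 1L)
    stopf("invalid phantom dimensions")
  if (spec$cortical_rim_px < 0L) stopf("cortical_rim_px must be >= 0")
  invisible(spec)
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(paste0("<phantom_spec> %d slices of %d x %d, %d bodies, ",
                     "FF ~ N(%.1f, %.1f)%%, noise %.3f, seed %d\n"),
              x$n_slices, x$image_size, x$image_size, x$n_vertebrae,
              x$ff_mean_pct, x$ff_sd_pct, x$noise_sd, x$seed))
  invisible(x)
}

# Superellipse (exponent 4) membership over a full slice grid; returns a
# logical matrix [row, col]. a = row half-axis, b = col half-axis.
superellipse_mask <- function(H, W, r0, c0, a, b, p = 4) {
  if (a <= 0 || b <= 0) return(matrix(FALSE, H, W))
  rows <- max(1L, floor(r0 - a)):min(H, ceiling(r0 + a))
  cols <- max(1L, floor(c0 - b)):min(W, ceiling(c0 + b))
  m <- matrix(FALSE, H, W)
  if (length(rows) == 0 || length(cols) == 0 ||
      rows[1] > H || cols[1] > W) return(m)
  dr <- abs(rows - r0) / a
  dc <- abs(cols - c0) / b
  m[rows, cols] <- outer(dr^p, dc^p, `+`) <= 1
  m
}

# Noise-free anatomy: tissue fields plus ground truth. Consumes RNG.
phantom_anatomy <- function(spec) {
  H <- spec$image_size; W <- spec$image_size; S <- spec$n_slices
  nV <- spec$n_vertebrae
  # --- per-subject anatomical parameters
  bh0 <- 0.11 * H; gap0 <- 0.04 * H; bw0 <- 0.16 * W
  body_scale <- runif(1, 0.92, 1.08)
  curv <- spec$lordosis_curvature * runif(1, 0.8, 1.2)
  col_center0 <- W * (0.42 + runif(1, -0.02, 0.02))
  levels <- .level_names[seq_len(min(nV, 5L))]
  if (nV > 5L) levels <- c(levels, paste0("X", seq_len(nV - 5L)))
  if (spec$include_t12_sacrum) levels <- c("T12", levels, "S1")
  nb <- length(levels)
  bh <- bh0 * body_scale * runif(nb, 0.94, 1.06)
  bw <- bw0 * body_scale * runif(nb, 0.94, 1.06)
  gap <- gap0 * runif(max(nb - 1L, 1L), 0.9, 1.1)
  if (spec$include_t12_sacrum) bh[nb] <- 2.2 * bh[nb]   # tall sacrum
  total <- sum(bh) + sum(gap[seq_len(nb - 1L)])
  top <- if (spec$include_t12_sacrum) -0.75 * bh[1] else (H - total) / 2
  r_center <- numeric(nb)
  cur <- top
  for (i in seq_len(nb)) {
    r_center[i] <- cur + bh[i] / 2
    cur <- cur + bh[i] + if (i < nb) gap[i] else 0
  }
  cc_of_row <- function(r) col_center0 + curv * W * (((r - H / 2) /
                                                       (H / 2))^2 - 0.5)
  c_center <- cc_of_row(r_center)
  # --- visible slice block
  vr <- spec$visible_slice_range
  V <- if (vr[1] == vr[2]) vr[1] else sample(seq(vr[1], vr[2]), 1)
  s0_max <- spec$n_slices - V + 1L
  s0_mid <- max(1L, as.integer(floor((spec$n_slices - V) / 2)) + 1L)
  s0 <- min(s0_max, max(1L, s0_mid + sample(-1:1, 1)))
  s_mid <- s0 + (V - 1) / 2
  slice_scale <- rep(0, S)
  vis <- s0:(s0 + V - 1L)
  slice_scale[vis] <- sqrt(pmax(0, 1 - ((vis - s_mid) / (V / 2 + 0.5))^2))
  # --- per-body true fat fraction, truncated normal
  draw_ff <- function(n) {
    out <- numeric(n)
    for (i in seq_len(n)) {
      repeat {
        x <- rnorm(1, spec$ff_mean_pct, spec$ff_sd_pct)
        if (x >= 5 && x <= 70) { out[i] <- x; break }
      }
    }
    out
  }
  true_ff <- draw_ff(nb)
  names(true_ff) <- levels
  # --- smooth 3D shading and R2* modulation fields (coarse grid, trilinear)
  shade_grid <- array(rnorm(4 * 6 * 6), c(4, 6, 6))
  r2_grid <- array(rnorm(4 * 6 * 6), c(4, 6, 6))
  interp_slices <- function(grid, s) {
    z <- 1 + (s - 1) / max(S - 1, 1) * (dim(grid)[1] - 1)
    z0 <- min(floor(z), dim(grid)[1] - 1); fz <- z - z0
    g <- grid[z0, , ] * (1 - fz) + grid[z0 + 1, , ] * fz
    bilinear_resize(g, H, W)
  }
  tex_fields <- lapply(seq_len(S), function(s)
    smooth_field_2d(H, W, grid = 12L))
  # --- paint tissues slice by slice
  ff_vol <- array(0, c(S, H, W))       # noise-free voxel fat fraction, %
  sig_vol <- array(0, c(S, H, W))      # total signal (water+fat), a.u.
  r2_vol <- array(0, c(S, H, W))
  labels <- array(0L, c(S, H, W))      # ground-truth marrow labels
  mus_cols <- max(1L, round(0.58 * W)):round(0.84 * W)
  fatb_cols <- round(0.86 * W):min(W, round(0.97 * W))
  for (s in seq_len(S)) {
    shade <- 1 + 0.15 * interp_slices(shade_grid, s)
    ffm <- matrix(0, H, W)
    sgm <- matrix(0.0, H, W)           # air: zero signal
    r2m <- matrix(20, H, W)
    # paraspinal muscle and subcutaneous fat bands (all slices)
    ffm[, mus_cols] <- 5;  sgm[, mus_cols] <- 0.9;  r2m[, mus_cols] <- 40
    ffm[, fatb_cols] <- 90; sgm[, fatb_cols] <- 1.3; r2m[, fatb_cols] <- 60
    sc <- slice_scale[s]
    if (sc > 0) {
      # intervertebral discs
      for (i in seq_len(nb - 1L)) {
        rg <- (r_center[i] + bh[i] / 2 + r_center[i + 1] - bh[i + 1] / 2) / 2
        disc <- superellipse_mask(H, W, rg, cc_of_row(rg),
                                  0.45 * gap[i] * sc + 0.5,
                                  0.45 * (bw[i] + bw[i + 1]) / 2 * sc, p = 2)
        ffm[disc] <- 20; sgm[disc] <- 0.8; r2m[disc] <- 35
      }
      # vertebral bodies: cortical rim (dark) around trabecular marrow
      for (i in seq_len(nb)) {
        a_out <- bh[i] / 2 * sc; b_out <- bw[i] / 2 * sc
        outer_m <- superellipse_mask(H, W, r_center[i], c_center[i],
                                     a_out, b_out)
        inner_m <- superellipse_mask(H, W, r_center[i], c_center[i],
                                     a_out - spec$cortical_rim_px,
                                     b_out - spec$cortical_rim_px)
        rim <- outer_m & !inner_m
        ffm[rim] <- 10; sgm[rim] <- 0.25; r2m[rim] <- 220
        if (any(inner_m)) {
          tex <- tex_fields[[s]][inner_m]
          tex <- tex - mean(tex)       # centred: never biases the body mean
          ffv <- true_ff[i] + spec$ff_heterogeneity_pct * tex
          ffm[inner_m] <- pmin(100, pmax(0, ffv))
          sgm[inner_m] <- 1.0
          r2m[inner_m] <- 160
          lab <- matrix(labels[s, , ], H, W)
          code <- if (levels[i] %in% names(.level_codes))
            .level_codes[[levels[i]]] else 20L + i
          lab[inner_m] <- code
          labels[s, , ] <- lab
        }
      }
    }
    sig_vol[s, , ] <- sgm * shade
    ff_vol[s, , ] <- ffm
    r2_vol[s, , ] <- pmax(0, r2m * (1 + 0.1 * interp_slices(r2_grid, s)))
  }
  list(spec = spec, ff = ff_vol, signal = sig_vol, r2star = r2_vol,
       labels = labels, true_ff = true_ff,
       visible_slices = vis, levels = levels)
}

# Apply the acquisition model to a noise-free anatomy: split signal into
# water/fat, add iid Gaussian noise to both channels, recompute the fat
# fraction from the noisy channels (preserving the fat/(fat+water) coupling)
# and clip to [0, 100].
phantom_apply_noise <- function(anat, noise_seed) {
  spec <- anat$spec
  fat0 <- anat$signal * anat$ff / 100
  water0 <- anat$signal * (1 - anat$ff / 100)
  r2 <- anat$r2star
  if (spec$noise_sd > 0) {
    tissue <- anat$signal > 1e-9
    s_mean <- mean(anat$signal[tissue])
    sdv <- spec$noise_sd * s_mean
    with_seed(noise_seed, {
      water0 <- water0 + rnorm(length(water0), 0, sdv)
      fat0 <- fat0 + rnorm(length(fat0), 0, sdv)
      r2 <- r2 * (1 + rnorm(length(r2), 0, spec$noise_sd))
    })
    water0 <- pmax(water0, 0)
    fat0 <- pmax(fat0, 0)
    r2 <- pmax(r2, 0)
  }
  denom <- water0 + fat0
  ff <- ifelse(denom > 1e-12, 100 * fat0 / denom, 0)
  ff <- pmin(pmax(ff, 0), 100)
  dixon_series(subject_id = sprintf("phantom_%d", spec$seed),
               water = water0, fat = fat0, fat_fraction = ff, r2star = r2,
               pixel_spacing_mm = c(1.375, 1.375) * 256 / spec$image_size,
               slice_thickness_mm = 4)
}

new_ground_truth <- function(anat) {
  structure(list(mask = mask_volume((anat$labels > 0) * 1, "binary"),
                 labels = anat$labels,
                 true_ff_pct = anat$true_ff,
                 visible_slices = anat$visible_slices,
                 spec = anat$spec),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %s; vertebrae on slices %d-%d\n",
              paste(sprintf("%s=%.1f%%", names(x$true_ff_pct),
                            x$true_ff_pct), collapse = " "),
              min(x$visible_slices), max(x$visible_slices)))
  invisible(x)
}

#' Generate a synthetic Dixon series with ground truth
#'
#' Deterministic for a fixed spec (including its seed): the anatomy and the
#' noise realisation are both derived from `spec$seed`. The voxel model is
#' `fat = S * FF/100`, `water = S * (1 - FF/100)` with `S` a smooth intensity
#' field; Gaussian noise is added to the water and fat channels and the fat
#' fraction channel is recomputed from the noisy channels, then clipped to
#' `[0, 100]`.
#'
#' @param spec A [phantom_spec()].
#' @return A list with elements `series` (a [dixon_series()]) and `truth`
#'   (a `ground_truth`: binary rim-excluded mask, per-component anatomical
#'   levels, and per-level true fat fractions).
#' @export
generate_phantom <- function(spec) {
  validate_phantom_spec(spec)
  seeds <- derive_seeds(spec$seed, 2L)
  anat <- with_seed(seeds[1], phantom_anatomy(spec))
  series <- phantom_apply_noise(anat, seeds[2])
  list(series = series, truth = new_ground_truth(anat))
}

#' Generate a test-retest phantom pair
#'
#' Same anatomy (identical ground truth), two independent noise realisations
#' -- the synthetic analogue of scanning a subject twice in one session.
#'
#' @param spec A [phantom_spec()].
#' @return A list with `test` and `retest` (each as [generate_phantom()]
#'   output sharing one `truth`).
#' @export
generate_retest_pair <- function(spec) {
  validate_phantom_spec(spec)
  seeds <- derive_seeds(spec$seed, 3L)
  anat <- with_seed(seeds[1], phantom_anatomy(spec))
  truth <- new_ground_truth(anat)
  list(test = list(series = phantom_apply_noise(anat, seeds[2]),
                   truth = truth),
       retest = list(series = phantom_apply_noise(anat, seeds[3]),
                     truth = truth))
}

#' Generate a phantom cohort
#'
#' Per-subject seeds are derived deterministically from `seed`; anatomy
#' (body sizes, curvature, per-body fat fractions) varies across subjects.
#' Selected spec parameters can additionally be varied uniformly within
#' stated ranges via `vary`.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param spec Base [phantom_spec()].
#' @param vary Named list of `c(min, max)` ranges for numeric spec fields,
#'   e.g. `list(ff_mean_pct = c(25, 45))`.
#' @param seed Master seed.
#' @param retest If TRUE, each element is a test-retest pair from
#'   [generate_retest_pair()] (same anatomy, fresh noise).
#' @return A list of [generate_phantom()] results (or retest pairs).
#' @export
generate_cohort <- function(n_subjects, spec = phantom_spec(), vary = list(),
                            seed = spec$seed, retest = FALSE) {
  if (n_subjects < 1) stopf("n_subjects must be >= 1")
  seeds <- derive_seeds(seed, n_subjects)
  draws <- list()
  if (length(vary) > 0) {
    draws <- with_seed(seed + 1L, {
      lapply(seq_len(n_subjects), function(i)
        vapply(vary, function(rg) runif(1, rg[1], rg[2]), numeric(1)))
    })
  }
  lapply(seq_len(n_subjects), function(i) {
    sp <- spec
    sp$seed <- seeds[i]
    if (length(vary) > 0)
      for (nm in names(vary)) sp[[nm]] <- unname(draws[[i]][nm])
    validate_phantom_spec(sp)
    out <- if (retest) generate_retest_pair(sp) else generate_phantom(sp)
    if (retest) {
      out$test$series$subject_id <- sprintf("sub%02d", i)
      out$retest$series$subject_id <- sprintf("sub%02d", i)
    } else {
      out$series$subject_id <- sprintf("sub%02d", i)
    }
    out
  })
}

#' Simulate a human rater's mask
#'
#' Emulates inter-rater variability: each body is dilated (`bias_px > 0`) or
#' eroded (`bias_px < 0`) with a square structuring element, then the
#' boundary is perturbed with seeded Bernoulli jitter of RMS magnitude
#' roughly `boundary_jitter_px`.
#'
#' @param truth A `ground_truth` (or binary [mask_volume()]).
#' @param bias_px Signed integer systematic over/under-segmentation.
#' @param boundary_jitter_px Nonnegative jitter magnitude in pixels.
#' @param seed Integer seed.
#' @return A binary [mask_volume()].
#' @export
simulate_rater <- function(truth, bias_px = 0L, boundary_jitter_px = 0,
                           seed = 1L) {
  mask <- if (inherits(truth, "ground_truth")) truth$mask else truth
  if (!is_binary_mask(mask)) stopf("simulate_rater needs a binary mask")
  d <- dim(mask$data)
  out <- array(0, d)
  with_seed(seed, {
    for (s in seq_len(d[1])) {
      m0 <- matrix(as.integer(mask$data[s, , ]), d[2], d[3])
      m <- m0
      if (bias_px != 0)
        m <- cpp_binary_morph(m, abs(as.integer(bias_px)), bias_px > 0)
      if (boundary_jitter_px > 0) {
        rounds <- max(1L, ceiling(boundary_jitter_px))
        p <- min(1, 0.5 * boundary_jitter_px / rounds)
        for (k in seq_len(rounds)) {
          dil <- cpp_binary_morph(m, 1L, TRUE)
          ero <- cpp_binary_morph(m, 1L, FALSE)
          outer_b <- which(dil == 1L & m == 0L)
          inner_b <- which(m == 1L & ero == 0L)
          add <- outer_b[runif(length(outer_b)) < p]
          drop <- inner_b[runif(length(inner_b)) < p]
          m[add] <- 1L
          m[drop] <- 0L
        }
      }
      if (sum(m0) > 0) {
        lab <- cpp_label_components(m0, 8L)
        ncomp <- attr(lab, "n")
        for (k in seq_len(ncomp)) {
          if (sum(m[lab == k]) == 0)
            stopf("degenerate rater mask: component annihilated on slice %d",
                  s)
        }
      }
      out[s, , ] <- m
    }
  })
  mask_volume(out, "binary")
}
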
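# BMF quantification: slice means, equal slice weighting, closure on the
# phantom, and the invariance/directionality properties.

test_that("slice_mean_ff is the arithmetic mean over the pixel set", {
  ff <- matrix(40, 10, 10)
  px <- cbind(c(2, 3, 4), c(2, 3, 4))
  expect_equal(slice_mean_ff(ff, px)$mean_ff_pct, 40)
  ff[cbind(c(2, 3, 4), c(2, 3, 4))] <- c(10, 20, 30)
  expect_equal(slice_mean_ff(ff, px)$mean_ff_pct, 20)
  # summation oracle on a random 50-pixel set
  set.seed(14)
  ffr <- matrix(runif(400, 0, 100), 20, 20)
  sel <- sample(400, 50)
  px <- cbind((sel - 1) %% 20 + 1, (sel - 1) %/% 20 + 1)
  expect_equal(slice_mean_ff(ffr, px)$mean_ff_pct, sum(ffr[px]) / 50)
  expect_error(slice_mean_ff(ffr, px[0, , drop = FALSE]), "empty")
  expect_error(slice_mean_ff(ffr, cbind(25, 1)), "out of bounds")
  # non-finite pixels excluded and counted
  ffn <- matrix(c(10, NaN, 30, Inf), 2, 2)
  r <- slice_mean_ff(ffn, cbind(c(1, 2, 1, 2), c(1, 1, 2, 2)))
  expect_equal(r$mean_ff_pct, 20)
  expect_equal(r$n_pixels, 2)
  expect_equal(r$n_nonfinite, 2)
})

test_that("vertebra mean weights slices equally, not by pixel count", {
  expect_equal(vertebra_mean_bmf(c(30, 40), n_pixels = c(100, 10)), 35)
  expect_equal(vertebra_mean_bmf(c(30, 40), n_pixels = c(100, 10),
                                 weighted = TRUE), 3400 / 110)
  expect_equal(vertebra_mean_bmf(33.1), 33.1)
  expect_true(is.na(vertebra_mean_bmf(numeric(0))))
  set.seed(5)
  v <- runif(5, 0, 100)
  expect_equal(vertebra_mean_bmf(v), sum(v) / 5)
})

test_that("noise-free closure: quantified BMF equals the stated truth exactly", {
  p <- generate_phantom(tiny_spec(seed = 6, noise_sd = 0,
                                  ff_heterogeneity_pct = 0))
  rep <- quantify_bmf(p$series, roiset_from_truth(p$truth))
  expect_equal(sort(rep$summary$level), paste0("L", 1:5))
  expect_equal(rep$summary$mean_bmf_pct,
               unname(p$truth$true_ff_pct[rep$summary$level]),
               tolerance = 1e-12)
  # heterogeneity is centred per body and slice, so closure still holds
  p2 <- generate_phantom(tiny_spec(seed = 6, noise_sd = 0,
                                   ff_heterogeneity_pct = 2))
  rep2 <- quantify_bmf(p2$series, roiset_from_truth(p2$truth))
  expect_equal(rep2$summary$mean_bmf_pct,
               unname(p2$truth$true_ff_pct[rep2$summary$level]),
               tolerance = 1e-9)
})

test_that("quantification is invariant to slice order and ROI erosion on
           constant-FF bodies", {
  p <- generate_phantom(tiny_spec(seed = 16, noise_sd = 0,
                                  ff_heterogeneity_pct = 0))
  rs <- roiset_from_truth(p$truth)
  rep1 <- quantify_bmf(p$series, rs)
  # permute component order
  rs2 <- rs
  perm <- rev(seq_len(nrow(rs2$components)))
  rs2$components <- rs2$components[perm, ]
  rep2 <- quantify_bmf(p$series, rs2)
  expect_equal(rep1$summary[order(rep1$summary$level), "mean_bmf_pct"],
               rep2$summary[order(rep2$summary$level), "mean_bmf_pct"])
  # uniform erosion of every ROI leaves constant-FF means unchanged
  eroded <- p$truth$mask$data
  for (s in seq_len(dim(eroded)[1])) {
    m <- matrix(as.integer(eroded[s, , ]), dim(eroded)[2], dim(eroded)[3])
    eroded[s, , ] <- spinefat:::cpp_binary_morph(m, 1L, FALSE)
  }
  truth_e <- p$truth
  truth_e$labels[eroded == 0] <- 0L
  truth_e$mask <- mask_volume(eroded * 1, "binary")
  rs_e <- roiset_from_truth(truth_e)
  rep_e <- quantify_bmf(p$series, rs_e)
  common <- intersect(rep1$summary$level, rep_e$summary$level)
  expect_equal(rep_e$summary$mean_bmf_pct[match(common, rep_e$summary$level)],
               rep1$summary$mean_bmf_pct[match(common, rep1$summary$level)],
               tolerance = 1e-12)
})

test_that("ROI overreach biases BMF toward the neighbouring tissue's FF", {
  # partial-volume directionality: dilated ROIs absorb the cortical rim
  # (FF 10%), discs (20%) and air (0%), so for bodies with marrow FF above
  # those values the reported BMF must strictly decrease; the magnitude of
  # the bias grows with the overreach.
  p <- generate_phantom(phantom_spec(seed = 26, noise_sd = 0))
  rep0 <- quantify_bmf(p$series, roiset_from_truth(p$truth))
  bias_of <- function(px) {
    dil <- simulate_rater(p$truth, bias_px = px, boundary_jitter_px = 0)
    rs <- suppressWarnings(assign_vertebra_labels(extract_components(dil)))
    quantify_bmf(p$series, rs)$summary
  }
  d2 <- bias_of(2); d4 <- bias_of(4)
  lv <- names(p$truth$true_ff_pct)[p$truth$true_ff_pct > 25]
  lv <- Reduce(intersect, list(lv, rep0$summary$level, d2$level, d4$level))
  expect_gte(length(lv), 3)
  b0 <- rep0$summary$mean_bmf_pct[match(lv, rep0$summary$level)]
  b2 <- d2$mean_bmf_pct[match(lv, d2$level)]
  b4 <- d4$mean_bmf_pct[match(lv, d4$level)]
  expect_true(all(b2 < b0))
  expect_true(all(b4 < b2))
})

test_that("noisy-phantom BMF stays within the noise-propagated band", {
  # Monte-Carlo oracle: many noise realisations of one anatomy give the
  # sampling SD of each body's mask-mean FF; fresh realisations must land
  # within a 99% band around the true value.
  set.seed(99)
  spec <- tiny_spec(seed = 33, noise_sd = 0.05)
  seeds <- spinefat:::derive_seeds(spec$seed, 2L)
  anat <- spinefat:::with_seed(seeds[1], spinefat:::phantom_anatomy(spec))
  levels <- paste0("L", 1:5)
  codes <- spinefat:::.level_codes[levels]
  mc <- replicate(300, {
    ser <- spinefat:::phantom_apply_noise(anat, sample.int(2^30, 1))
    vapply(codes, function(cd) mean(ser$fat_fraction[anat$labels == cd]),
           numeric(1))
  })
  truth <- anat$true_ff[levels]
  mc_err <- mc - truth
  ctr <- rowMeans(mc_err)             # ratio-estimator noise bias
  sds <- apply(mc_err, 1, sd)
  fresh <- replicate(60, {
    ser <- spinefat:::phantom_apply_noise(anat, sample.int(2^30, 1))
    vapply(codes, function(cd) mean(ser$fat_fraction[anat$labels == cd]),
           numeric(1))
  })
  inside <- abs((fresh - truth) - ctr) <= 2.576 * sds
  expect_gte(mean(inside), 0.95)
  # the noise-propagated uncertainty itself stays small at 5% channel noise
  expect_true(all(abs(ctr) + 2.576 * sds < 2))
})
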
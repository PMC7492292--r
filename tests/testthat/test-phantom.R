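# Synthetic phantom generator: determinism, closure to the stated truth,
# cohort/retest structure, rater simulation.

test_that("phantom generation is deterministic for a fixed spec", {
  sp <- tiny_spec(seed = 5)
  a <- generate_phantom(sp)
  b <- generate_phantom(sp)
  expect_identical(a$series$water, b$series$water)
  expect_identical(a$series$fat_fraction, b$series$fat_fraction)
  expect_identical(a$truth$mask$data, b$truth$mask$data)
  expect_identical(a$truth$true_ff_pct, b$truth$true_ff_pct)
})

test_that("generated series satisfy the data-model invariants", {
  for (seed in 1:3) {
    p <- generate_phantom(tiny_spec(seed = seed))
    s <- p$series
    expect_identical(dim(s$water), dim(s$fat))
    expect_identical(dim(s$water), dim(s$fat_fraction))
    expect_identical(dim(s$water), dim(s$r2star))
    expect_true(all(s$water >= 0) && all(s$fat >= 0) && all(s$r2star >= 0))
    expect_true(all(s$fat_fraction >= 0 & s$fat_fraction <= 100))
    expect_true(all(p$truth$mask$data %in% c(0, 1)))
    nv <- length(p$truth$visible_slices)
    expect_true(nv >= 4 && nv <= 5)
    # vertebrae only on a contiguous mid-stack block
    has_mask <- which(apply(p$truth$mask$data, 1, sum) > 0)
    expect_identical(has_mask, p$truth$visible_slices)
    expect_true(all(diff(has_mask) == 1))
  }
})

test_that("noise-free phantoms close exactly on the stated fat fractions", {
  p <- generate_phantom(tiny_spec(seed = 2, noise_sd = 0,
                                  ff_heterogeneity_pct = 0))
  for (lv in names(p$truth$true_ff_pct)) {
    code <- spinefat:::.level_codes[[lv]]
    sel <- p$truth$labels == code
    expect_equal(mean(p$series$fat_fraction[sel]),
                 unname(p$truth$true_ff_pct[lv]), tolerance = 1e-12)
  }
})

test_that("increasing ff_mean strictly increases mask-mean FF (noise-free)", {
  means <- vapply(c(20, 33.1, 45), function(mu) {
    p <- generate_phantom(tiny_spec(seed = 9, noise_sd = 0, ff_mean_pct = mu,
                                    ff_sd_pct = 5))
    mean(p$series$fat_fraction[p$truth$mask$data == 1])
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("cohort generation is reproducible, varied, and retest-capable", {
  co <- generate_cohort(5, tiny_spec(), seed = 42)
  co2 <- generate_cohort(5, tiny_spec(), seed = 42)
  expect_identical(co[[3]]$series$water, co2[[3]]$series$water)
  # distinct anatomies across subjects
  ffs <- t(vapply(co, function(x) x$truth$true_ff_pct[1:5], numeric(5)))
  expect_true(nrow(unique(round(ffs, 6))) == 5)
  # n = 1 equals generate_phantom at the derived seed
  co1 <- generate_cohort(1, tiny_spec(), seed = 7)
  seed1 <- spinefat:::derive_seeds(7, 1)[1]
  sp <- tiny_spec(); sp$seed <- seed1
  solo <- generate_phantom(sp)
  expect_identical(co1[[1]]$series$fat_fraction, solo$series$fat_fraction)
  # vary ranges are respected
  cov <- generate_cohort(6, tiny_spec(), vary = list(ff_mean_pct = c(25, 41)),
                         seed = 11)
  mus <- vapply(cov, function(x) x$truth$spec$ff_mean_pct, numeric(1))
  expect_true(all(mus >= 25 & mus <= 41) && length(unique(mus)) > 1)
  # retest pairs: identical truth, different voxels
  rt <- generate_cohort(2, tiny_spec(), seed = 13, retest = TRUE)
  for (pair in rt) {
    expect_identical(pair$test$truth$mask$data, pair$retest$truth$mask$data)
    expect_identical(pair$test$truth$true_ff_pct,
                     pair$retest$truth$true_ff_pct)
    expect_false(identical(pair$test$series$water,
                           pair$retest$series$water))
  }
})

test_that("invalid phantom specs are rejected", {
  expect_error(phantom_spec(visible_slice_range = c(5, 25)),
               "visible_slice_range")
  expect_error(phantom_spec(ff_mean_pct = 90, ff_sd_pct = 8), "ff_mean_pct")
  expect_error(phantom_spec(noise_sd = -0.1), "nonnegative")
})

test_that("simulate_rater reproduces, dilates and jitters as specified", {
  p <- generate_phantom(tiny_spec(seed = 4, noise_sd = 0))
  # identity
  r0 <- simulate_rater(p$truth, bias_px = 0, boundary_jitter_px = 0)
  expect_identical(r0$data, p$truth$mask$data)
  # dilation increment matches the brute-force oracle on a synthetic square
  sq <- array(0, c(1L, 24L, 24L)); sq[1, 8:17, 8:17] <- 1
  gt <- structure(list(mask = mask_volume(sq, "binary")),
                  class = "ground_truth")
  r1 <- simulate_rater(gt$mask, bias_px = 1, boundary_jitter_px = 0)
  expect_identical(matrix(as.integer(r1$data[1, , ]), 24, 24),
                   oracle_dilate(matrix(as.integer(sq[1, , ]), 24, 24), 1))
  expect_equal(sum(r1$data), 144)     # 10x10 -> 12x12
  # jitter is seeded and produces a valid binary mask
  j1 <- simulate_rater(p$truth, bias_px = 0, boundary_jitter_px = 1, seed = 2)
  j2 <- simulate_rater(p$truth, bias_px = 0, boundary_jitter_px = 1, seed = 2)
  expect_identical(j1$data, j2$data)
  expect_true(all(j1$data %in% c(0, 1)))
  expect_false(identical(j1$data, p$truth$mask$data))
  # two raters with opposite bias: 0 < kappa < 1
  ra <- simulate_rater(p$truth, bias_px = 1, boundary_jitter_px = 0.5,
                       seed = 5)
  rb <- simulate_rater(p$truth, bias_px = -1, boundary_jitter_px = 0.5,
                       seed = 6)
  k <- cohen_kappa(as.vector(ra$data), as.vector(rb$data))$kappa
  expect_true(k > 0 && k < 1)
  # over-erosion annihilates a component -> degenerate error
  expect_error(simulate_rater(p$truth, bias_px = -4), "degenerate rater mask")
})
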
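# U-Net construction, the soft-Jaccard loss, backprop correctness, training
# bookkeeping, inference determinism, binarization.

test_that("build_unet enforces the input contract and emits probabilities", {
  m <- build_unet(c(64, 64), n_channels = 4, model_scale = 0.25, seed = 1)
  expect_s3_class(m, "unet")
  expect_equal(m$layer_defs$e1c1$cin, 4)
  expect_equal(m$layer_defs$final$cout, 1)
  x <- array(rnorm(64 * 64 * 4 * 2), c(64, 64, 4, 2))
  p <- spinefat:::unet_forward(m, x)$p
  expect_equal(dim(p), c(64L, 64L, 1L, 2L))
  expect_true(all(p >= 0 & p <= 1))
  # reduced models are valid; indivisible sizes are not
  expect_s3_class(build_unet(c(256, 256), model_scale = 0.25, seed = 1),
                  "unet")
  expect_error(build_unet(c(250, 250)), "divisible")
})

test_that("jaccard distance loss matches its definition and contracts", {
  y <- matrix(0, 8, 8); y[3:4, 3:4] <- 1          # 4-pixel square
  # identity: loss = s/(A+s) exactly
  expect_equal(jaccard_distance_loss(y, y, smooth = 100), 1 - 104 / 104)
  expect_equal(jaccard_distance_loss(y, y, smooth = 0), 0)
  # total miss: ones vs zeros
  y1 <- matrix(1, 8, 8)
  expect_equal(jaccard_distance_loss(y1, matrix(0, 8, 8), smooth = 1e-9),
               1, tolerance = 1e-6)
  # brute-force pixel-sum oracle: y_pred = 0.5 everywhere
  p <- matrix(0.5, 8, 8)
  i <- sum(y * p); u <- sum(y) + sum(p) - i
  expect_equal(jaccard_distance_loss(y, p, smooth = 100),
               1 - (i + 100) / (u + 100))
  expect_error(jaccard_distance_loss(y, matrix(0.5, 4, 4)), "shape")
  expect_error(jaccard_distance_loss(p, p), "binary")
})

test_that("loss -> 0 as smooth -> 0 for random binary masks, and equals 1-IoU", {
  set.seed(42)
  for (rep in 1:20) {
    y <- matrix(rbinom(100, 1, runif(1, 0.1, 0.9)), 10, 10)
    expect_lt(jaccard_distance_loss(y, y, smooth = 1e-12), 1e-10)
    yp <- matrix(rbinom(100, 1, 0.5), 10, 10)
    cc <- confusion_counts(array(yp, c(1, 10, 10)), array(y, c(1, 10, 10)),
                           scope = "all_slices")
    iou <- overlap_scores(cc)$iou
    if (cc$tp + cc$fp + cc$fn > 0)
      expect_equal(jaccard_distance_loss(y, yp, smooth = 0), 1 - iou)
  }
})

test_that("analytic gradients match numerical gradients", {
  set.seed(3)
  m <- build_unet(c(8, 8), n_channels = 2, model_scale = 0.05, depth = 1,
                  base_filters = 8, seed = 9)
  x <- array(rnorm(8 * 8 * 2), c(8, 8, 2, 1))
  t <- array(rbinom(64, 1, 0.3), c(8, 8, 1, 1))
  fw <- spinefat:::unet_forward(m, x, cache = TRUE)
  lg <- spinefat:::jaccard_loss_grad(t, fw$p, smooth = 10)
  gr <- spinefat:::unet_backward(m, lg$dp, fw$cache)
  lossfn <- function(mm)
    spinefat:::jaccard_loss_grad(t, spinefat:::unet_forward(mm, x)$p, 10)$loss
  eps <- 1e-5
  for (nm in names(m$params)) {
    w <- m$params[[nm]]$wt
    ks <- sample(length(w), min(4, length(w)))
    for (k in ks) {
      m2 <- m; m2$params[[nm]]$wt[k] <- w[k] + eps
      m3 <- m; m3$params[[nm]]$wt[k] <- w[k] - eps
      num <- (lossfn(m2) - lossfn(m3)) / (2 * eps)
      expect_equal(gr[[nm]]$wt[k], num, tolerance = 1e-5)
    }
  }
})

test_that("training bookkeeping: epochs, determinism, best-so-far restore", {
  spec <- tiny_spec(seed = 8)
  cohort <- generate_cohort(2, spec, seed = 55)
  cfg <- train_config(max_epochs = 1, model_scale = 0.1, smooth = 1,
                      seed = 4, validation_fraction = 0.4)
  m1 <- train_unet(cohort, cfg)
  expect_equal(nrow(m1$history), 1L)
  expect_true(m1$trained)
  m2 <- train_unet(cohort, cfg)
  expect_identical(m1$history$val_loss, m2$history$val_loss)
  expect_identical(m1$params$final$wt, m2$params$final$wt)
  expect_error(train_unet(cohort[1], cfg), "at least 2 subjects")
  # best-so-far validation sequence is non-increasing
  fx <- trained_fixture()
  best_seq <- cummin(fx$model$history$val_loss)
  expect_true(all(diff(best_seq) <= 0))
  # restored weights reproduce the best recorded validation loss
  expect_equal(min(fx$model$history$val_loss),
               fx$model$history$val_loss[which.min(fx$model$history$val_loss)])
})

test_that("inference is deterministic, shape-checked, and separates classes", {
  fx <- trained_fixture()
  p <- generate_phantom(tiny_spec(seed = 31, noise_sd = 0))
  pr1 <- predict(fx$model, p$series, type = "prob")
  pr2 <- predict(fx$model, p$series, type = "prob")
  expect_identical(pr1$data, pr2$data)
  expect_equal(dim(pr1$data), dim(p$series$water))
  expect_true(all(pr1$data >= 0 & pr1$data <= 1))
  inmask <- pr1$data[p$truth$mask$data == 1]
  outmask <- pr1$data[p$truth$mask$data == 0]
  expect_gt(mean(inmask), mean(outmask))
  bad <- p$series
  bad$water <- bad$water[, 1:32, ]
  dim(bad$water) <- c(dim(bad$water)[1], 32, dim(bad$water)[3])
  expect_error(predict(fx$model, array(0, c(32, 64, 4, 2))), "geometry")
})

test_that("binarize uses a strict threshold and complements correctly", {
  pm <- mask_volume(array(c(0.49, 0.5, 0.51, 0, 1, 0.3), c(1, 2, 3)),
                    "probability")
  b <- binarize(pm, 0.5)
  expect_equal(as.vector(b$data), c(0, 0, 1, 0, 1, 0))
  expect_error(binarize(pm, 1.2), "threshold")
  expect_error(binarize(b, 0.5), "probability mask")
  # complementation: binarize(p) == 1 - binarize(1-p) except exact ties
  set.seed(9)
  p <- array(runif(500), c(5, 10, 10))
  b1 <- binarize(mask_volume(p, "probability"), 0.5)$data
  b2 <- 1 - binarize(mask_volume(1 - p, "probability"), 0.5)$data
  ties <- p == 0.5
  expect_identical(b1[!ties], b2[!ties])
  # all-zero probabilities -> all-zero mask
  expect_true(all(binarize(mask_volume(array(0, c(1, 4, 4)),
                                       "probability"))$data == 0))
})

test_that("model checkpoints round-trip", {
  fx <- trained_fixture()
  f <- tempfile(fileext = ".rds")
  save_unet(fx$model, f)
  m <- load_unet(f)
  p <- generate_phantom(tiny_spec(seed = 77))
  expect_identical(predict(m, p$series)$data,
                   predict(fx$model, p$series)$data)
})
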
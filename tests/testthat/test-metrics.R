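# Evaluation statistics against independent brute-force oracles and
# hand-computed examples.

test_that("confusion counts match the per-pixel oracle and honour scope", {
  set.seed(31)
  for (rep in 1:20) {
    d <- c(3L, 10L, 10L)
    pred <- array(rbinom(prod(d), 1, 0.4), d)
    truth <- array(rbinom(prod(d), 1, 0.3), d)
    truth[1, , ] <- 0                       # one vertebra-free slice
    cc <- confusion_counts(pred, truth, "all_slices")
    oc <- oracle_confusion(pred, truth)
    expect_identical(cc[c("tp", "fp", "fn", "tn")], oc)
    expect_equal(cc$tp + cc$fp + cc$fn + cc$tn, prod(d))
    ccs <- confusion_counts(pred, truth, "vertebra_slices_only")
    ocs <- oracle_confusion(pred[-1, , ], truth[-1, , ])
    expect_identical(ccs[c("tp", "fp", "fn", "tn")], ocs)
  }
  # perfect prediction and complement
  t0 <- array(c(rep(1, 30), rep(0, 70)), c(1L, 10L, 10L))
  cc <- confusion_counts(t0, t0, "all_slices")
  expect_equal(unlist(cc[c("tp", "tn", "fp", "fn")]),
               c(tp = 30, tn = 70, fp = 0, fn = 0))
  cc2 <- confusion_counts(1 - t0, t0, "all_slices")
  expect_equal(cc2$tp + cc2$tn, 0)
  expect_error(confusion_counts(t0, array(0, c(2, 10, 10))), "geometry")
})

test_that("overlap and classification scores satisfy the printed identities", {
  mk <- function(tp, fp, fn, tn)
    structure(list(tp = tp, fp = fp, fn = fn, tn = tn),
              class = "confusion_counts")
  ov <- overlap_scores(mk(2, 1, 1, 96))
  expect_equal(ov$dsc, 2 * 2 / 6)
  expect_equal(ov$iou, 0.5)
  expect_equal(overlap_scores(mk(30, 0, 0, 70)), list(dsc = 1, iou = 1))
  expect_equal(overlap_scores(mk(0, 0, 0, 100)), list(dsc = 1, iou = 1))
  cs <- classification_scores(mk(8, 5, 2, 85))
  expect_equal(cs$sensitivity, 0.8)
  expect_equal(cs$specificity, 85 / 90, tolerance = 1e-10)
  expect_equal(cs$precision, 8 / 13, tolerance = 1e-10)
  expect_equal(cs$accuracy, 0.93)
  expect_equal(cs$f1, 2 * (8 / 13) * 0.8 / ((8 / 13) + 0.8),
               tolerance = 1e-10)
  perfect <- classification_scores(mk(10, 0, 0, 90))
  expect_true(all(unlist(perfect) == 1))
  # degenerate denominators surface as missing values
  expect_true(is.na(classification_scores(mk(0, 0, 0, 10))$sensitivity))
  # algebraic identities on random counts
  set.seed(8)
  for (rep in 1:200) {
    k <- mk(sample(0:50, 1), sample(0:50, 1), sample(0:50, 1),
            sample(0:50, 1))
    if (k$tp + k$fp + k$fn == 0) next
    ov <- overlap_scores(k)
    expect_equal(ov$dsc, 2 * ov$iou / (1 + ov$iou), tolerance = 1e-12)
    cs <- classification_scores(k)
    if (!is.na(cs$f1)) expect_equal(cs$f1, ov$dsc, tolerance = 1e-12)
  }
})

test_that("DeLong AUC equals pair counting and is monotone-invariant", {
  set.seed(77)
  # tie conventions
  expect_equal(roc_auc_delong(c(1, 2, 3, 4), c(0, 0, 1, 1))$auc, 1)
  expect_equal(roc_auc_delong(rep(2, 10), rep(c(0, 1), 5))$auc, 0.5)
  expect_error(roc_auc_delong(1:4, rep(1, 4)), "both classes")
  for (rep in 1:50) {
    n <- 200
    sc <- round(runif(n), 2)           # induce ties
    lb <- rbinom(n, 1, 0.35)
    if (length(unique(lb)) < 2) next
    r <- roc_auc_delong(sc, lb)
    expect_equal(r$auc, oracle_auc(sc, lb), tolerance = 1e-12)
    expect_true(r$ci_low <= r$auc && r$auc <= r$ci_high)
    # strictly monotone transform leaves the AUC unchanged
    r2 <- roc_auc_delong(exp(3 * sc) + 1, lb)
    expect_equal(r2$auc, r$auc, tolerance = 1e-12)
  }
})

test_that("PR AUC equals the exhaustive threshold sweep and its limits", {
  set.seed(91)
  expect_equal(pr_auc(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1)), 1)
  expect_error(pr_auc(1:4, rep(0, 4)), "no positives")
  for (rep in 1:50) {
    n <- 50
    sc <- round(runif(n), 1)
    lb <- rbinom(n, 1, 0.4)
    if (sum(lb) == 0) next
    expect_equal(pr_auc(sc, lb), oracle_pr_auc(sc, lb), tolerance = 1e-12)
  }
  # random scores at prevalence pi approach pi for large n
  n <- 20000
  lb <- rbinom(n, 1, 0.3)
  sc <- runif(n)
  expect_equal(pr_auc(sc, lb), 0.3, tolerance = 0.03)
})

test_that("Cohen's kappa matches the hand example and the table oracle", {
  k <- cohen_kappa(c(1, 1, 0, 0, 1), c(1, 0, 0, 0, 1))
  expect_equal(k$p_o, 0.8)
  expect_equal(k$p_e, 0.6 * 0.4 + 0.4 * 0.6)
  expect_equal(k$kappa, (0.8 - 0.48) / 0.52, tolerance = 1e-12)
  expect_equal(cohen_kappa(c(0, 1, 1), c(0, 1, 1))$kappa, 1)
  # linear weighting degenerates to unweighted for two classes
  expect_equal(cohen_kappa(c(1, 1, 0, 0, 1), c(1, 0, 0, 0, 1),
                           weighting = "linear")$kappa, k$kappa)
  # constant-and-equal raters; constant-but-different raters
  expect_equal(cohen_kappa(rep(1, 5), rep(1, 5))$kappa, 1)
  expect_warning(k0 <- cohen_kappa(rep(1, 5), rep(0, 5))$kappa,
                 "constant")
  expect_equal(k0, 0)
  set.seed(12)
  for (rep in 1:50) {
    a <- rbinom(100, 1, runif(1, 0.2, 0.8))
    b <- rbinom(100, 1, runif(1, 0.2, 0.8))
    if (sd(a) == 0 || sd(b) == 0) next
    expect_equal(cohen_kappa(a, b)$kappa, oracle_kappa(a, b),
                 tolerance = 1e-12)
  }
  # independent raters: kappa near zero for large n
  a <- rbinom(50000, 1, 0.3); b <- rbinom(50000, 1, 0.6)
  expect_lt(abs(cohen_kappa(a, b)$kappa), 0.02)
})

test_that("ROC/PR curve points are monotone and end at (1,1)", {
  set.seed(55)
  sc <- round(runif(300), 2)
  lb <- rbinom(300, 1, 0.4)
  pts <- roc_pr_points(sc, lb)
  expect_true(all(diff(pts$fpr) >= 0) && all(diff(pts$tpr) >= 0))
  expect_equal(pts$fpr[nrow(pts)], 1)
  expect_equal(pts$tpr[nrow(pts)], 1)
  expect_equal(pts$recall, pts$tpr)
  # trapezoid over the ROC points reproduces the tie-corrected AUC
  fpr <- c(0, pts$fpr); tpr <- c(0, pts$tpr)
  trap <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  expect_equal(trap, roc_auc_delong(sc, lb)$auc, tolerance = 1e-12)
})

test_that("Bland-Altman bias, limits and equivariance are correct", {
  # identical pairs
  ba0 <- bland_altman(c(10, 20, 30), c(10, 20, 30))
  expect_equal(ba0$bias, 0)
  expect_equal(ba0$loa_high - ba0$loa_low, 0)
  # differences exactly {-1, 0, 1}
  ba1 <- bland_altman(c(9, 20, 31), c(10, 20, 30))
  expect_equal(ba1$bias, 0)
  expect_equal(ba1$sd_diff, 1)
  expect_equal(c(ba1$loa_low, ba1$loa_high), c(-1.96, 1.96))
  expect_error(bland_altman(1:2, 2:3), "at least 3")
  # Monte-Carlo consistency at the geometry of the larger test set
  set.seed(20)
  n <- 5000
  d <- rnorm(n, -0.605, 1.362)
  b <- runif(n, 25, 45)
  ba <- bland_altman(b + d, b)
  expect_equal(ba$bias, -0.605, tolerance = 0.05)
  expect_equal(ba$loa_low, -0.605 - 1.96 * 1.362, tolerance = 0.08)
  expect_equal(ba$loa_high, -0.605 + 1.96 * 1.362, tolerance = 0.08)
  expect_true(ba$loa_low <= ba$bias && ba$bias <= ba$loa_high)
  # equivariance: shifting both members leaves the bias; shifting one moves it
  ba2 <- bland_altman(b + d + 7, b + 7)
  expect_equal(ba2$bias, ba$bias, tolerance = 1e-10)
  ba3 <- bland_altman(b + d + 7, b)
  expect_equal(ba3$bias, ba$bias + 7, tolerance = 1e-10)
})

test_that("repeatability: ICC recovery, degenerate regime, precision error", {
  # identical test-retest -> ICC 1, precision error 0
  r <- repeatability(c(30, 35, 40, 28), c(30, 35, 40, 28))
  expect_equal(r$table$icc[1], 1)
  expect_equal(r$table$precision_error_pct[1], 0)
  # hand arithmetic for one pair's CV
  r2 <- repeatability(c(30, 40), c(31, 40))
  cv1 <- (abs(30 - 31) / sqrt(2)) / 30.5 * 100
  expect_equal(r2$table$precision_error_pct[1],
               sqrt(mean(c(cv1^2, 0))), tolerance = 1e-10)
  expect_equal(cv1, 2.318, tolerance = 1e-3)
  # variance-component recovery: ICC -> sb^2/(sb^2+sw^2)
  set.seed(44)
  sb <- 6; sw <- 2; n <- 500
  subj <- rnorm(n, 33.1, sb)
  t1 <- subj + rnorm(n, 0, sw)
  t2 <- subj + rnorm(n, 0, sw)
  ri <- repeatability(t1, t2)
  expect_equal(ri$table$icc[1], sb^2 / (sb^2 + sw^2), tolerance = 0.02)
  # per-level grouping
  lv <- rep(paste0("L", 1:5), each = 100)
  rl <- repeatability(t1, t2, level = lv)
  expect_equal(nrow(rl$table), 6)
  expect_error(repeatability(c(1, NA), c(1, 2)), "positions")
})
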
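# Evaluation statistics: pixel confusion counts, overlap and classification
# scores, Cohen's kappa, ROC AUC with DeLong variance, precision-recall AUC,
# Bland-Altman agreement, and test-retest repeatability (ICC + short-term
# precision error).

#' Pixel confusion counts between two binary masks
#'
#' @param pred,truth Binary [mask_volume()]s of equal shape (or plain binary
#'   arrays).
#' @param scope `"vertebra_slices_only"` tallies only slices on which the
#'   truth mask has at least one positive pixel (the convention used when
#'   evaluating against manual segmentations); `"all_slices"` tallies the
#'   whole volume.
#' @return An object of class `confusion_counts` with fields `tp`, `fp`,
#'   `fn`, `tn` and the scope descriptor.
#' @export
confusion_counts <- function(pred, truth,
                             scope = c("vertebra_slices_only",
                                       "all_slices")) {
  scope <- match.arg(scope)
  p <- if (inherits(pred, "mask_volume")) pred$data else pred
  t <- if (inherits(truth, "mask_volume")) truth$data else truth
  if (inherits(pred, "mask_volume") && pred$kind != "binary")
    stopf("binarize first: confusion counts need binary masks")
  if (!identical(dim(p), dim(t)))
    stopf("geometry mismatch: %s vs %s", paste(dim(p), collapse = "x"),
          paste(dim(t), collapse = "x"))
  if (!all(p %in% c(0, 1)) || !all(t %in% c(0, 1)))
    stopf("confusion counts need binary masks")
  keep <- rep(TRUE, if (length(dim(t)) == 3L) dim(t)[1] else 1L)
  if (scope == "vertebra_slices_only" && length(dim(t)) == 3L) {
    keep <- apply(t, 1, function(x) any(x > 0))
    if (!any(keep)) stopf("no slices with vertebral segmentations in scope")
    p <- p[keep, , , drop = FALSE]
    t <- t[keep, , , drop = FALSE]
  }
  structure(list(tp = sum(p == 1 & t == 1), fp = sum(p == 1 & t == 0),
                 fn = sum(p == 0 & t == 1), tn = sum(p == 0 & t == 0),
                 scope = scope, n_slices = sum(keep)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> TP %d FP %d FN %d TN %d (%s, %d slices)\n",
              x$tp, x$fp, x$fn, x$tn, x$scope, x$n_slices))
  invisible(x)
}

#' Dice and Jaccard overlap from confusion counts
#'
#' `DSC = 2 TP / (2 TP + FP + FN)` and `IoU = TP / (TP + FP + FN)`. If both
#' masks are empty in scope the overlap is defined as perfect (1).
#'
#' @param counts A `confusion_counts`.
#' @return List with `dsc` and `iou`.
#' @export
overlap_scores <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn
  if (tp + fp + fn == 0) return(list(dsc = 1, iou = 1))
  list(dsc = 2 * tp / (2 * tp + fp + fn), iou = tp / (tp + fp + fn))
}

#' Classification scores from confusion counts
#'
#' Standard definitions; any score with a zero denominator is returned as
#' `NA`. Note `f1` is algebraically identical to the Dice coefficient
#' computed from the same counts.
#'
#' @param counts A `confusion_counts`.
#' @return List with `sensitivity`, `specificity`, `precision`, `f1`,
#'   `accuracy`.
#' @export
classification_scores <- function(counts) {
  safe <- function(num, den) if (den > 0) num / den else NA_real_
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn; tn <- counts$tn
  sens <- safe(tp, tp + fn)
  spec <- safe(tn, tn + fp)
  prec <- safe(tp, tp + fp)
  f1 <- if (!is.na(sens) && !is.na(prec) && (prec + sens) > 0)
    2 * prec * sens / (prec + sens) else safe(2 * tp, 2 * tp + fp + fn)
  list(sensitivity = sens, specificity = spec, precision = prec,
       f1 = f1, accuracy = safe(tp + tn, tp + fp + fn + tn))
}

#' ROC AUC with DeLong variance
#'
#' AUC as the normalized Mann-Whitney statistic (ties credited 1/2);
#' standard error from DeLong's structural components; 95% CI
#' `auc +/- 1.96 SE`, clipped to `[0, 1]`.
#'
#' @param scores Numeric scores (e.g. predicted probabilities).
#' @param labels Binary labels (0/1 or logical), both classes present.
#' @return List with `auc`, `se`, `ci_low`, `ci_high`.
#' @export
roc_auc_delong <- function(scores, labels) {
  labels <- as.numeric(labels)
  if (length(scores) != length(labels)) stopf("length mismatch")
  if (!all(labels %in% c(0, 1))) stopf("labels must be binary")
  m <- sum(labels == 1); n <- sum(labels == 0)
  if (m == 0 || n == 0) stopf("both classes must be present")
  x <- scores[labels == 1]; y <- scores[labels == 0]
  r_all <- rank(c(x, y), ties.method = "average")
  v10 <- (r_all[seq_len(m)] - rank(x, ties.method = "average")) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - rank(y, ties.method = "average")) / m
  auc <- mean(v10)
  se <- sqrt(var(v10) / m + var(v01) / n)
  list(auc = auc, se = se,
       ci_low = max(0, auc - 1.96 * se),
       ci_high = min(1, auc + 1.96 * se))
}

#' Area under the precision-recall curve
#'
#' Step-wise integration over the unique score thresholds, descending; no
#' precision envelope (interpolation) is applied:
#' `AUC = sum_i (R_i - R_{i-1}) * P_i`.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels with at least one positive.
#' @return Scalar AUC.
#' @export
pr_auc <- function(scores, labels) {
  labels <- as.numeric(labels)
  if (length(scores) != length(labels)) stopf("length mismatch")
  pos <- sum(labels == 1)
  if (pos == 0) stopf("no positives present")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; l <- labels[o]
  grp_end <- which(diff(s) != 0)
  grp_end <- c(grp_end, length(s))
  ctp <- cumsum(l)[grp_end]
  cn <- grp_end
  recall <- ctp / pos
  precision <- ctp / cn
  sum(diff(c(0, recall)) * precision)
}

#' Cohen's kappa for two pixel annotators
#'
#' `kappa = (p_o - p_e) / (1 - p_e)` where `p_o` is the observed agreement
#' ratio and `p_e` the chance agreement from per-annotator empirical class
#' priors. For two classes, linear weighting coincides with the unweighted
#' statistic (`weighting` is accepted for interface parity and documented as
#' degenerate).
#'
#' @param labels_a,labels_b Binary label vectors of equal length.
#' @param weighting `"none"` or `"linear"` (identical for two classes).
#' @return List with `kappa`, `p_o`, `p_e`.
#' @export
cohen_kappa <- function(labels_a, labels_b, weighting = c("none", "linear")) {
  weighting <- match.arg(weighting)
  a <- as.numeric(labels_a); b <- as.numeric(labels_b)
  if (length(a) != length(b)) stopf("length mismatch")
  if (!all(a %in% c(0, 1)) || !all(b %in% c(0, 1)))
    stopf("labels must be binary")
  p_o <- mean(a == b)
  pa1 <- mean(a); pb1 <- mean(b)
  p_e <- pa1 * pb1 + (1 - pa1) * (1 - pb1)
  if (p_e >= 1) {
    kappa <- if (p_o >= 1) 1 else 0
  } else if ((pa1 %in% c(0, 1)) && (pb1 %in% c(0, 1)) && pa1 != pb1) {
    warnf("both annotators constant but different; kappa set to 0")
    kappa <- 0
  } else {
    kappa <- (p_o - p_e) / (1 - p_e)
  }
  list(kappa = kappa, p_o = p_o, p_e = p_e)
}

#' Bland-Altman agreement analysis
#'
#' Differences are oriented as `a - b` (use the manual measurement as `a` and
#' the automatic one as `b`, so a negative bias means the automatic method
#' reads higher). Limits of agreement are `bias +/- 1.96 SD` of the
#' differences (sample SD, n-1 denominator); the bias CI is
#' `bias +/- 1.96 SD / sqrt(n)`.
#'
#' @param a,b Paired measurements (>= 3 pairs), e.g. per-vertebra BMF in
#'   percent.
#' @return An object of class `bland_altman` with `bias`, `bias_ci`,
#'   `loa_low`, `loa_high`, `sd_diff`, `pct_outside` (percent of differences
#'   outside the LOA) and the pairs.
#' @export
bland_altman <- function(a, b) {
  if (length(a) != length(b)) stopf("length mismatch")
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  if (n < 3) stopf("Bland-Altman analysis needs at least 3 pairs")
  d <- a - b
  bias <- mean(d)
  s <- sd(d)
  loa_low <- bias - 1.96 * s
  loa_high <- bias + 1.96 * s
  structure(list(n = n, bias = bias, sd_diff = s,
                 bias_ci = c(bias - 1.96 * s / sqrt(n),
                             bias + 1.96 * s / sqrt(n)),
                 loa_low = loa_low, loa_high = loa_high,
                 pct_outside = 100 * mean(d < loa_low | d > loa_high),
                 mean_ab = (a + b) / 2, diff = d),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("<bland_altman> n = %d pairs\n", x$n))
  cat(sprintf("  bias %+.3f%% (95%% CI %+.3f to %+.3f)\n", x$bias,
              x$bias_ci[1], x$bias_ci[2]))
  cat(sprintf("  limits of agreement %+.3f to %+.3f; %.1f%% outside\n",
              x$loa_low, x$loa_high, x$pct_outside))
  invisible(x)
}

#' @export
plot.bland_altman <- function(x, xlab = "mean of methods (%)",
                              ylab = "difference (%)", ...) {
  plot(x$mean_ab, x$diff, xlab = xlab, ylab = ylab,
       ylim = range(c(x$diff, x$loa_low, x$loa_high)), ...)
  abline(h = x$bias, lty = 1)
  abline(h = c(x$loa_low, x$loa_high), lty = 2)
  invisible(x)
}

# ICC(2,1): two-way random effects, absolute agreement, single measure,
# from the paired-measurement ANOVA decomposition (k = 2 occasions).
icc_2_1 <- function(x1, x2) {
  n <- length(x1); k <- 2
  if (n < 2) return(NA_real_)
  dat <- cbind(x1, x2)
  row_means <- rowMeans(dat)
  col_means <- colMeans(dat)
  grand <- mean(dat)
  msr <- k * sum((row_means - grand)^2) / (n - 1)
  msc <- n * sum((col_means - grand)^2) / (k - 1)
  sse <- sum((dat - outer(row_means, rep(1, k)) -
                outer(rep(1, n), col_means) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + k * (msc - mse) / n
  if (denom <= 0) return(if (msr == 0) NA_real_ else 1)
  (msr - mse) / denom
}

#' Test-retest repeatability: ICC and short-term precision error
#'
#' The intraclass correlation is the two-way random-effects,
#' absolute-agreement, single-measure form ICC(2,1). The short-term precision
#' error is the root-mean-square coefficient of variation across subjects,
#' with the two-point SD `|test - retest| / sqrt(2)`:
#' `PE% = sqrt(mean_i((sd_i / mean_i * 100)^2))`.
#'
#' @param test,retest Paired measurements (same subjects/levels, same order).
#' @param level Optional factor (e.g. vertebral level L1-L5) for per-level
#'   results in addition to the pooled ones.
#' @return An object of class `repeatability_result`: data frame with
#'   columns `group`, `icc`, `precision_error_pct`, `n_pairs`.
#' @export
repeatability <- function(test, retest, level = NULL) {
  if (length(test) != length(retest)) stopf("length mismatch")
  miss <- which(!is.finite(test) | !is.finite(retest))
  if (length(miss) > 0)
    stopf("unpaired or missing entries at positions: %s",
          paste(miss, collapse = ", "))
  one <- function(t1, t2, group) {
    cv <- (abs(t1 - t2) / sqrt(2)) / ((t1 + t2) / 2) * 100
    data.frame(group = group, icc = icc_2_1(t1, t2),
               precision_error_pct = sqrt(mean(cv^2)),
               n_pairs = length(t1))
  }
  out <- one(test, retest, "pooled")
  if (!is.null(level)) {
    level <- as.character(level)
    for (lv in sort(unique(level))) {
      i <- level == lv
      if (sum(i) >= 2) out <- rbind(out, one(test[i], retest[i], lv))
    }
  }
  structure(list(table = out), class = "repeatability_result")
}

#' @export
print.repeatability_result <- function(x, ...) {
  cat("<repeatability_result>\n")
  for (i in seq_len(nrow(x$table)))
    cat(sprintf("  %-7s ICC %.3f, precision error %.2f%% (n = %d)\n",
                x$table$group[i], x$table$icc[i],
                x$table$precision_error_pct[i], x$table$n_pairs[i]))
  invisible(x)
}

#' ROC and precision-recall curve points
#'
#' Curve coordinates over the unique score thresholds (descending), suitable
#' for plotting; the same conventions as [roc_auc_delong()] and [pr_auc()].
#'
#' @param scores Numeric scores.
#' @param labels Binary labels.
#' @return A data frame: `threshold`, `fpr`, `tpr` (sensitivity),
#'   `precision`, `recall`.
#' @export
roc_pr_points <- function(scores, labels) {
  labels <- as.numeric(labels)
  pos <- sum(labels == 1); neg <- sum(labels == 0)
  if (pos == 0 || neg == 0) stopf("both classes must be present")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; l <- labels[o]
  grp_end <- c(which(diff(s) != 0), length(s))
  ctp <- cumsum(l)[grp_end]
  cfp <- grp_end - ctp
  data.frame(threshold = s[grp_end], fpr = cfp / neg, tpr = ctp / pos,
             precision = ctp / grp_end, recall = ctp / pos)
}

plot_roc_pr_png <- function(scores, labels, path) {
  pts <- roc_pr_points(scores, labels)
  grDevices::png(path, width = 900, height = 440)
  op <- par(mfrow = c(1, 2))
  plot(c(0, pts$fpr, 1), c(0, pts$tpr, 1), type = "l",
       xlab = "1 - specificity", ylab = "sensitivity", main = "ROC")
  abline(0, 1, lty = 3)
  plot(c(0, pts$recall), c(1, pts$precision), type = "s",
       xlab = "recall", ylab = "precision", ylim = c(0, 1),
       main = "precision-recall")
  par(op)
  grDevices::dev.off()
  invisible(path)
}

#' Full segmentation agreement report
#'
#' Bundles the battery used to evaluate a predicted segmentation against a
#' reference: confusion counts, DSC/IoU, classification scores, Cohen's
#' kappa, ROC AUC with DeLong CI and PR AUC (the latter two from the
#' probability map when given).
#'
#' @param pred Binary predicted [mask_volume()].
#' @param truth Binary reference [mask_volume()].
#' @param prob Optional probability [mask_volume()] for the ROC/PR AUCs.
#' @param scope Evaluation scope, see [confusion_counts()].
#' @return A list (class `agreement_report`).
#' @export
agreement_report <- function(pred, truth, prob = NULL,
                             scope = c("vertebra_slices_only",
                                       "all_slices")) {
  scope <- match.arg(scope)
  cc <- confusion_counts(pred, truth, scope)
  ov <- overlap_scores(cc)
  cs <- classification_scores(cc)
  kap <- cohen_kappa(scoped_pixels(pred, truth, scope),
                     scoped_pixels(truth, truth, scope))
  out <- c(list(counts = cc), ov, cs,
           list(kappa = kap$kappa, p_o = kap$p_o, p_e = kap$p_e))
  if (!is.null(prob)) {
    sc <- scoped_pixels(prob, truth, scope)
    lb <- scoped_pixels(truth, truth, scope)
    roc <- roc_auc_delong(sc, lb)
    out$roc_auc <- roc$auc
    out$roc_auc_ci <- c(roc$ci_low, roc$ci_high)
    out$pr_auc <- pr_auc(sc, lb)
  }
  class(out) <- "agreement_report"
  out
}

scoped_pixels <- function(vol, truth, scope) {
  v <- if (inherits(vol, "mask_volume")) vol$data else vol
  t <- if (inherits(truth, "mask_volume")) truth$data else truth
  if (scope == "vertebra_slices_only") {
    keep <- apply(t, 1, function(x) any(x > 0))
    as.vector(v[keep, , , drop = FALSE])
  } else {
    as.vector(v)
  }
}

#' @export
print.agreement_report <- function(x, ...) {
  cat("<agreement_report>\n")
  cat(sprintf("  DSC %.3f  IoU %.3f  kappa %.3f\n", x$dsc, x$iou, x$kappa))
  cat(sprintf("  sensitivity %.3f  specificity %.3f  precision %.3f  accuracy %.3f\n",
              x$sensitivity, x$specificity, x$precision, x$accuracy))
  if (!is.null(x$roc_auc))
    cat(sprintf("  ROC AUC %.3f (95%% CI %.4f-%.4f)  PR AUC %.3f\n",
                x$roc_auc, x$roc_auc_ci[1], x$roc_auc_ci[2], x$pr_auc))
  invisible(x)
}
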
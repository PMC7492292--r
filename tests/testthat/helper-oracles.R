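# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths.

# Flood-fill connected-component count (BFS, pure R).
oracle_count_components <- function(m, connectivity = 8) {
  H <- nrow(m); W <- ncol(m)
  seen <- matrix(FALSE, H, W)
  nb <- if (connectivity == 8)
    cbind(c(-1, 1, 0, 0, -1, -1, 1, 1), c(0, 0, -1, 1, -1, 1, -1, 1))
  else cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  count <- 0
  for (c0 in seq_len(W)) for (r0 in seq_len(H)) {
    if (m[r0, c0] == 0 || seen[r0, c0]) next
    count <- count + 1
    queue <- list(c(r0, c0)); seen[r0, c0] <- TRUE
    while (length(queue) > 0) {
      p <- queue[[1]]; queue <- queue[-1]
      for (k in seq_len(nrow(nb))) {
        r <- p[1] + nb[k, 1]; c <- p[2] + nb[k, 2]
        if (r >= 1 && r <= H && c >= 1 && c <= W && m[r, c] != 0 &&
            !seen[r, c]) {
          seen[r, c] <- TRUE
          queue[[length(queue) + 1]] <- c(r, c)
        }
      }
    }
  }
  count
}

# Chebyshev (square structuring element) dilation by brute force.
oracle_dilate <- function(m, r) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(0L, H, W)
  for (c0 in seq_len(W)) for (r0 in seq_len(H)) {
    rs <- max(1, r0 - r):min(H, r0 + r)
    cs <- max(1, c0 - r):min(W, c0 + r)
    out[r0, c0] <- as.integer(any(m[rs, cs] == 1))
  }
  out
}

# Per-pixel confusion tally.
oracle_confusion <- function(pred, truth) {
  list(tp = sum(pred == 1 & truth == 1), fp = sum(pred == 1 & truth == 0),
       fn = sum(pred == 0 & truth == 1), tn = sum(pred == 0 & truth == 0))
}

# All-pairs AUC with half credit for ties.
oracle_auc <- function(scores, labels) {
  x <- scores[labels == 1]; y <- scores[labels == 0]
  tot <- 0
  for (xi in x) tot <- tot + sum(xi > y) + 0.5 * sum(xi == y)
  tot / (length(x) * length(y))
}

# Exhaustive-threshold PR AUC (step-wise, no envelope).
oracle_pr_auc <- function(scores, labels) {
  thr <- sort(unique(scores), decreasing = TRUE)
  pos <- sum(labels == 1)
  rec_prev <- 0; auc <- 0
  for (t in thr) {
    sel <- scores >= t
    tp <- sum(labels[sel] == 1)
    rec <- tp / pos
    prec <- tp / sum(sel)
    auc <- auc + (rec - rec_prev) * prec
    rec_prev <- rec
  }
  auc
}

# Contingency-table kappa.
oracle_kappa <- function(a, b) {
  tab <- table(factor(a, c(0, 1)), factor(b, c(0, 1)))
  n <- sum(tab)
  p_o <- sum(diag(tab)) / n
  p_e <- sum(rowSums(tab) * colSums(tab)) / n^2
  (p_o - p_e) / (1 - p_e)
}

# Bootstrap SE of the AUC.
oracle_bootstrap_auc_se <- function(scores, labels, reps = 2000) {
  n <- length(scores)
  aucs <- replicate(reps, {
    i <- sample.int(n, n, replace = TRUE)
    if (length(unique(labels[i])) < 2) return(NA_real_)
    spinefat::roc_auc_delong(scores[i], labels[i])$auc
  })
  stats::sd(aucs, na.rm = TRUE)
}

# A small noise-free phantom spec shared by several tests.
tiny_spec <- function(seed = 1, ...) {
  phantom_spec(image_size = 64, n_slices = 8, visible_slice_range = c(4, 5),
               cortical_rim_px = 1, seed = seed, ...)
}

# Shared trained-model fixture: built once per test run (a few subjects, a
# few epochs; enough to separate marrow from background on easy phantoms).
.fixture_env <- new.env(parent = emptyenv())

trained_fixture <- function() {
  if (!is.null(.fixture_env$model)) return(.fixture_env)
  spec <- tiny_spec(seed = 3)
  cohort <- generate_cohort(6, spec, seed = 101)
  cfg <- train_config(max_epochs = 4, early_stopping_patience = 4,
                      model_scale = 0.25, smooth = 1, seed = 7,
                      validation_fraction = 0.2)
  .fixture_env$model <- train_unet(cohort, cfg)
  .fixture_env$spec <- spec
  .fixture_env$cohort <- cohort
  .fixture_env
}
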
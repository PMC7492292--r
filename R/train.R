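#' Training configuration for the U-Net
#'
#' Defaults mirror the reference training recipe: Adam with learning rate
#' 1e-4, batch size 4, up to 100 epochs with early stopping on validation
#' loss, a roughly 7-in-31 subject-level validation holdout, and a 0.5
#' binarization threshold.
#'
#' @param learning_rate Adam learning rate (default 1e-4).
#' @param batch_size Slices per gradient step (default 4).
#' @param max_epochs Maximum epochs (default 100).
#' @param early_stopping_patience Epochs without validation improvement
#'   before stopping; best weights are restored (default 10).
#' @param validation_fraction Fraction of subjects held out for validation
#'   (default 7/31).
#' @param threshold Binarization threshold in (0, 1) (default 0.5).
#' @param seed Seed controlling the split, shuffling and weight init.
#' @param model_scale Channel-width multiplier for models built by
#'   [train_unet()] (default 1).
#' @param smooth Smooth term of the Jaccard distance loss (default 100).
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-4, batch_size = 4L,
                         max_epochs = 100L, early_stopping_patience = 10L,
                         validation_fraction = 7 / 31, threshold = 0.5,
                         seed = 1L, model_scale = 1, smooth = 100) {
  if (threshold <= 0 || threshold >= 1)
    stopf("threshold must lie strictly inside (0, 1)")
  if (batch_size < 1) stopf("batch_size must be >= 1")
  if (max_epochs < 1) stopf("max_epochs must be >= 1")
  if (validation_fraction <= 0 || validation_fraction >= 1)
    stopf("validation_fraction must lie in (0, 1)")
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 early_stopping_patience = as.integer(early_stopping_patience),
                 validation_fraction = validation_fraction,
                 threshold = threshold, seed = as.integer(seed),
                 model_scale = model_scale, smooth = smooth),
            class = "train_config")
}

adam_init <- function(params) {
  lapply(params, function(p) list(mw = p$wt * 0, vw = p$wt * 0,
                                  mb = p$b * 0, vb = p$b * 0))
}

adam_step <- function(params, grads, state, lr, t, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  bc1 <- 1 - beta1^t; bc2 <- 1 - beta2^t
  for (nm in names(params)) {
    g <- grads[[nm]]; s <- state[[nm]]
    s$mw <- beta1 * s$mw + (1 - beta1) * g$wt
    s$vw <- beta2 * s$vw + (1 - beta2) * g$wt^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$b
    s$vb <- beta2 * s$vb + (1 - beta2) * g$b^2
    params[[nm]]$wt <- params[[nm]]$wt -
      lr * (s$mw / bc1) / (sqrt(s$vw / bc2) + eps)
    params[[nm]]$b <- params[[nm]]$b -
      lr * (s$mb / bc1) / (sqrt(s$vb / bc2) + eps)
    state[[nm]] <- s
  }
  list(params = params, state = state)
}

# Normalize a cohort element to list(series=, mask=).
cohort_item <- function(x) {
  if (!is.null(x$mask) && inherits(x$mask, "mask_volume"))
    return(list(series = x$series, mask = x$mask))
  if (!is.null(x$truth) && inherits(x$truth, "ground_truth"))
    return(list(series = x$series, mask = x$truth$mask))
  stopf("cohort elements must carry a series and a mask (or ground truth)")
}

#' Train the U-Net on a cohort
#'
#' The fitting function of the package. Every slice of every subject enters
#' training (including vertebra-free slices); no cropping or intensity
#' normalization is applied. The subject-level validation holdout is drawn
#' from `config$seed`; early stopping monitors validation loss with the
#' configured patience and the best-validation-loss weights are restored.
#'
#' @param cohort List of subjects, each a list with a [dixon_series()] and a
#'   binary mask (`$mask`, or `$truth$mask` as produced by
#'   [generate_phantom()]). At least 2 subjects (1 train + 1 validation).
#' @param config A [train_config()].
#' @param model Optionally a pre-built [build_unet()] model; by default one
#'   is built to match the cohort geometry at `config$model_scale`.
#' @return The trained `unet` object with `$history` (one row per epoch:
#'   training and validation loss) and the config snapshot.
#' @export
train_unet <- function(cohort, config = train_config(), model = NULL) {
  if (length(cohort) < 2L)
    stopf("need at least 2 subjects (1 training + 1 validation)")
  items <- lapply(cohort, cohort_item)
  xs <- lapply(items, function(it) series_to_input(it$series))
  ys <- lapply(items, function(it) {
    m <- it$mask
    check_same_shape(m, it$series, "mask and series")
    d <- dim(m$data)
    y <- array(0, c(d[2], d[3], 1L, d[1]))
    for (s in seq_len(d[1])) y[, , 1L, s] <- m$data[s, , ]
    y
  })
  H <- dim(xs[[1]])[1]; W <- dim(xs[[1]])[2]
  if (is.null(model))
    model <- build_unet(c(H, W), n_channels = 4L,
                        model_scale = config$model_scale,
                        seed = config$seed)
  if (!identical(model$input_size, c(H, W)))
    stopf("model input contract %dx%d does not match cohort %dx%d",
          model$input_size[1], model$input_size[2], H, W)
  n_sub <- length(items)
  n_val <- max(1L, round(config$validation_fraction * n_sub))
  if (n_val >= n_sub) n_val <- n_sub - 1L
  with_seed(config$seed, {
    val_sub <- sort(sample.int(n_sub, n_val))
    train_sub <- setdiff(seq_len(n_sub), val_sub)
    idx <- do.call(rbind, lapply(train_sub, function(i)
      cbind(i, seq_len(dim(xs[[i]])[4]))))
    vidx <- do.call(rbind, lapply(val_sub, function(i)
      cbind(i, seq_len(dim(xs[[i]])[4]))))
    gather <- function(ix) {
      nb <- nrow(ix)
      xb <- array(0, c(H, W, 4L, nb))
      yb <- array(0, c(H, W, 1L, nb))
      for (j in seq_len(nb)) {
        xb[, , , j] <- xs[[ix[j, 1]]][, , , ix[j, 2]]
        yb[, , 1L, j] <- ys[[ix[j, 1]]][, , 1L, ix[j, 2]]
      }
      list(x = xb, y = yb)
    }
    eval_loss <- function(ix) {
      tot <- 0
      starts <- seq(1L, nrow(ix), by = config$batch_size)
      for (st in starts) {
        rows <- st:min(st + config$batch_size - 1L, nrow(ix))
        b <- gather(ix[rows, , drop = FALSE])
        p <- unet_forward(model, b$x)$p
        tot <- tot + jaccard_loss_grad(b$y, p, config$smooth)$loss *
          length(rows)
      }
      tot / nrow(ix)
    }
    if (!isTRUE(model$calibrated)) {
      cal_rows <- idx[unique(round(seq(1, nrow(idx),
                                       length.out = min(8, nrow(idx))))), ,
                      drop = FALSE]
      model <- calibrate_unet(model, gather(cal_rows)$x)
    }
    state <- adam_init(model$params)
    tstep <- 0L
    best_val <- Inf; best_params <- model$params; wait <- 0L
    hist <- list()
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample.int(nrow(idx))
      ep_loss <- 0
      starts <- seq(1L, nrow(idx), by = config$batch_size)
      for (st in starts) {
        rows <- ord[st:min(st + config$batch_size - 1L, nrow(idx))]
        b <- gather(idx[rows, , drop = FALSE])
        fw <- unet_forward(model, b$x, cache = TRUE)
        lg <- jaccard_loss_grad(b$y, fw$p, config$smooth)
        if (!is.finite(lg$loss))
          stopf("training aborted: non-finite loss at epoch %d", epoch)
        ep_loss <- ep_loss + lg$loss * length(rows)
        grads <- unet_backward(model, lg$dp, fw$cache)
        tstep <- tstep + 1L
        upd <- adam_step(model$params, grads, state, config$learning_rate,
                         tstep)
        model$params <- upd$params
        state <- upd$state
      }
      val_loss <- eval_loss(vidx)
      hist[[epoch]] <- data.frame(epoch = epoch,
                                  train_loss = ep_loss / nrow(idx),
                                  val_loss = val_loss)
      if (val_loss < best_val - 1e-9) {
        best_val <- val_loss
        best_params <- model$params
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$early_stopping_patience) break
      }
    }
    model$params <- best_params
  })
  model$trained <- TRUE
  model$history <- do.call(rbind, hist)
  model$config <- config
  model$validation_subjects <- val_sub
  model
}

#' Predict a segmentation probability map
#'
#' Per-slice deterministic inference over all slices of a series.
#'
#' @param object A trained (or untrained) `unet`.
#' @param newdata A [dixon_series()] or a `[H, W, 4, n]` input array.
#' @param type `"prob"` for the probability map, `"mask"` for the binarized
#'   mask at `threshold`.
#' @param threshold Binarization threshold used when `type = "mask"`.
#' @param batch_size Slices per forward pass.
#' @param ... Unused.
#' @return A [mask_volume()] (probability or binary).
#' @export
predict.unet <- function(object, newdata, type = c("prob", "mask"),
                         threshold = NULL, batch_size = 4L, ...) {
  type <- match.arg(type)
  x <- if (inherits(newdata, "dixon_series")) series_to_input(newdata)
  else newdata
  if (length(dim(x)) != 4L || dim(x)[3] != object$n_channels)
    stopf("input must be [H, W, %d, n]", object$n_channels)
  if (!identical(as.integer(dim(x)[1:2]), object$input_size))
    stopf("geometry mismatch: model expects %dx%d, got %dx%d",
          object$input_size[1], object$input_size[2], dim(x)[1], dim(x)[2])
  n <- dim(x)[4]
  out <- array(0, c(n, dim(x)[1], dim(x)[2]))
  for (st in seq(1L, n, by = batch_size)) {
    sl <- st:min(st + batch_size - 1L, n)
    p <- unet_forward(object, x[, , , sl, drop = FALSE])$p
    for (j in seq_along(sl)) out[sl[j], , ] <- p[, , 1, j]
  }
  prob <- mask_volume(out, "probability")
  if (type == "prob") return(prob)
  thr <- threshold %||% object$config$threshold %||% 0.5
  binarize(prob, thr)
}

#' Binarize a probability mask
#'
#' A pixel becomes 1 iff its probability strictly exceeds `threshold`
#' (ties at the threshold go to background).
#'
#' @param prob A probability [mask_volume()].
#' @param threshold Threshold in (0, 1) (default 0.5).
#' @return A binary [mask_volume()].
#' @export
binarize <- function(prob, threshold = 0.5) {
  stopifnot(inherits(prob, "mask_volume"))
  if (prob$kind != "probability")
    stopf("binarize() expects a probability mask")
  if (threshold <= 0 || threshold >= 1)
    stopf("threshold must lie strictly inside (0, 1)")
  mask_volume((prob$data > threshold) * 1, "binary")
}

#' Save / load a model checkpoint
#'
#' Single-file archive holding parameters, config snapshot and history.
#'
#' @param model A `unet` object.
#' @param path Checkpoint path (`.rds`).
#' @return `save_unet`: `path` invisibly; `load_unet`: the `unet`.
#' @export
save_unet <- function(model, path) {
  stopifnot(inherits(model, "unet"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_unet
#' @export
load_unet <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "unet")) stopf("'%s' is not a unet checkpoint", path)
  model
}
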
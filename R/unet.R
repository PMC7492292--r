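# U-Net architecture and its forward/backward passes, built on the package's
# RcppArmadillo conv/pool/upsample kernels. The design follows the original
# depth-4 encoder-decoder: repeated 3x3 conv + ReLU pairs with 2x2 max
# pooling on the contracting path; nearest-neighbour upsampling + 3x3 conv,
# skip concatenation and conv pairs on the expansive path; a 1x1 sigmoid
# output head. `model_scale` shrinks filter counts for desk-scale runs.

#' Build an (untrained) U-Net for 4-channel segmentation
#'
#' @param input_size `(H, W)` of input slices; both must be divisible by
#'   `2^depth`.
#' @param n_channels Number of input channels (4: water, fat, fat fraction,
#'   R2*).
#' @param model_scale Channel-width multiplier; 1.0 is the original 64-filter
#'   design, smaller values give CPU-sized models.
#' @param depth Number of pooling stages (default 4).
#' @param base_filters Filters in the first encoder block at scale 1
#'   (default 64).
#' @param seed Optional seed for weight initialisation (He init). Because
#'   input channels are deliberately not normalised, [train_unet()] applies a
#'   one-off data-driven rescaling of the initial weights (LSUV-style; see
#'   [calibrate_unet()]) so pre-activations start at unit scale.
#' @return An object of class `unet` (untrained).
#' @export
build_unet <- function(input_size = c(256L, 256L), n_channels = 4L,
                       model_scale = 1, depth = 4L, base_filters = 64L,
                       seed = NULL) {
  H <- as.integer(input_size[1]); W <- as.integer(input_size[2])
  div <- 2L^depth
  if (H %% div != 0L || W %% div != 0L)
    stopf(paste0("input size %dx%d is not divisible by 2^depth = %d; ",
                 "pad the images or reduce depth"), H, W, div)
  f <- pmax(2L, as.integer(round(base_filters * model_scale * 2^(0:(depth)))))
  # f[1..depth] encoder widths, f[depth+1] bottleneck width
  layer_defs <- list()
  add <- function(name, cin, cout, k) {
    layer_defs[[name]] <<- list(cin = cin, cout = cout, k = k)
  }
  for (d in seq_len(depth)) {
    add(sprintf("e%dc1", d), if (d == 1) n_channels else f[d - 1], f[d], 3L)
    add(sprintf("e%dc2", d), f[d], f[d], 3L)
  }
  add("b1", f[depth], f[depth + 1], 3L)
  add("b2", f[depth + 1], f[depth + 1], 3L)
  for (d in seq_len(depth)) {
    above <- if (d == depth) f[depth + 1] else f[d + 1]
    add(sprintf("d%du", d), above, f[d], 3L)
    add(sprintf("d%dc1", d), 2L * f[d], f[d], 3L)
    add(sprintf("d%dc2", d), f[d], f[d], 3L)
  }
  add("final", f[1], 1L, 1L)
  init_one <- function(def) {
    K <- def$cin * def$k^2
    list(wt = matrix(rnorm(K * def$cout, sd = sqrt(2 / K)), K, def$cout),
         b = rep(0, def$cout))
  }
  init_all <- function() {
    p <- list()
    for (nm in names(layer_defs)) p[[nm]] <- init_one(layer_defs[[nm]])
    p
  }
  params <- if (is.null(seed)) init_all() else with_seed(seed, init_all())
  structure(list(input_size = c(H, W), n_channels = as.integer(n_channels),
                 depth = as.integer(depth), filters = f,
                 model_scale = model_scale, layer_defs = layer_defs,
                 params = params, trained = FALSE, history = NULL,
                 config = NULL),
            class = "unet")
}

n_params <- function(model) {
  sum(vapply(model$params,
             function(p) length(p$wt) + length(p$b), numeric(1)))
}

#' @export
print.unet <- function(x, ...) {
  cat(sprintf(paste0("<unet> depth %d, filters %s, input %dx%dx%d, ",
                     "%s parameters (%s)\n"),
              x$depth, paste(x$filters, collapse = "/"),
              x$input_size[1], x$input_size[2], x$n_channels,
              format(n_params(x), big.mark = ","),
              if (x$trained) "trained" else "untrained"))
  if (!is.null(x$history))
    cat(sprintf("  %d epochs, best validation loss %.4f (epoch %d)\n",
                nrow(x$history), min(x$history$val_loss),
                which.min(x$history$val_loss)))
  invisible(x)
}

#' @export
summary.unet <- function(object, ...) {
  print(object)
  cat("  layers:\n")
  for (nm in names(object$layer_defs)) {
    d <- object$layer_defs[[nm]]
    cat(sprintf("    %-6s %dx%d conv, %d -> %d channels\n", nm, d$k, d$k,
                d$cin, d$cout))
  }
  invisible(object)
}

#' @export
plot.unet <- function(x, ...) {
  if (is.null(x$history)) stopf("model has no training history")
  h <- x$history
  plot(h$epoch, h$train_loss, type = "l", xlab = "epoch",
       ylab = "Jaccard distance loss",
       ylim = range(c(h$train_loss, h$val_loss)), ...)
  lines(h$epoch, h$val_loss, lty = 2)
  legend("topright", c("training", "validation"), lty = c(1, 2), bty = "n")
  invisible(x)
}

relu <- function(y) { y[y < 0] <- 0; y }

# Logits are clipped so probabilities stay within [~1e-7, 1 - 1e-7] (the
# same hygiene Keras applies via its backend epsilon): saturated pixels keep
# a usable gradient instead of underflowing to zero.
sigmoid <- function(z) 1 / (1 + exp(-pmin(pmax(z, -16), 16)))

concat_ch <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

#' Data-driven initial weight rescaling (LSUV-style)
#'
#' The input channels are kept at their raw intensity values (no
#' normalisation), so their scales differ by orders of magnitude (signal in
#' arbitrary units near 1, fat fraction 0-100, R2* of order 100 1/s). With a
#' generic He initialisation this makes the initial logits enormous and the
#' sigmoid saturates irrecoverably. Instead of normalising the data, each
#' convolution's initial weights are rescaled once so that its pre-activation
#' standard deviation on a calibration batch is 1 (Mishkin-Matas "layer-
#' sequential unit variance" scheme). This touches only the starting point of
#' optimisation, not the data or architecture.
#'
#' @param model An untrained `unet`.
#' @param x A calibration batch `[H, W, C, N]` of training slices.
#' @return The model with rescaled initial weights.
#' @export
calibrate_unet <- function(model, x) {
  scale_layer <- function(nm, cur, k) {
    y <- cpp_conv2d_fwd(cur, dim(cur), model$params[[nm]]$wt,
                        model$params[[nm]]$b, k)
    s <- stats::sd(y)
    if (is.finite(s) && s > 1e-12) {
      model$params[[nm]]$wt <<- model$params[[nm]]$wt / s
      y <- y / s
    }
    y
  }
  depth <- model$depth
  skips <- vector("list", depth)
  cur <- x
  for (d in seq_len(depth)) {
    cur <- relu(scale_layer(sprintf("e%dc1", d), cur, 3L))
    cur <- relu(scale_layer(sprintf("e%dc2", d), cur, 3L))
    skips[[d]] <- cur
    cur <- cpp_maxpool_fwd(cur, dim(cur))$y
  }
  cur <- relu(scale_layer("b1", cur, 3L))
  cur <- relu(scale_layer("b2", cur, 3L))
  for (d in rev(seq_len(depth))) {
    up <- cpp_upsample2_fwd(cur, dim(cur))
    up <- relu(scale_layer(sprintf("d%du", d), up, 3L))
    cur <- concat_ch(up, skips[[d]])
    cur <- relu(scale_layer(sprintf("d%dc1", d), cur, 3L))
    cur <- relu(scale_layer(sprintf("d%dc2", d), cur, 3L))
  }
  scale_layer("final", cur, 1L)
  model$calibrated <- TRUE
  model
}

# Forward pass over a batch x [H, W, C, N]. With cache = TRUE returns
# everything backward() needs.
unet_forward <- function(model, x, cache = FALSE) {
  P <- model$params
  cc <- if (cache) new.env(parent = emptyenv()) else NULL
  conv_step <- function(cur, nm, k, use_relu = TRUE) {
    if (cache) assign(paste0("in.", nm), cur, envir = cc)
    y <- cpp_conv2d_fwd(cur, dim(cur), P[[nm]]$wt, P[[nm]]$b, k)
    if (use_relu) y <- relu(y)
    if (cache && use_relu) assign(paste0("out.", nm), y, envir = cc)
    y
  }
  depth <- model$depth
  skips <- vector("list", depth)
  cur <- x
  for (d in seq_len(depth)) {
    cur <- conv_step(cur, sprintf("e%dc1", d), 3L)
    cur <- conv_step(cur, sprintf("e%dc2", d), 3L)
    skips[[d]] <- cur
    mp <- cpp_maxpool_fwd(cur, dim(cur))
    if (cache) assign(sprintf("poolidx.%d", d), mp$idx, envir = cc)
    if (cache) assign(sprintf("pooldim.%d", d), dim(cur), envir = cc)
    cur <- mp$y
  }
  cur <- conv_step(cur, "b1", 3L)
  cur <- conv_step(cur, "b2", 3L)
  for (d in rev(seq_len(depth))) {
    up <- cpp_upsample2_fwd(cur, dim(cur))
    if (cache) assign(sprintf("updim.%d", d), dim(up), envir = cc)
    up <- conv_step(up, sprintf("d%du", d), 3L)
    cur <- concat_ch(up, skips[[d]])
    cur <- conv_step(cur, sprintf("d%dc1", d), 3L)
    cur <- conv_step(cur, sprintf("d%dc2", d), 3L)
  }
  z <- conv_step(cur, "final", 1L, use_relu = FALSE)
  p <- sigmoid(z)
  if (cache) assign("p", p, envir = cc)
  list(p = p, cache = cc)
}

# Backward pass: dp is dLoss/dp with p = sigmoid(z). Returns gradients
# parallel to model$params.
unet_backward <- function(model, dp, cache) {
  P <- model$params
  p <- get("p", envir = cache)
  dz <- dp * p * (1 - p)
  grads <- list()
  conv_back <- function(dy, nm, k, use_relu = TRUE) {
    if (use_relu) {
      out <- get(paste0("out.", nm), envir = cache)
      dy[out <= 0] <- 0
    }
    xin <- get(paste0("in.", nm), envir = cache)
    g <- cpp_conv2d_bwd(xin, dim(xin), P[[nm]]$wt, k, dy)
    grads[[nm]] <<- list(wt = g$dwt, b = g$db)
    g$dx
  }
  depth <- model$depth
  dcur <- conv_back(dz, "final", 1L, use_relu = FALSE)
  dskips <- vector("list", depth)
  for (d in seq_len(depth)) {
    dcur <- conv_back(dcur, sprintf("d%dc2", d), 3L)
    dcat <- conv_back(dcur, sprintf("d%dc1", d), 3L)
    fd <- dim(dcat)[3] %/% 2L
    dup <- dcat[, , seq_len(fd), , drop = FALSE]
    dskips[[d]] <- dcat[, , fd + seq_len(fd), , drop = FALSE]
    dup <- conv_back(dup, sprintf("d%du", d), 3L)
    dcur <- cpp_upsample2_bwd(dup, get(sprintf("updim.%d", d),
                                       envir = cache))
  }
  dcur <- conv_back(dcur, "b2", 3L)
  dcur <- conv_back(dcur, "b1", 3L)
  for (d in rev(seq_len(depth))) {
    dskip <- cpp_maxpool_bwd(dcur, get(sprintf("poolidx.%d", d),
                                       envir = cache),
                             get(sprintf("pooldim.%d", d), envir = cache)) +
      dskips[[d]]
    dskip <- conv_back(dskip, sprintf("e%dc2", d), 3L)
    dcur <- conv_back(dskip, sprintf("e%dc1", d), 3L)
  }
  grads
}

#' Soft Jaccard distance loss
#'
#' `1 - (|intersection| + s) / (|union| + s)` with pixel sums
#' `intersection = sum(y_true * y_pred)` and
#' `union = sum(y_true) + sum(y_pred) - intersection`. Zero for a perfect
#' binary prediction (up to the smooth-term perturbation `s/(A + s)` with `A`
#' the mask area) and differentiable in `y_pred`.
#'
#' @param y_true Binary array/matrix.
#' @param y_pred Probability array/matrix, same shape, values in `[0, 1]`.
#' @param smooth Smoothing constant `s` (default 100, the widely used value
#'   for this loss).
#' @return Scalar loss, >= 0.
#' @export
jaccard_distance_loss <- function(y_true, y_pred, smooth = 100) {
  if (!identical(dim(y_true) %||% length(y_true),
                 dim(y_pred) %||% length(y_pred)))
    stopf("shape mismatch between y_true and y_pred")
  if (!all(y_true %in% c(0, 1))) stopf("y_true must be binary")
  if (any(y_pred < 0 | y_pred > 1)) stopf("y_pred must lie in [0, 1]")
  i <- sum(y_true * y_pred)
  u <- sum(y_true) + sum(y_pred) - i
  1 - (i + smooth) / (u + smooth)
}

# Batch loss + gradient: per-sample soft Jaccard, averaged over the batch.
# t and p are [H, W, 1, N].
jaccard_loss_grad <- function(t, p, smooth = 100) {
  N <- dim(p)[4]
  loss <- 0
  dp <- array(0, dim(p))
  for (n in seq_len(N)) {
    tn <- t[, , 1, n]; pn <- p[, , 1, n]
    i <- sum(tn * pn)
    u <- sum(tn) + sum(pn) - i
    loss <- loss + (1 - (i + smooth) / (u + smooth))
    dp[, , 1, n] <- -(tn * (u + smooth) - (i + smooth) * (1 - tn)) /
      (u + smooth)^2 / N
  }
  list(loss = loss / N, dp = dp)
}
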
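# Internal helpers shared across modules.

# Smooth random field on an arbitrary grid: coarse iid normals, bilinearly
# interpolated up to (H, W). Used for coil-shading, FF texture and R2* fields.
smooth_field_2d <- function(H, W, grid = 6L, sd = 1) {
  g <- matrix(rnorm(grid * grid, sd = sd), grid, grid)
  bilinear_resize(g, H, W)
}

# Bilinear resize of a matrix to (H, W).
bilinear_resize <- function(m, H, W) {
  gh <- nrow(m); gw <- ncol(m)
  r <- seq(1, gh, length.out = H)
  c_ <- seq(1, gw, length.out = W)
  r0 <- pmin(floor(r), gh - 1L); c0 <- pmin(floor(c_), gw - 1L)
  fr <- r - r0; fc <- c_ - c0
  m00 <- m[cbind(rep(r0, W), rep(c0, each = H))]
  m10 <- m[cbind(rep(r0 + 1, W), rep(c0, each = H))]
  m01 <- m[cbind(rep(r0, W), rep(c0 + 1, each = H))]
  m11 <- m[cbind(rep(r0 + 1, W), rep(c0 + 1, each = H))]
  fr_ <- rep(fr, W); fc_ <- rep(fc, each = H)
  v <- m00 * (1 - fr_) * (1 - fc_) + m10 * fr_ * (1 - fc_) +
    m01 * (1 - fr_) * fc_ + m11 * fr_ * fc_
  matrix(v, H, W)
}

# Derive a stream of reproducible sub-seeds (< 2^31) from one master seed.
derive_seeds <- function(seed, n) {
  force(seed); force(n)   # force before snapshotting the RNG state
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

# Evaluate `expr` with a local RNG stream seeded by `seed`, restoring the
# caller's RNG state afterwards. `seed` is forced before the state snapshot
# so that lazily evaluated seed expressions drawing from the ambient RNG
# (e.g. sample.int(...)) are not rolled back.
with_seed <- function(seed, expr) {
  force(seed)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  expr
}

# Polynomial rolling hash over serialized R objects (no digest pkg available);
# used only to tie pipeline outputs to their run manifest.
config_hash <- function(x) {
  raw <- serialize(x, NULL, version = 2)
  b <- as.double(raw)
  h <- 0
  p <- 2^31 - 1
  for (i in seq_along(b)) h <- (h * 131 + b[i]) %% p
  sprintf("%08x", as.integer(h %% 2^31))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
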
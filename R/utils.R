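# Internal helpers shared across modules: seeded evaluation, index-clamped
# image shifts, and small stencil operations with replicate borders.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
local_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  expr
}

# Derive a stream seed from a base seed and an index; stays below 2^31.
derive_seed <- function(seed, index) {
  ((as.numeric(seed) %% 100003L) * 20011 + as.numeric(index) * 7919 + 17) %%
    2147483647
}

# Shift a matrix by (dr, dc) with replicate (clamped-index) borders.
shift_replicate <- function(x, dr, dc) {
  h <- nrow(x)
  w <- ncol(x)
  ri <- pmin(pmax(seq_len(h) + dr, 1L), h)
  ci <- pmin(pmax(seq_len(w) + dc, 1L), w)
  x[ri, ci, drop = FALSE]
}

# Shift with zero fill (pixels falling outside vanish rather than replicate).
shift_zero <- function(x, dr, dc) {
  h <- nrow(x)
  w <- ncol(x)
  out <- matrix(0, h, w)
  rs <- max(1L, 1L - dr):min(h, h - dr)
  cs <- max(1L, 1L - dc):min(w, w - dc)
  if (length(rs) > 0L && length(cs) > 0L) {
    out[rs, cs] <- x[rs + dr, cs + dc]
  }
  out
}

# 2-D correlation of `x` with kernel `k` (odd square), replicate borders.
conv2_replicate <- function(x, k) {
  stopifnot(nrow(k) == ncol(k), nrow(k) %% 2L == 1L)
  c0 <- (nrow(k) + 1L) %/% 2L
  out <- matrix(0, nrow(x), ncol(x))
  for (a in seq_len(nrow(k))) {
    for (b in seq_len(ncol(k))) {
      if (k[a, b] != 0) {
        out <- out + k[a, b] * shift_replicate(x, a - c0, b - c0)
      }
    }
  }
  out
}

# Sliding-window mean / max with stride 1 and replicate borders.
pool_mean <- function(x, win) {
  k <- matrix(1 / (win * win), win, win)
  conv2_replicate(x, k)
}

pool_max <- function(x, win) {
  r <- (win - 1L) %/% 2L
  out <- x
  for (a in -r:r) {
    for (b in -r:r) {
      if (a != 0L || b != 0L) {
        out <- pmax(out, shift_replicate(x, a, b))
      }
    }
  }
  out
}

clip01 <- function(x, lo = 0, hi = 255) {
  pmin(pmax(x, lo), hi)
}

# Isotropic Gaussian kernel on an odd win x win stencil, normalized to sum 1.
gaussian_kernel <- function(win, sigma = win / 3) {
  r <- (win - 1L) / 2L
  d <- outer((-r:r)^2, (-r:r)^2, "+")
  k <- exp(-d / (2 * sigma^2))
  k / sum(k)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
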
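# Quantum Matched-Filter Technique (QMFT) denoising.
#
# The denoiser minimizes a total-variation-style variational objective
#   Omega(I) = sum_pixels sqrt(1 + beta^2 |grad I|^2) + (lambda/2) (I - I0)^2
# by explicit gradient descent with adaptive step halving, then runs a seeded
# stochastic local search: directional scans (row / column / diagonal) select
# image bands on which reconstruction operators (Gaussian blur, mean filter,
# global intensity scaling) propose candidates, accepted only when they lower
# the objective and a uniform draw falls below the local-search rate. The
# accepted-state objective trace is non-increasing by construction.

#' Denoising configuration
#'
#' @param beta Edge weight of the gradient term; larger values penalize image
#'   gradients more strongly (dimensionless, > 0).
#' @param lam Fidelity weight of the `(I - I0)^2` term on the 8-bit intensity
#'   scale (> 0).
#' @param step Initial gradient-descent step size; halved on divergence,
#'   never raised.
#' @param max_iters Gradient-descent iteration cap.
#' @param rel_tol Relative objective-change stopping tolerance.
#' @param local_search_rate Probability gate of the local-search acceptance
#'   rule, in [0, 1]; 0 disables the local search entirely.
#' @param n_rounds Local-search rounds (each round cycles the three scan
#'   directions).
#' @param tau Soft-threshold level (intensity units) applied to the high-pass
#'   residual when forming the detail mask / thresholded proposal.
#' @param seed Integer seed driving every stochastic proposal.
#' @return List of class `denoise_config`.
#' @export
denoise_config <- function(beta = 1, lam = 0.05, step = 1, max_iters = 120,
                           rel_tol = 1e-6, local_search_rate = 0.1,
                           n_rounds = 12, tau = 5, seed = 1) {
  stopifnot(
    beta > 0, lam > 0, step > 0, max_iters >= 1,
    local_search_rate >= 0, local_search_rate <= 1,
    n_rounds >= 0, tau >= 0
  )
  structure(
    list(beta = beta, lam = lam, step = step, max_iters = max_iters,
         rel_tol = rel_tol, local_search_rate = local_search_rate,
         n_rounds = n_rounds, tau = tau, seed = seed),
    class = "denoise_config"
  )
}

#' Variational denoising objective
#'
#' Evaluates `sum( sqrt(1 + beta^2 |grad I|^2) + (lam/2) (I - I0)^2 )` with
#' forward-difference gradients and replicate borders (the forward difference
#' across the last row/column is zero).
#'
#' @param I Current image estimate (matrix).
#' @param I0 Noisy input of the same shape.
#' @param beta,lam Balance weights, both > 0.
#' @return Scalar objective value.
#' @examples
#' I <- matrix(5, 4, 4)
#' denoise_objective(I, I, beta = 2, lam = 1) # == 16: gradient term is 1/pixel
#' @export
denoise_objective <- function(I, I0, beta, lam) {
  if (!identical(dim(I), dim(I0))) {
    stop("I and I0 must have the same shape")
  }
  g <- forward_gradients(I)
  sum(sqrt(1 + beta^2 * (g$gx^2 + g$gy^2))) + (lam / 2) * sum((I - I0)^2)
}

# Forward differences with replicate borders: gx along columns, gy along rows.
forward_gradients <- function(I) {
  h <- nrow(I)
  w <- ncol(I)
  gx <- cbind(I[, -1, drop = FALSE] - I[, -w, drop = FALSE], rep(0, h))
  gy <- rbind(I[-1, , drop = FALSE] - I[-h, , drop = FALSE], rep(0, w))
  list(gx = gx, gy = gy)
}

# Analytic gradient of the objective w.r.t. I.
objective_gradient <- function(I, I0, beta, lam) {
  g <- forward_gradients(I)
  s <- sqrt(1 + beta^2 * (g$gx^2 + g$gy^2))
  A <- beta^2 * g$gx / s
  B <- beta^2 * g$gy / s
  h <- nrow(I)
  w <- ncol(I)
  Axm <- cbind(rep(0, h), A[, -w, drop = FALSE])
  Bym <- rbind(rep(0, w), B[-h, , drop = FALSE])
  (Axm - A) + (Bym - B) + lam * (I - I0)
}

#' Gradient-descent minimization of the denoising objective
#'
#' Explicit descent from `I = I0` with adaptive step halving: a step that
#' would raise the objective is rejected and the step size halved (never
#' raised). Stops at `max_iters`, when the relative objective change drops
#' below `rel_tol`, or when the step underflows.
#'
#' @param I0 Noisy image (matrix).
#' @param config A [denoise_config()].
#' @return Denoised matrix with attribute `objective_trace`, the
#'   non-increasing sequence of accepted objective values (starting at
#'   `Omega(I0)`).
#' @export
gradient_descent_denoise <- function(I0, config = denoise_config()) {
  stopifnot(inherits(config, "denoise_config"))
  I <- I0
  step <- config$step
  obj <- denoise_objective(I, I0, config$beta, config$lam)
  trace <- obj
  for (it in seq_len(config$max_iters)) {
    gr <- objective_gradient(I, I0, config$beta, config$lam)
    accepted <- FALSE
    while (step > 1e-8) {
      cand <- I - step * gr
      cobj <- denoise_objective(cand, I0, config$beta, config$lam)
      if (cobj <= obj) {
        accepted <- TRUE
        break
      }
      step <- step / 2
    }
    if (!accepted) break
    rel <- (obj - cobj) / max(abs(obj), 1e-12)
    I <- cand
    obj <- cobj
    trace <- c(trace, obj)
    if (rel < config$rel_tol) break
  }
  attr(I, "objective_trace") <- trace
  I
}

#' Directional pixel scan orders
#'
#' Enumerates every pixel exactly once in row-major, column-major or
#' anti-diagonal band order (bands of constant `row + col`, rows ascending
#' within a band).
#'
#' @param shape Integer vector `c(height, width)`.
#' @param mode One of `"row"`, `"column"`, `"diagonal"`.
#' @return Integer matrix with columns `row`, `col`; a permutation of the
#'   full index set.
#' @export
directional_scan <- function(shape, mode = c("row", "column", "diagonal")) {
  mode <- match.arg(mode)
  h <- shape[1]
  w <- shape[2]
  grid <- cbind(
    row = rep(seq_len(h), each = w),
    col = rep(seq_len(w), times = h)
  )
  ord <- switch(mode,
    row = order(grid[, "row"], grid[, "col"]),
    column = order(grid[, "col"], grid[, "row"]),
    diagonal = order(grid[, "row"] + grid[, "col"], grid[, "row"])
  )
  grid[ord, , drop = FALSE]
}

#' Stochastic reconstruction operators
#'
#' The three image-reconstruction proposals of the local search: Gaussian
#' blur and mean filtering with a seeded size draw from {3, 5}, and a global
#' intensity scaling by one draw from U[0.7, 1.3]. Output is clipped to
#' [0, 255].
#'
#' @param I Image matrix.
#' @param op_name One of `"gaussian_blur"`, `"mean_filter"`,
#'   `"intensity_scale"`.
#' @param seed Optional seed for the size / factor draw (uses the current RNG
#'   stream when `NULL`).
#' @param size Force the filter size (3 or 5) instead of drawing it.
#' @param factor Force the intensity factor instead of drawing it.
#' @return Transformed matrix.
#' @export
reconstruction_op <- function(I, op_name = c("gaussian_blur", "mean_filter",
                                             "intensity_scale"),
                              seed = NULL, size = NULL, factor = NULL) {
  op_name <- match.arg(op_name)
  local_seed(seed, {
    out <- switch(op_name,
      gaussian_blur = {
        win <- size %||% sample(c(3L, 5L), 1L)
        conv2_replicate(I, gaussian_kernel(win))
      },
      mean_filter = {
        win <- size %||% sample(c(3L, 5L), 1L)
        pool_mean(I, win)
      },
      intensity_scale = {
        f <- factor %||% stats::runif(1, 0.7, 1.3)
        I * f
      }
    )
    matrix(clip01(out), nrow(I), ncol(I))
  })
}

# Detail mask: pixels whose high-pass residual survives soft-thresholding at
# tau; realizes the "threshold the detail coefficients" decomposition step.
detail_mask <- function(I, tau) {
  resid <- I - pool_mean(I, 3L)
  abs(resid) > tau
}

soft_threshold_detail <- function(I, tau) {
  smooth <- pool_mean(I, 3L)
  resid <- I - smooth
  matrix(clip01(smooth + sign(resid) * pmax(abs(resid) - tau, 0)),
         nrow(I), ncol(I))
}

#' QMFT denoising: gradient descent plus stochastic local search
#'
#' Runs [gradient_descent_denoise()] and then, for `n_rounds` rounds cycling
#' the three scan directions, proposes reconstruction-operator candidates on
#' a random band of the current scan order intersected with the detail mask.
#' A candidate is accepted only when it lowers the variational objective
#' *and* a seeded uniform draw falls below `local_search_rate`; the accepted
#' chain is therefore monotone in the objective and the best image seen is
#' the one returned (elitism). With `local_search_rate = 0` the output equals
#' the gradient-descent output exactly.
#'
#' @param I0 Noisy image (matrix).
#' @param config A [denoise_config()].
#' @return Denoised matrix with attribute `objective_trace` (accepted-state
#'   objectives, non-increasing) and `n_accepted`.
#' @export
qmft_denoise <- function(I0, config = denoise_config()) {
  stopifnot(inherits(config, "denoise_config"))
  I <- gradient_descent_denoise(I0, config)
  trace <- attr(I, "objective_trace")
  attr(I, "objective_trace") <- NULL
  obj <- trace[length(trace)]
  n_acc <- 0L

  if (config$local_search_rate > 0 && config$n_rounds > 0) {
    mask <- detail_mask(I, config$tau)
    ops <- c("gaussian_blur", "mean_filter", "intensity_scale")
    modes <- c("row", "column", "diagonal")
    local_seed(derive_seed(config$seed, 421L), {
      # First proposal: the soft-thresholded decomposition itself.
      cand <- soft_threshold_detail(I, config$tau)
      cobj <- denoise_objective(cand, I0, config$beta, config$lam)
      if (cobj < obj && stats::runif(1) < config$local_search_rate) {
        I <- cand
        obj <- cobj
        trace <- c(trace, obj)
        n_acc <- n_acc + 1L
      }
      for (round in seq_len(config$n_rounds)) {
        for (mode in modes) {
          scan <- directional_scan(dim(I), mode)
          n <- nrow(scan)
          band_len <- max(1L, n %/% 4L)
          start <- sample.int(n - band_len + 1L, 1L)
          band <- scan[start:(start + band_len - 1L), , drop = FALSE]
          sel <- matrix(FALSE, nrow(I), ncol(I))
          sel[band] <- TRUE
          sel <- sel & mask
          if (!any(sel)) next
          op <- sample(ops, 1L)
          prop <- reconstruction_op(I, op)
          cand <- I
          cand[sel] <- prop[sel]
          cobj <- denoise_objective(cand, I0, config$beta, config$lam)
          if (cobj < obj && stats::runif(1) < config$local_search_rate) {
            I <- cand
            obj <- cobj
            trace <- c(trace, obj)
            n_acc <- n_acc + 1L
          }
        }
      }
    })
  }
  attr(I, "objective_trace") <- trace
  attr(I, "n_accepted") <- n_acc
  I
}

#' Kernel admissibility check
#'
#' Reports the discrete analogues of the wavelet-style admissibility
#' conditions for a weight stencil: finite energy (sum of squares) and zero
#' mean (sum within 1e-12 of zero).
#'
#' @param kernel Numeric vector or matrix stencil.
#' @return List of class `kernel_check` with `kernel`, `energy`, `mean`,
#'   `admissible`.
#' @examples
#' check_admissibility(c(1, -1)) # admissible Haar-like pair, energy 2
#' @export
check_admissibility <- function(kernel) {
  stopifnot(is.numeric(kernel), all(is.finite(kernel)))
  energy <- sum(kernel^2)
  m <- sum(kernel)
  structure(
    list(kernel = kernel, energy = energy, mean = m,
         admissible = is.finite(energy) && abs(m) < 1e-12),
    class = "kernel_check"
  )
}

#' @export
print.kernel_check <- function(x, ...) {
  cat(sprintf("<kernel_check> energy=%g mean=%g admissible=%s\n",
              x$energy, x$mean, x$admissible))
  invisible(x)
}

#' Mean squared error and peak signal-to-noise ratio
#'
#' `img_mse` is the mean squared difference; `psnr` is
#' `10 * log10(peak^2 / mse)` in dB, reported as `Inf` when the images are
#' identical.
#'
#' @param ref,test Matrices of the same shape.
#' @param peak Peak intensity (255 for 8-bit images).
#' @return Scalar.
#' @export
img_mse <- function(ref, test) {
  if (!identical(dim(ref), dim(test))) {
    stop("ref and test must have the same shape")
  }
  mean((ref - test)^2)
}

#' @rdname img_mse
#' @export
psnr <- function(ref, test, peak = 255) {
  m <- img_mse(ref, test)
  if (m == 0) {
    return(Inf)
  }
  10 * log10(peak^2 / m)
}
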
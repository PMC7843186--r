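# Closed-form oracle for the 2x2 discretized objective, written directly from
# the forward-difference / replicate-border definition (independent of the
# package's matrix implementation). Pixels: a=I[1,1], b=I[1,2], c=I[2,1],
# d=I[2,2].
objective_2x2 <- function(a, b, c, d, I0, beta, lam) {
  sqrt(1 + beta^2 * ((b - a)^2 + (c - a)^2)) +
    sqrt(1 + beta^2 * (d - b)^2) +
    sqrt(1 + beta^2 * (d - c)^2) +
    1 +
    (lam / 2) * ((a - I0[1, 1])^2 + (b - I0[1, 2])^2 +
                   (c - I0[2, 1])^2 + (d - I0[2, 2])^2)
}

test_that("objective matches hand-evaluated forward-difference formula", {
  I <- matrix(5, 4, 4)
  expect_equal(denoise_objective(I, I, beta = 3, lam = 9), 16)

  I <- matrix(c(0, 1), 1, 2)
  I0 <- matrix(0, 1, 2)
  expect_equal(denoise_objective(I, I0, beta = 1, lam = 2), sqrt(2) + 2)

  # Linearity in lambda on a fixed pair.
  set.seed(4)
  I <- matrix(runif(12, 0, 255), 3, 4)
  I0 <- matrix(runif(12, 0, 255), 3, 4)
  lam <- 0.3
  expect_equal(
    denoise_objective(I, I0, 1, 2 * lam) - denoise_objective(I, I0, 1, lam),
    (lam / 2) * sum((I - I0)^2)
  )

  # Agreement with the independent 2x2 closed form.
  I <- matrix(c(10, 200, 30, 90), 2, 2)
  I0 <- matrix(c(0, 180, 60, 100), 2, 2)
  expect_equal(
    denoise_objective(I, I0, 0.5, 0.1),
    objective_2x2(I[1, 1], I[1, 2], I[2, 1], I[2, 2], I0, 0.5, 0.1)
  )

  expect_error(denoise_objective(matrix(0, 2, 2), matrix(0, 2, 3), 1, 1))
})

test_that("gradient descent reaches the coarse-grid exhaustive minimum", {
  levels <- seq(0, 255, length.out = 17)
  grid <- expand.grid(a = levels, b = levels, c = levels, d = levels)
  for (cfg in list(c(beta = 0.05, lam = 0.02), c(beta = 0.2, lam = 0.1))) {
    set.seed(11)
    I0 <- matrix(runif(4, 0, 255), 2, 2)
    vals <- objective_2x2(grid$a, grid$b, grid$c, grid$d, I0,
                          cfg[["beta"]], cfg[["lam"]])
    out <- gradient_descent_denoise(
      I0, denoise_config(beta = cfg[["beta"]], lam = cfg[["lam"]],
                         max_iters = 500)
    )
    obj <- denoise_objective(out, I0, cfg[["beta"]], cfg[["lam"]])
    expect_lte(obj, min(vals) + 1e-3)
  }
})

test_that("gradient descent is monotone and fixes constant images", {
  I0 <- matrix(42, 8, 8)
  out <- gradient_descent_denoise(I0)
  expect_equal(unclass(out), I0, ignore_attr = TRUE)

  set.seed(2)
  I0 <- matrix(runif(400, 0, 255), 20, 20)
  out <- gradient_descent_denoise(I0)
  tr <- attr(out, "objective_trace")
  expect_true(all(diff(tr) <= 1e-9))
  expect_lte(tr[length(tr)], denoise_objective(I0, I0, 1, 0.05))
})

test_that("directional scans visit every pixel exactly once", {
  expect_identical(
    directional_scan(c(2, 2), "row"),
    cbind(row = c(1L, 1L, 2L, 2L), col = c(1L, 2L, 1L, 2L))
  )
  expect_identical(
    directional_scan(c(2, 2), "diagonal"),
    cbind(row = c(1L, 1L, 2L, 2L), col = c(1L, 2L, 1L, 2L))
  )
  expect_identical(
    directional_scan(c(2, 3), "column")[1:2, ],
    cbind(row = 1:2, col = c(1L, 1L))
  )
  for (mode in c("row", "column", "diagonal")) {
    sc <- directional_scan(c(5, 7), mode)
    keys <- paste(sc[, 1], sc[, 2])
    expect_equal(sort(keys), sort(paste(rep(1:5, each = 7), rep(1:7, 5))))
  }
})

test_that("reconstruction operators behave as documented", {
  I <- matrix(runif(64, 0, 255), 8, 8)
  expect_equal(reconstruction_op(I, "intensity_scale", factor = 1), I)

  K <- matrix(50, 6, 6)
  expect_equal(reconstruction_op(K, "mean_filter", size = 3), K)

  spike <- matrix(0, 3, 3)
  spike[2, 2] <- 9
  out <- reconstruction_op(spike, "mean_filter", size = 3)
  expect_equal(out[2, 2], 1)

  doubled <- reconstruction_op(matrix(200, 4, 4), "intensity_scale",
                               factor = 1.3)
  expect_true(all(doubled == 255)) # clipped

  expect_identical(reconstruction_op(I, "gaussian_blur", seed = 5),
                   reconstruction_op(I, "gaussian_blur", seed = 5))
})

test_that("qmft local search is gated, elitist and monotone", {
  ph <- generate_phantom(7, 64, 64)
  noisy <- add_noise(ph$channels$flair, "gaussian", 20, seed = 3)

  cfg0 <- denoise_config(local_search_rate = 0, seed = 9)
  gd <- gradient_descent_denoise(noisy, cfg0)
  q0 <- qmft_denoise(noisy, cfg0)
  expect_equal(unclass(q0), unclass(gd), ignore_attr = TRUE)

  cfg <- denoise_config(seed = 9)
  q <- qmft_denoise(noisy, cfg)
  expect_lte(
    denoise_objective(unclass(q), noisy, cfg$beta, cfg$lam),
    denoise_objective(unclass(gd), noisy, cfg$beta, cfg$lam) + 1e-9
  )
  expect_true(all(diff(attr(q, "objective_trace")) <= 1e-9))
  expect_gt(psnr(ph$channels$flair, q), psnr(ph$channels$flair, noisy))
})

test_that("admissibility check reports energy and zero mean", {
  haar <- check_admissibility(c(1, -1))
  expect_equal(haar$energy, 2)
  expect_equal(haar$mean, 0)
  expect_true(haar$admissible)

  box <- check_admissibility(c(1, 1, 1))
  expect_equal(box$mean, 3)
  expect_false(box$admissible)

  lap <- check_admissibility(c(1, -2, 1))
  expect_equal(lap$energy, 6)
  expect_true(lap$admissible)
})

test_that("mse and psnr follow the direct formulas", {
  x <- matrix(runif(100, 0, 255), 10, 10)
  expect_equal(psnr(x, x), Inf)
  expect_equal(img_mse(x, x + 3), 9)

  ref <- matrix(c(0, 255), 1, 2)
  test <- matrix(c(0, 254), 1, 2)
  expect_equal(img_mse(ref, test), 0.5)
  expect_equal(psnr(ref, test), 10 * log10(255^2 / 0.5), tolerance = 1e-12)
  expect_equal(psnr(ref, test), 51.1413, tolerance = 1e-4)

  expect_error(img_mse(matrix(0, 2, 2), matrix(0, 3, 2)))
})
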
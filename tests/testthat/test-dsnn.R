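test_that("spike rate code follows the integrate-and-fire count formula", {
  expect_equal(encode_spikes(0, 10), 0)
  expect_equal(encode_spikes(255, 10), 10)
  expect_equal(encode_spikes(128, 10), floor(10 * 128 / 255))
  expect_equal(encode_spikes(128, 10), 5)
  # Monotone non-decreasing in intensity.
  v <- encode_spikes(seq(0, 255, by = 1), 16)
  expect_true(all(diff(v) >= 0))
  expect_equal(encode_spikes(255, 10, threshold_scale = 2), 5)
})

test_that("feature extraction is constant on constant images and translates", {
  cfg <- small_net_config()
  X <- extract_features(matrix(100, 32, 32), cfg)
  expect_lt(max(apply(X, 2, function(col) diff(range(col)))), 1e-12)

  # Content translated away from borders yields translated features.
  A <- matrix(20, 48, 48)
  A[20:24, 18:22] <- 240
  B <- matrix(20, 48, 48)
  B[23:27, 23:27] <- 240 # shifted by (3, 5)
  FA <- extract_features(A, cfg)
  FB <- extract_features(B, cfg)
  at <- function(Fm, r, c) Fm[(c - 1) * 48 + r, ]
  expect_equal(at(FA, 22, 20), at(FB, 25, 25), tolerance = 1e-10)

  expect_error(extract_features(matrix(0, 8, 8), cfg), "smaller")
})

test_that("single bright pixel propagates through identity stencil chain", {
  # One identity-like filter per stage; linear activation; raw channel
  # features off, so the chain is: rate code -> delta conv -> 7x7 average
  # pool -> delta conv -> 5x5 max pool.
  cfg <- net_config(n_filters1 = 1, n_filters2 = 1, activation = "identity",
                    include_raw = FALSE, spike_window = 16, seed = 1)
  delta9 <- array(0, dim = c(9, 9, 1, 1))
  delta9[5, 5, 1, 1] <- 1
  bank <- list(f1 = delta9, f2 = delta9)

  img <- matrix(0, 11, 11)
  img[6, 6] <- 255
  X <- extract_features(img, cfg, bank = bank)
  got <- matrix(X[, 1], 11, 11)

  # Independent hand-tracked propagation: the rate code is 1 at the bright
  # pixel; averaging spreads 1/49 over the 7x7 block; the 5x5 max then
  # extends the plateau by Chebyshev radius 2.
  expected <- matrix(0, 11, 11)
  for (r in 1:11) {
    for (c in 1:11) {
      if (max(abs(r - 6), abs(c - 6)) <= 5) {
        expected[r, c] <- 1 / 49
      }
    }
  }
  expect_equal(got, expected, tolerance = 1e-12)
})

test_that("hidden map computes g(Wx + b)", {
  expect_equal(as.vector(hidden_map(matrix(1, 1, 3), matrix(0, 3, 2), c(0, 0),
                                    identity)), c(0, 0))
  expect_equal(as.vector(hidden_map(matrix(1, 1, 1), matrix(2, 1, 1), 1,
                                    identity)), 3)
  expect_equal(as.vector(hidden_map(matrix(0, 1, 1), matrix(5, 1, 1), 0)), 0.5)
  expect_error(hidden_map(matrix(1, 1, 2), matrix(1, 3, 2), c(0, 0)))
})

test_that("output-weight solve is a generalized inverse", {
  expect_equal(solve_output_weights(diag(2), diag(2)), diag(2))

  set.seed(10)
  H <- matrix(rnorm(9), 3, 3) + 3 * diag(3)
  Y <- matrix(rnorm(6), 3, 2)
  expect_equal(solve_output_weights(H, Y), solve(H, Y), tolerance = 1e-10)

  # Rank-deficient H (duplicated column): residual orthogonal to col(H) and
  # minimum-norm signature (weights shared across the duplicated columns).
  h <- matrix(rnorm(8), 4, 2)
  H <- cbind(h[, 1], h[, 1], h[, 2])
  Y <- matrix(rnorm(8), 4, 2)
  beta <- solve_output_weights(H, Y)
  expect_lt(max(abs(crossprod(H, H %*% beta - Y))), 1e-8)
  expect_equal(beta[1, ], beta[2, ], tolerance = 1e-8)

  # Column permutation of targets permutes the solution columns.
  expect_equal(solve_output_weights(H, Y[, 2:1]), beta[, 2:1])

  expect_error(solve_output_weights(matrix(numeric(0), 0, 0), matrix(0, 0, 1)))
})

test_that("least-squares solution beats random output weights", {
  set.seed(21)
  H <- matrix(rnorm(100), 20, 5)
  Y <- matrix(rnorm(40), 20, 2)
  beta <- solve_output_weights(H, Y)
  res <- sum((H %*% beta - Y)^2)
  for (k in 1:100) {
    cand <- matrix(rnorm(10), 5, 2)
    expect_lte(res, sum((H %*% cand - Y)^2) + 1e-9)
  }
})

test_that("training is deterministic and separates easy phantoms", {
  ds <- small_dataset(n = 6, seed = 7)
  cfg <- small_net_config(seed = 7)
  m1 <- dsnn_train(ds, cfg)
  m2 <- dsnn_train(ds, cfg)
  expect_identical(m1$beta, m2$beta)
  expect_identical(m1$train_idx, m2$train_idx)

  accs <- vapply(m1$test_idx, function(i) {
    pixel_accuracy(predict_labels(predict_proba(ds[[i]], m1)), ds[[i]]$labels)
  }, numeric(1))
  expect_gte(min(accs), 0.95)

  # Single-class labels make one-hot targets degenerate.
  flat <- lapply(ds[1:2], function(ph) {
    ph$labels[] <- 0L
    ph
  })
  expect_error(dsnn_train(flat, cfg), "single class")
})

test_that("probability maps are normalized softmax outputs", {
  ds <- small_dataset(n = 4, seed = 11, size = 48)
  model <- dsnn_train(ds, small_net_config(seed = 11))
  P <- predict_proba(ds[[1]], model)
  expect_true(all(P >= 0))
  expect_lt(max(abs(apply(P, c(1, 2), sum) - 1)), 1e-9)

  # Softmax closed forms through the shared kernel.
  sm <- qaisdsnn:::softmax_rows
  expect_equal(as.vector(sm(matrix(c(0, log(3)), 1, 2))), c(0.25, 0.75))
  expect_equal(as.vector(sm(matrix(c(1, 1, 1), 1, 3))), rep(1 / 3, 3))
  dominated <- sm(matrix(c(0, 100), 1, 2))
  expect_gt(dominated[1, 2], 0.99)

  # A dominant logit offset drives the argmax probability to ~1.
  model$logit_offsets[1] <- 100
  P2 <- predict_proba(ds[[1]], model)
  expect_true(all(P2[, , 1] > 0.99))

  expect_error(predict_proba(ds[[1]], structure(list(), class = "seg_model")))
})

test_that("iterative output refinement honours its stopping contract", {
  ds <- small_dataset(n = 4, seed = 5, size = 48)
  model <- dsnn_train(ds, small_net_config(seed = 5))
  refined <- refine_output_weights(model, epochs = 25, mse_target = 1e-5)
  tr <- attr(refined, "mse_trace")
  expect_lte(length(tr), 25)
  expect_lte(attr(refined, "mse"), tr[1]) # elitist: best weights kept
})
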
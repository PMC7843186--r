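# DSNN: spiking-flavoured segmentation network.
#
# Per-pixel features come from a fixed, seeded conv/pool stack applied to
# rate-coded (integrate-and-fire) channel intensities:
#   spike encode -> conv 9x9 -> average pool 7x7 -> conv 9x9 -> max pool 5x5,
# all stride 1 with replicate padding so every pixel keeps a feature vector.
# Classification is a random-hidden-layer model h = g(W x + b) whose output
# weights are solved in closed form by a (ridge-stabilized) generalized
# inverse of the hidden-activation matrix H — no iterative weight updates in
# the default mode. An optional Rprop-style refinement of the output layer is
# provided for completeness.

activation_fn <- function(name) {
  switch(name,
    sigmoid = function(x) 1 / (1 + exp(-x)),
    tanh = tanh,
    relu = function(x) pmax(x, 0),
    identity = identity,
    stop("unknown activation: ", name)
  )
}

#' Segmentation network configuration
#'
#' Window sizes follow the 9x9 convolution / 7x7 pooling / 9x9 convolution /
#' 5x5 max-pooling stage geometry; counts of random filters and hidden units
#' are desk-scale defaults.
#'
#' @param conv_window,pool_window,conv2_window,maxpool_window Odd window
#'   sizes of the four feature stages.
#' @param n_filters1,n_filters2 Number of seeded random filters in the two
#'   convolution stages.
#' @param n_hidden Hidden-layer width m of the random projection.
#' @param activation Name of the hidden nonlinearity g (`"sigmoid"`,
#'   `"tanh"`, `"relu"`, `"identity"`).
#' @param spike_window Integrate-and-fire time window (timesteps) of the rate
#'   code.
#' @param threshold_scale Membrane-threshold scale of the rate code (1 means
#'   a full-scale pixel fires every timestep).
#' @param include_raw Append the rate-coded raw channels to the conv features.
#' @param ridge Ridge stabilization of the output-weight solve.
#' @param epochs_cap,mse_target Iteration cap and mean-squared-error stopping
#'   target of the optional iterative refinement mode (defaults 7000 and
#'   1e-5); the closed-form solve ignores both.
#' @param train_fraction Fraction of images used for training (default 0.75,
#'   i.e. a 75/25 split).
#' @param pixels_per_image Per-image training-pixel subsample (stratified by
#'   class) feeding the output solve.
#' @param seed Seed of the random filters, hidden weights and split shuffle.
#' @return List of class `net_config`.
#' @export
net_config <- function(conv_window = 9, pool_window = 7, conv2_window = 9,
                       maxpool_window = 5, n_filters1 = 4, n_filters2 = 6,
                       n_hidden = 64, activation = "sigmoid",
                       spike_window = 16, threshold_scale = 1,
                       include_raw = TRUE, ridge = 1e-6,
                       epochs_cap = 7000, mse_target = 1e-5,
                       train_fraction = 0.75, pixels_per_image = 1500,
                       seed = 1) {
  wins <- c(conv_window, pool_window, conv2_window, maxpool_window)
  stopifnot(
    all(wins %% 2 == 1), all(wins > 0),
    n_filters1 >= 1, n_filters2 >= 1, n_hidden >= 1,
    spike_window >= 1, threshold_scale > 0, ridge >= 0,
    train_fraction > 0, train_fraction < 1, pixels_per_image >= 1
  )
  activation_fn(activation) # validates the name
  structure(
    list(conv_window = conv_window, pool_window = pool_window,
         conv2_window = conv2_window, maxpool_window = maxpool_window,
         n_filters1 = n_filters1, n_filters2 = n_filters2,
         n_hidden = n_hidden, activation = activation,
         spike_window = spike_window, threshold_scale = threshold_scale,
         include_raw = include_raw, ridge = ridge,
         epochs_cap = epochs_cap, mse_target = mse_target,
         train_fraction = train_fraction,
         pixels_per_image = pixels_per_image, seed = seed),
    class = "net_config"
  )
}

#' Integrate-and-fire rate coding
#'
#' Deterministic spike count over a time window: a pixel of intensity `x`
#' fires `floor(x * window / (255 * threshold_scale))` spikes, so the code is
#' zero at zero intensity, saturates at `window` for a full-scale pixel at
#' unit threshold, and is monotone non-decreasing in intensity.
#'
#' @param x Intensities in [0, 255] (any numeric shape).
#' @param window Number of timesteps (>= 1).
#' @param threshold_scale Membrane-threshold scale (> 0).
#' @return Spike counts, same shape as `x`.
#' @examples
#' encode_spikes(128, window = 10) # floor(10 * 128 / 255) = 5
#' @export
encode_spikes <- function(x, window, threshold_scale = 1) {
  stopifnot(window >= 1, threshold_scale > 0)
  pmax(floor(x * window / (255 * threshold_scale)), 0)
}

# Seeded random filter banks and hidden weights for a given input dimension.
make_filter_bank <- function(config, n_channels) {
  local_seed(derive_seed(config$seed, 11L), {
    f1 <- array(
      stats::rnorm(config$conv_window^2 * n_channels * config$n_filters1,
                   0, 1 / sqrt(config$conv_window^2 * n_channels)),
      dim = c(config$conv_window, config$conv_window, n_channels,
              config$n_filters1)
    )
    f2 <- array(
      stats::rnorm(config$conv2_window^2 * config$n_filters1 *
                     config$n_filters2,
                   0, 1 / sqrt(config$conv2_window^2 * config$n_filters1)),
      dim = c(config$conv2_window, config$conv2_window, config$n_filters1,
              config$n_filters2)
    )
    list(f1 = f1, f2 = f2)
  })
}

conv_bank <- function(maps, filters, act) {
  n_in <- length(maps)
  n_out <- dim(filters)[4]
  out <- vector("list", n_out)
  for (f in seq_len(n_out)) {
    acc <- matrix(0, nrow(maps[[1]]), ncol(maps[[1]]))
    for (ch in seq_len(n_in)) {
      acc <- acc + conv2_replicate(maps[[ch]], filters[, , ch, f])
    }
    out[[f]] <- act(acc)
  }
  out
}

#' Per-pixel feature extraction
#'
#' Applies the fixed seeded stack (spike rate code, 9x9 random convolution,
#' 7x7 average pooling, 9x9 random convolution, 5x5 max pooling; stride 1,
#' replicate padding) to a named list of channel matrices, yielding one
#' feature vector per pixel. The filter bank depends only on the config seed,
#' so features of translated content translate identically away from
#' borders.
#'
#' @param channels Named list of `H x W` intensity matrices (or a single
#'   matrix).
#' @param config A [net_config()].
#' @param bank Optional precomputed filter bank (from a trained model) to
#'   guarantee train/predict consistency.
#' @return `H*W x F` feature matrix (row-major over pixels in column-major
#'   matrix order), with attribute `shape = c(H, W)`.
#' @export
extract_features <- function(channels, config = net_config(), bank = NULL) {
  if (is.matrix(channels)) {
    channels <- list(channels)
  }
  h <- nrow(channels[[1]])
  w <- ncol(channels[[1]])
  biggest <- max(config$conv_window, config$pool_window, config$conv2_window,
                 config$maxpool_window)
  if (h < biggest || w < biggest) {
    stop("image smaller than the largest window (", biggest, ")")
  }
  if (is.null(bank)) {
    bank <- make_filter_bank(config, length(channels))
  }
  act <- activation_fn(config$activation)
  rate <- lapply(channels, function(ch) {
    encode_spikes(ch, config$spike_window, config$threshold_scale) /
      config$spike_window
  })
  s1 <- conv_bank(rate, bank$f1, act)
  s2 <- lapply(s1, pool_mean, win = config$pool_window)
  s3 <- conv_bank(s2, bank$f2, act)
  s4 <- lapply(s3, pool_max, win = config$maxpool_window)
  feats <- if (config$include_raw) c(s4, rate) else s4
  X <- do.call(cbind, lapply(feats, as.vector))
  attr(X, "shape") <- c(h, w)
  X
}

#' Hidden-layer mapping
#'
#' One row of the hidden-activation matrix H per input row:
#' `h_j = g(sum_i w_ij x_i + b_j)`.
#'
#' @param x Feature matrix (`n x F`) or a single feature vector.
#' @param W `F x m` input-to-hidden weights.
#' @param b Length-`m` biases.
#' @param g Activation function.
#' @return `n x m` activation matrix.
#' @export
hidden_map <- function(x, W, b, g = function(z) 1 / (1 + exp(-z))) {
  if (!is.matrix(x)) {
    x <- matrix(x, nrow = 1)
  }
  if (ncol(x) != nrow(W) || ncol(W) != length(b)) {
    stop("dimension mismatch between x, W and b")
  }
  g(sweep(x %*% W, 2, b, "+"))
}

#' Closed-form output-weight solve
#'
#' Minimum-norm least-squares solution `beta` of `H beta = Y` via the
#' Moore-Penrose generalized inverse (`ridge = 0`), or the ridge-stabilized
#' normal equations `(H'H + ridge I) beta = H'Y` for `ridge > 0`. At
#' `ridge = 0` the residual `H beta - Y` is orthogonal to the column space
#' of H.
#'
#' @param H `n x m` hidden-activation matrix.
#' @param Y `n x C` one-hot (or general) target matrix.
#' @param ridge Non-negative ridge parameter.
#' @return `m x C` output-weight matrix.
#' @export
solve_output_weights <- function(H, Y, ridge = 0) {
  if (!is.matrix(H) || nrow(H) == 0L) {
    stop("H must be a non-empty matrix")
  }
  Y <- as.matrix(Y)
  stopifnot(nrow(H) == nrow(Y), ridge >= 0)
  if (ridge > 0) {
    solve(crossprod(H) + ridge * diag(ncol(H)), crossprod(H, Y))
  } else {
    MASS::ginv(H) %*% Y
  }
}

one_hot <- function(labels, classes) {
  Y <- matrix(0, length(labels), length(classes))
  Y[cbind(seq_along(labels), match(labels, classes))] <- 1
  Y
}

# Stratified per-image pixel subsample: keeps every class represented.
sample_pixels <- function(labels_vec, n_pixels, seed) {
  local_seed(seed, {
    classes <- sort(unique(labels_vec))
    per_class <- max(1L, ceiling(n_pixels / length(classes)))
    idx <- unlist(lapply(classes, function(k) {
      pool <- which(labels_vec == k)
      pool[sample.int(length(pool), min(per_class, length(pool)))]
    }))
    sort(idx)
  })
}

#' Train the segmentation network
#'
#' Shuffles the images with the config seed, keeps `train_fraction` (default
#' 75%) for training, extracts per-pixel features from a stratified pixel
#' subsample of each training image and solves the output weights in closed
#' form. Training is deterministic given the dataset and seed.
#'
#' @param dataset List of phantoms (or lists with `channels` and `labels`);
#'   elements may carry a `noisy` or `denoised` channel set, which is
#'   preferred over the clean channels when present (denoised first).
#' @param config A [net_config()].
#' @return A `seg_model`: filter bank, hidden weights, solved output weights,
#'   class list, train/test split indices, training MSE, and the cached
#'   training design (`H`, `Y`) used by decision-layer tuning.
#' @export
dsnn_train <- function(dataset, config = net_config()) {
  stopifnot(length(dataset) >= 2)
  n <- length(dataset)
  split <- local_seed(derive_seed(config$seed, 23L), sample.int(n))
  n_train <- max(1L, floor(config$train_fraction * n))
  train_idx <- sort(split[seq_len(n_train)])
  test_idx <- sort(split[-seq_len(n_train)])

  n_channels <- length(model_channels(dataset[[train_idx[1]]]))
  bank <- make_filter_bank(config, n_channels)

  X_list <- list()
  y_list <- list()
  for (i in train_idx) {
    ch <- model_channels(dataset[[i]])
    X <- extract_features(ch, config, bank)
    lab <- as.vector(dataset[[i]]$labels)
    keep <- sample_pixels(lab, config$pixels_per_image,
                          derive_seed(config$seed, 1000L + i))
    X_list[[length(X_list) + 1L]] <- X[keep, , drop = FALSE]
    y_list[[length(y_list) + 1L]] <- lab[keep]
  }
  X <- do.call(rbind, X_list)
  y <- unlist(y_list)
  classes <- sort(unique(y))
  if (length(classes) < 2) {
    stop("training labels contain a single class; one-hot targets degenerate")
  }

  n_feat <- ncol(X)
  wb <- local_seed(derive_seed(config$seed, 37L), {
    list(
      W = matrix(stats::rnorm(n_feat * config$n_hidden, 0, 1 / sqrt(n_feat)),
                 n_feat, config$n_hidden),
      b = stats::runif(config$n_hidden, -1, 1)
    )
  })
  g <- activation_fn(config$activation)
  H <- hidden_map(X, wb$W, wb$b, g)
  Y <- one_hot(y, classes)
  beta <- solve_output_weights(H, Y, config$ridge)
  train_mse <- mean((H %*% beta - Y)^2)

  structure(
    list(config = config, classes = classes, bank = bank,
         W = wb$W, b = wb$b, beta = beta,
         feature_mask = rep(TRUE, config$n_hidden),
         logit_offsets = rep(0, length(classes)),
         train_idx = train_idx, test_idx = test_idx,
         train_mse = train_mse, train_H = H, train_Y = Y),
    class = "seg_model"
  )
}

# Channel set a model should see for an image: denoised > noisy > clean.
model_channels <- function(img) {
  img$denoised %||% img$noisy %||% img$channels
}

#' @export
print.seg_model <- function(x, ...) {
  cat(sprintf(
    "<seg_model> classes: %s | hidden: %d | features: %d | train MSE %.3g\n",
    paste(x$classes, collapse = ","), ncol(x$train_H), nrow(x$W), x$train_mse
  ))
  invisible(x)
}

softmax_rows <- function(S) {
  S <- S - apply(S, 1, max)
  E <- exp(S)
  E / rowSums(E)
}

# Per-pixel class scores for an image under a (possibly masked/offset) model.
model_scores <- function(channels, model) {
  X <- extract_features(channels, model$config, model$bank)
  H <- hidden_map(X, model$W, model$b, activation_fn(model$config$activation))
  mask <- model$feature_mask
  S <- H[, mask, drop = FALSE] %*% model$beta[mask, , drop = FALSE]
  sweep(S, 2, model$logit_offsets, "+")
}

#' Per-pixel class probabilities
#'
#' Softmax over the output scores of every pixel; each pixel's probabilities
#' sum to one.
#'
#' @param image A phantom, a named list of channel matrices, or a matrix.
#' @param model A trained `seg_model`.
#' @return `H x W x C` probability array with attribute `classes`.
#' @export
predict_proba <- function(image, model) {
  if (!inherits(model, "seg_model") || is.null(model$beta)) {
    stop("model must be a trained seg_model")
  }
  channels <- if (inherits(image, "phantom")) model_channels(image) else image
  if (is.matrix(channels)) {
    channels <- list(channels)
  }
  S <- model_scores(channels, model)
  P <- softmax_rows(S)
  shape <- c(nrow(channels[[1]]), ncol(channels[[1]]))
  out <- array(P, dim = c(shape, length(model$classes)))
  attr(out, "classes") <- model$classes
  out
}

#' Hard label map from a probability array
#'
#' @param probs `H x W x C` array from [predict_proba()] (or the CRF refiner).
#' @param classes Class codes; defaults to the array's `classes` attribute.
#' @return Integer label matrix.
#' @export
predict_labels <- function(probs, classes = attr(probs, "classes")) {
  stopifnot(length(dim(probs)) == 3)
  flat <- matrix(probs, prod(dim(probs)[1:2]), dim(probs)[3])
  matrix(classes[max.col(flat, ties.method = "first")],
         dim(probs)[1], dim(probs)[2])
}

#' Iterative (Rprop-style) refinement of the output layer
#'
#' Optional training mode: resilient sign-based updates of the output weights
#' against the cached training design, stopping at `epochs` rounds or when
#' the training MSE reaches `mse_target`. The closed-form solve already
#' minimizes the same criterion, so this mode exists for protocol parity, not
#' accuracy.
#'
#' @param model A trained `seg_model`.
#' @param epochs Round cap (default: config `epochs_cap`, 7000).
#' @param mse_target Stopping MSE (default: config `mse_target`, 1e-5).
#' @return The model with updated `beta` and an `mse_trace` attribute.
#' @export
refine_output_weights <- function(model, epochs = model$config$epochs_cap,
                                  mse_target = model$config$mse_target) {
  H <- model$train_H
  Y <- model$train_Y
  beta <- model$beta
  step <- matrix(0.01, nrow(beta), ncol(beta))
  prev_sign <- matrix(0, nrow(beta), ncol(beta))
  trace <- numeric(0)
  best_beta <- beta
  best_mse <- Inf
  for (ep in seq_len(epochs)) {
    R <- H %*% beta - Y
    mse <- mean(R^2)
    trace <- c(trace, mse)
    if (mse < best_mse) {
      best_mse <- mse
      best_beta <- beta
    }
    if (mse <= mse_target) break
    Gr <- crossprod(H, R)
    s <- sign(Gr)
    step <- ifelse(s * prev_sign > 0, pmin(step * 1.2, 1),
                   ifelse(s * prev_sign < 0, step * 0.5, step))
    beta <- beta - s * step
    prev_sign <- s
  }
  # Elitist: keep the best-MSE weights seen (Rprop steps are not monotone).
  model$beta <- best_beta
  attr(model, "mse_trace") <- trace
  attr(model, "mse") <- best_mse
  model
}
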
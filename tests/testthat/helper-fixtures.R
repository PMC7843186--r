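# Shared fixtures: small CRF instances with moderate coupling and a compact
# training dataset, all built in code at test time.

# Random two-class CRF instance whose unary gaps stay bounded away from zero
# (|gap| in [0.4, 2] nats) so the exact MAP is informative; kernel weights
# around 0.08 then put the total pairwise pull on a pixel at the order of the
# weakest unary evidence ("moderate coupling").
random_crf_instance <- function(seed, n_min = 5, n_max = 9) {
  set.seed(seed)
  n <- sample(n_min:n_max, 1)
  gaps <- stats::runif(n, 0.4, 2) * sample(c(-1, 1), n, replace = TRUE)
  unary <- cbind(pmax(gaps, 0), pmax(-gaps, 0))
  crf_instance(
    unary = unary,
    positions = cbind(stats::runif(n, 0, 4), stats::runif(n, 0, 4)),
    intensities = stats::runif(n, 0, 255)
  )
}

moderate_crf_params <- function(n_iters = 10) {
  crf_params(w1 = 0.08, w2 = 0.08, theta_alpha = 2, theta_beta = 40,
             theta_gamma = 2, n_iters = n_iters)
}

# Small easy dataset: high-contrast phantoms with mild acquisition noise.
small_dataset <- function(n = 6, seed = 7, size = 64, noise = 10) {
  generate_phantom_dataset(n, seed, size, size, "gaussian", noise)
}

small_net_config <- function(seed = 7, ...) {
  net_config(n_filters1 = 2, n_filters2 = 3, n_hidden = 32,
             pixels_per_image = 600, seed = seed, ...)
}
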
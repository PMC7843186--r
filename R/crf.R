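# Fully-connected CRF refinement.
#
# Energy over a labelling y of N pixels:
#   E(y) = sum_i psi_u(y_i) + sum_{ordered pairs i != j} mu(y_i, y_j)
#          * ( w1 * k1(f_i, f_j) + w2 * k2(f_i, f_j) )
# with Potts compatibility mu(a, b) = [a != b], a bilateral appearance kernel
#   k1 = exp(-|s_i - s_j|^2 / theta_alpha^2 - (e_i - e_j)^2 / theta_beta^2)
# and a spatial smoothness kernel
#   k2 = exp(-|s_i - s_j|^2 / theta_gamma^2).
# Inference is parallel mean field: naive O(N^2) message passing for small
# instances (oracle-verifiable against exact enumeration) and a truncated
# neighbourhood mode for images.

#' CRF parameters
#'
#' @param w1,w2 Non-negative weights of the appearance and smoothness
#'   kernels.
#' @param theta_alpha Spatial bandwidth of the appearance kernel (pixels).
#' @param theta_beta Intensity bandwidth of the appearance kernel (8-bit
#'   intensity units).
#' @param theta_gamma Spatial bandwidth of the smoothness kernel (pixels).
#' @param n_iters Mean-field iterations (>= 1).
#' @return List of class `crf_params`.
#' @export
crf_params <- function(w1 = 1, w2 = 1, theta_alpha = 8, theta_beta = 16,
                       theta_gamma = 3, n_iters = 5) {
  stopifnot(
    w1 >= 0, w2 >= 0, theta_alpha > 0, theta_beta > 0, theta_gamma > 0,
    n_iters >= 1
  )
  structure(
    list(w1 = w1, w2 = w2, theta_alpha = theta_alpha,
         theta_beta = theta_beta, theta_gamma = theta_gamma,
         n_iters = n_iters),
    class = "crf_params"
  )
}

#' Small CRF instance
#'
#' A pixel-list representation used by the exact oracle and the dense
#' mean-field solver.
#'
#' @param unary `N x C` matrix of unary potentials `psi_u` (use
#'   [unary_from_probs()] to build it from probabilities).
#' @param positions `N x 2` pixel coordinates `s_i`.
#' @param intensities Length-`N` intensities `e_i`.
#' @return List of class `crf_instance`.
#' @export
crf_instance <- function(unary, positions, intensities) {
  unary <- as.matrix(unary)
  positions <- as.matrix(positions)
  stopifnot(
    nrow(unary) == nrow(positions), ncol(positions) == 2,
    length(intensities) == nrow(unary), all(is.finite(unary))
  )
  structure(
    list(unary = unary, positions = positions,
         intensities = as.numeric(intensities)),
    class = "crf_instance"
  )
}

#' Unary potentials from class probabilities
#'
#' `psi_u(y_i) = -log(max(P(y_i | I), clamp))`; the clamp keeps zero
#' probabilities finite.
#'
#' @param probs Probability matrix (`N x C`) or array (`H x W x C`).
#' @param clamp Lower probability clamp (default 1e-10).
#' @return Same shape as `probs`, negative log probabilities.
#' @export
unary_from_probs <- function(probs, clamp = 1e-10) {
  -log(pmax(probs, clamp))
}

#' Pairwise Gaussian kernels
#'
#' `appearance_kernel` is the bilateral kernel k1 (near 1 for close pixels of
#' similar intensity); `smoothness_kernel` is the purely spatial kernel k2.
#' Both are symmetric and take values in (0, 1].
#'
#' @param s_i,s_j Length-2 pixel positions.
#' @param e_i,e_j Scalar intensities.
#' @param theta_alpha,theta_beta,theta_gamma Positive bandwidths.
#' @return Scalar kernel value.
#' @examples
#' appearance_kernel(c(0, 0), c(3, 4), 100, 100, theta_alpha = 5,
#'                   theta_beta = 16) # exp(-1)
#' @export
appearance_kernel <- function(s_i, s_j, e_i, e_j, theta_alpha, theta_beta) {
  stopifnot(theta_alpha > 0, theta_beta > 0)
  exp(-sum((s_i - s_j)^2) / theta_alpha^2 - (e_i - e_j)^2 / theta_beta^2)
}

#' @rdname appearance_kernel
#' @export
smoothness_kernel <- function(s_i, s_j, theta_gamma) {
  stopifnot(theta_gamma > 0)
  exp(-sum((s_i - s_j)^2) / theta_gamma^2)
}

# Dense pairwise-weight matrix w1*k1 + w2*k2 with zero diagonal.
pair_weight_matrix <- function(instance, params) {
  s <- instance$positions
  e <- instance$intensities
  d2 <- as.matrix(stats::dist(s))^2
  de2 <- outer(e, e, "-")^2
  K <- params$w1 * exp(-d2 / params$theta_alpha^2 - de2 / params$theta_beta^2) +
    params$w2 * exp(-d2 / params$theta_gamma^2)
  diag(K) <- 0
  K
}

#' CRF energy of a labelling
#'
#' Unary sum plus the pairwise Potts term over all ordered pairs `i != j`
#' (each unordered pair therefore contributes twice, exactly as the energy is
#' written).
#'
#' @param labels Integer labels in `1..C`, length N.
#' @param instance A [crf_instance()].
#' @param params A [crf_params()].
#' @return Scalar energy.
#' @export
crf_energy <- function(labels, instance, params) {
  n <- nrow(instance$unary)
  stopifnot(length(labels) == n,
            all(labels >= 1), all(labels <= ncol(instance$unary)))
  K <- pair_weight_matrix(instance, params)
  diff <- outer(labels, labels, "!=")
  sum(instance$unary[cbind(seq_len(n), labels)]) + sum(K * diff)
}

#' Exact MAP labelling by exhaustive enumeration
#'
#' Brute-force argmin of the CRF energy over all `C^N` labellings; the
#' oracle for mean-field inference. Ties break toward the lexicographically
#' smallest labelling. Limited to N <= 12 pixels and C <= 3 classes.
#'
#' @param instance A [crf_instance()].
#' @param params A [crf_params()].
#' @return Integer label vector (values in `1..C`) with attribute `energy`.
#' @export
brute_force_map <- function(instance, params) {
  n <- nrow(instance$unary)
  C <- ncol(instance$unary)
  if (n > 12 || C > 3) {
    stop("instance too large for exhaustive enumeration (N <= 12, C <= 3)")
  }
  K <- pair_weight_matrix(instance, params)
  n_lab <- C^n
  best <- NULL
  best_e <- Inf
  digits <- C^(rev(seq_len(n)) - 1)
  for (r in 0:(n_lab - 1)) {
    lab <- (r %/% digits) %% C + 1
    e <- sum(instance$unary[cbind(seq_len(n), lab)]) +
      sum(K * outer(lab, lab, "!="))
    if (e < best_e - 1e-12) {
      best_e <- e
      best <- lab
    }
  }
  structure(best, energy = best_e)
}

#' Mean-field inference on a small dense instance
#'
#' Parallel mean-field updates
#' `Q_i(l) proportional to exp(-psi_u(l) - sum_{j != i} sum_{l'} Q_j(l')
#' mu(l, l') (w1 k1 + w2 k2))`, renormalized every iteration. With zero
#' kernel weights the output equals the input probabilities.
#'
#' @param instance A [crf_instance()].
#' @param params A [crf_params()].
#' @return List with `Q` (`N x C`, rows summing to 1), `labels` (per-pixel
#'   argmax) and `energy` of the MAP labelling.
#' @export
mean_field_infer <- function(instance, params) {
  stopifnot(inherits(instance, "crf_instance"), inherits(params, "crf_params"))
  U <- instance$unary
  K <- pair_weight_matrix(instance, params)
  Q <- softmax_rows(-U)
  for (it in seq_len(params$n_iters)) {
    M <- K %*% Q
    penalty <- rowSums(M) - M # Potts: sum over labels l' != l
    Q <- softmax_rows(-U - penalty)
  }
  dimnames(Q) <- NULL
  labels <- max.col(Q, ties.method = "first")
  list(Q = Q, labels = labels,
       energy = crf_energy(labels, instance, params))
}

#' CRF refinement of an image probability map
#'
#' Truncated-neighbourhood mean field for images: messages are accumulated
#' over all pixel offsets within `radius` (zero-fill at borders, so
#' non-existent neighbours contribute nothing). The bilateral term uses the
#' supplied reference channel.
#'
#' @param probs `H x W x C` probability array (e.g. from [predict_proba()]).
#' @param reference `H x W` intensity matrix feeding the appearance kernel
#'   (typically the denoised FLAIR-like channel).
#' @param params A [crf_params()].
#' @param radius Neighbourhood truncation radius in pixels.
#' @return `H x W x C` refined probability array (same `classes` attribute),
#'   with attribute `labels`, the refined MAP label matrix.
#' @export
crf_refine <- function(probs, reference, params = crf_params(), radius = 4) {
  stopifnot(length(dim(probs)) == 3, is.matrix(reference),
            all(dim(probs)[1:2] == dim(reference)), radius >= 1)
  h <- dim(probs)[1]
  w <- dim(probs)[2]
  C <- dim(probs)[3]
  classes <- attr(probs, "classes")
  U <- array(unary_from_probs(probs), dim = dim(probs))

  offsets <- expand.grid(dr = -radius:radius, dc = -radius:radius)
  offsets <- offsets[offsets$dr != 0 | offsets$dc != 0, ]
  offsets <- offsets[offsets$dr^2 + offsets$dc^2 <= radius^2, ]

  # Per-offset weights: spatial parts are constants, bilateral part is a map.
  spatial1 <- exp(-(offsets$dr^2 + offsets$dc^2) / params$theta_alpha^2)
  spatial2 <- exp(-(offsets$dr^2 + offsets$dc^2) / params$theta_gamma^2)

  Q <- matrix(probs, h * w, C)
  for (it in seq_len(params$n_iters)) {
    M <- array(0, dim = c(h, w, C))
    for (o in seq_len(nrow(offsets))) {
      dr <- offsets$dr[o]
      dc <- offsets$dc[o]
      eshift <- shift_zero(reference, dr, dc)
      # zero-filled shift loses the border intensities; mask via indicator
      ind <- shift_zero(matrix(1, h, w), dr, dc)
      bilat <- exp(-(reference - eshift)^2 / params$theta_beta^2) * ind
      wmap <- params$w1 * spatial1[o] * bilat + params$w2 * spatial2[o] * ind
      for (l in seq_len(C)) {
        M[, , l] <- M[, , l] + wmap * shift_zero(matrix(Q[, l], h, w), dr, dc)
      }
    }
    Mtot <- apply(M, 1:2, sum)
    S <- matrix(0, h * w, C)
    for (l in seq_len(C)) {
      S[, l] <- -as.vector(U[, , l]) - as.vector(Mtot - M[, , l])
    }
    Q <- softmax_rows(S)
  }
  out <- array(Q, dim = c(h, w, C))
  attr(out, "classes") <- classes
  lab_idx <- matrix(max.col(Q, ties.method = "first"), h, w)
  attr(out, "labels") <- if (is.null(classes)) {
    lab_idx
  } else {
    matrix(classes[lab_idx], h, w)
  }
  out
}
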
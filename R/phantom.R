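# Synthetic multi-contrast brain phantoms.
#
# Every downstream stage (denoising, segmentation, CRF refinement, immune
# tuning) is exercised on these seeded phantoms, so the generator is
# first-class, deterministic code: identical seeds yield bit-identical output.
# The tissue taxonomy follows the standard five-class brain-tumor labelling
# (background / normal tissue / peritumoral edema / enhancing core / necrosis)
# with the composite regions WT (whole tumor), TC (tumor core) and ET
# (enhancing tumor) nested as ET
# \eqn{\subseteq} TC \eqn{\subseteq} WT.

#' Phantom tissue classes
#'
#' Integer label codes used throughout the package.
#'
#' @format Named integer vector.
#' @export
PHANTOM_CLASSES <- c(
  background = 0L, normal = 1L, edema = 2L, core = 3L, necrosis = 4L
)

#' Phantom generator configuration
#'
#' Geometry and contrast parameters of the synthetic brain phantom. The brain
#' is an ellipse; the tumor is a set of nested noisy blobs (necrosis inside
#' enhancing core inside edema). Per-class channel means are chosen so that
#' edema is bright on the FLAIR/T2-like channels and the enhancing core is the
#' brightest tissue on the T1ce-like channel, mirroring how radiologists read
#' the corresponding MRI contrasts.
#'
#' @param edema_frac Area of the edema blob as a fraction of the brain ellipse.
#' @param core_frac Area of the enhancing core as a fraction of the edema blob.
#' @param necrosis_frac Area of necrosis as a fraction of the core.
#' @param texture_sd Standard deviation (8-bit intensity units) of the
#'   within-tissue texture noise baked into the clean phantom.
#' @param boundary_wobble Relative amplitude of the harmonic perturbation of
#'   the tumor boundary radius (0 = perfect circles).
#' @param means Optional 5 x 4 matrix of per-class channel means
#'   (rows: classes 0-4; columns: flair, t1, t1ce, t2), values in [0, 255].
#' @return A list of class `phantom_config`.
#' @export
phantom_config <- function(edema_frac = 0.12,
                           core_frac = 0.45,
                           necrosis_frac = 0.35,
                           texture_sd = 6,
                           boundary_wobble = 0.15,
                           means = NULL) {
  stopifnot(
    edema_frac > 0, edema_frac < 1,
    core_frac > 0, core_frac < 1,
    necrosis_frac > 0, necrosis_frac < 1,
    texture_sd >= 0, boundary_wobble >= 0
  )
  if (is.null(means)) {
    means <- rbind(
      background = c(5, 5, 5, 5),
      normal     = c(120, 140, 130, 110),
      edema      = c(200, 110, 140, 190),
      core       = c(170, 120, 220, 150),
      necrosis   = c(150, 70, 60, 170)
    )
    colnames(means) <- c("flair", "t1", "t1ce", "t2")
  }
  stopifnot(nrow(means) == 5L, ncol(means) == 4L, all(means >= 0), all(means <= 255))
  structure(
    list(
      edema_frac = edema_frac, core_frac = core_frac,
      necrosis_frac = necrosis_frac, texture_sd = texture_sd,
      boundary_wobble = boundary_wobble, means = means
    ),
    class = "phantom_config"
  )
}

#' Generate a seeded multi-contrast brain phantom
#'
#' Produces four co-registered intensity planes emulating FLAIR, T1, T1ce and
#' T2 contrasts plus a per-pixel ground-truth label map. Identical arguments
#' (including the seed) yield bit-identical phantoms.
#'
#' @param seed Integer RNG seed.
#' @param height,width Image size in pixels; both must be at least 32.
#' @param config A [phantom_config()].
#' @return A list of class `phantom` with elements `channels` (named list of
#'   four `height x width` matrices, values in [0, 255]), `labels` (integer
#'   matrix, codes in [PHANTOM_CLASSES]), `shape`, `seed` and `config`.
#' @examples
#' ph <- generate_phantom(seed = 7, height = 64, width = 64)
#' table(ph$labels)
#' @export
generate_phantom <- function(seed, height = 128, width = 128,
                             config = phantom_config()) {
  stopifnot(height >= 32, width >= 32, inherits(config, "phantom_config"))
  local_seed(seed, {
    rows <- matrix(seq_len(height), height, width)
    cols <- matrix(seq_len(width), height, width, byrow = TRUE)

    # Brain ellipse, slightly rotated per seed.
    cy <- height / 2
    cx <- width / 2
    ang <- stats::runif(1, -0.3, 0.3)
    a <- 0.42 * height
    b <- 0.36 * width
    dr <- rows - cy
    dc <- cols - cx
    u <- cos(ang) * dr + sin(ang) * dc
    v <- -sin(ang) * dr + cos(ang) * dc
    brain <- (u / a)^2 + (v / b)^2 <= 1

    labels <- matrix(PHANTOM_CLASSES[["background"]], height, width)
    labels[brain] <- PHANTOM_CLASSES[["normal"]]

    # Tumor: nested noisy blobs defined by a harmonic radius profile.
    brain_area <- sum(brain)
    r0 <- sqrt(config$edema_frac * brain_area / pi)
    wob <- config$boundary_wobble
    hcoef <- stats::rnorm(4, 0, 0.5)
    r_max <- r0 * (1 + wob * sum(abs(hcoef)))
    # Admissible tumor centers keep the whole edema blob inside the brain.
    shrink_a <- a - r_max
    shrink_b <- b - r_max
    if (shrink_a <= 0 || shrink_b <= 0) {
      stop("degenerate geometry: tumor larger than brain mask")
    }
    repeat {
      tu <- stats::runif(1, -0.8, 0.8) * shrink_a
      tv <- stats::runif(1, -0.8, 0.8) * shrink_b
      if ((tu / shrink_a)^2 + (tv / shrink_b)^2 <= 1) break
    }
    # Back to row/col coordinates.
    t_r <- cy + cos(ang) * tu - sin(ang) * tv
    t_c <- cx + sin(ang) * tu + cos(ang) * tv

    pr <- rows - t_r
    pc <- cols - t_c
    theta <- atan2(pc, pr)
    rho <- r0 * (1 + wob * (hcoef[1] * cos(theta) + hcoef[2] * sin(theta) +
                              hcoef[3] * cos(2 * theta) + hcoef[4] * sin(2 * theta)))
    ratio <- sqrt(pr^2 + pc^2) / pmax(rho, 1e-6)

    edema <- brain & ratio <= 1
    core <- brain & ratio <= sqrt(config$core_frac)
    necro <- brain & ratio <= sqrt(config$core_frac * config$necrosis_frac)
    labels[edema] <- PHANTOM_CLASSES[["edema"]]
    labels[core] <- PHANTOM_CLASSES[["core"]]
    labels[necro] <- PHANTOM_CLASSES[["necrosis"]]

    present <- PHANTOM_CLASSES %in% labels
    if (!all(present)) {
      stop(
        "degenerate geometry: class(es) ",
        paste(names(PHANTOM_CLASSES)[!present], collapse = ", "),
        " absent from the generated phantom"
      )
    }

    channels <- lapply(seq_len(ncol(config$means)), function(ch) {
      base <- matrix(config$means[labels + 1L, ch], height, width)
      tex <- matrix(stats::rnorm(height * width, 0, config$texture_sd),
                    height, width)
      matrix(as.numeric(round(clip01(base + tex))), height, width)
    })
    names(channels) <- colnames(config$means)

    structure(
      list(channels = channels, labels = labels,
           shape = c(height, width), seed = seed, config = config),
      class = "phantom"
    )
  })
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf(
    "<phantom %dx%d, seed %s> classes: %s\n",
    x$shape[1], x$shape[2], format(x$seed),
    paste(sprintf("%s=%d", names(PHANTOM_CLASSES),
                  sapply(PHANTOM_CLASSES, function(k) sum(x$labels == k))),
          collapse = " ")
  ))
  invisible(x)
}

#' Add seeded noise to an intensity plane
#'
#' @param image Numeric matrix with values in [0, 255].
#' @param model One of `"gaussian"` (additive, sd = `level`), `"rician"`
#'   (magnitude of the image plus a complex Gaussian with per-component
#'   sd = `level`, the standard MRI magnitude-noise model) or `"salt_pepper"`
#'   (`level` = fraction of pixels forced to 0 or 255).
#' @param level Non-negative noise level; `level = 0` returns the input
#'   unchanged for every model.
#' @param seed Integer RNG seed.
#' @return Noisy matrix clipped to [0, 255].
#' @export
add_noise <- function(image, model = c("gaussian", "rician", "salt_pepper"),
                      level, seed) {
  stopifnot(is.matrix(image), level >= 0)
  model <- match.arg(model)
  if (level == 0) {
    return(image)
  }
  local_seed(seed, {
    n <- length(image)
    out <- switch(model,
      gaussian = image + stats::rnorm(n, 0, level),
      rician = {
        n1 <- stats::rnorm(n, 0, level)
        n2 <- stats::rnorm(n, 0, level)
        sqrt((image + n1)^2 + n2^2)
      },
      salt_pepper = {
        hit <- stats::runif(n) < level
        val <- ifelse(stats::runif(n) < 0.5, 0, 255)
        ifelse(hit, val, image)
      }
    )
    matrix(clip01(out), nrow(image), ncol(image))
  })
}

#' Composite tumor region masks
#'
#' Builds the standard composite regions from a five-class label map:
#' whole tumor `WT` (edema, core and necrosis), tumor core `TC` (core and
#' necrosis) and enhancing tumor `ET` (enhancing core only). By construction
#' `ET` is a subset of `TC`, itself a subset of `WT`.
#'
#' @param labels Integer matrix of class codes (see [PHANTOM_CLASSES]).
#' @return A list of class `region_masks` with logical matrices `WT`, `TC`,
#'   `ET`.
#' @export
region_masks <- function(labels) {
  stopifnot(all(labels %in% PHANTOM_CLASSES))
  shape <- function(v) matrix(v, nrow(labels), ncol(labels))
  structure(
    list(
      WT = shape(labels %in% c(2L, 3L, 4L)),
      TC = shape(labels %in% c(3L, 4L)),
      ET = shape(labels == 3L)
    ),
    class = "region_masks"
  )
}

#' Generate a seeded phantom dataset with acquisition noise
#'
#' Convenience wrapper used by the pipeline: draws `n` phantoms with seeds
#' derived from `seed` and corrupts every channel with the requested noise.
#'
#' @param n Number of phantoms.
#' @param seed Base seed; image `i` uses a seed derived from `(seed, i)`.
#' @param height,width Phantom size.
#' @param noise_model,noise_level Passed to [add_noise()]; `noise_level = 0`
#'   yields clean images.
#' @param config A [phantom_config()].
#' @return List of phantoms; each carries an extra `noisy` element (named list
#'   of corrupted channels).
#' @export
generate_phantom_dataset <- function(n, seed, height = 128, width = 128,
                                     noise_model = "gaussian", noise_level = 10,
                                     config = phantom_config()) {
  stopifnot(n >= 1)
  lapply(seq_len(n), function(i) {
    ph <- generate_phantom(derive_seed(seed, i), height, width, config)
    ph$noisy <- lapply(seq_along(ph$channels), function(ch) {
      add_noise(ph$channels[[ch]], noise_model, noise_level,
                seed = derive_seed(seed, i * 101 + ch))
    })
    names(ph$noisy) <- names(ph$channels)
    ph
  })
}
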
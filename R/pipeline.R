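# End-to-end orchestration and evaluation.
#
# Stage order: phantom simulation (or loading), per-channel QMFT denoising,
# DSNN training with a 75/25 image split, per-pixel probability prediction,
# CRF mean-field refinement, immune tuning of the decision layer on held-out
# validation images, and metric aggregation over the test split.

#' Dice overlap coefficient
#'
#' `2 |A intersect B| / (|A| + |B|)`; two empty masks score 1 (the standard
#' convention in tumor-segmentation benchmarking).
#'
#' @param mask_a,mask_b Logical matrices of the same shape.
#' @return Value in [0, 1].
#' @export
dice <- function(mask_a, mask_b) {
  if (!identical(dim(mask_a), dim(mask_b))) {
    stop("masks must have the same shape")
  }
  denom <- sum(mask_a) + sum(mask_b)
  if (denom == 0) {
    return(1)
  }
  2 * sum(mask_a & mask_b) / denom
}

#' Pixelwise accuracy
#'
#' @param pred_labels,true_labels Equal-shape label matrices.
#' @return Matched fraction in [0, 1].
#' @export
pixel_accuracy <- function(pred_labels, true_labels) {
  if (!identical(dim(pred_labels), dim(true_labels))) {
    stop("label maps must have the same shape")
  }
  mean(pred_labels == true_labels)
}

#' Area under the ROC curve
#'
#' Rank-statistic (Mann-Whitney) estimator with midranks for ties:
#' `AUC = (sum of positive ranks - n1 (n1 + 1) / 2) / (n1 n0)`.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param truth 0/1 (or logical) ground truth containing both classes.
#' @return AUC in [0, 1].
#' @export
roc_auc <- function(scores, truth) {
  truth <- as.integer(as.logical(truth))
  stopifnot(length(scores) == length(truth))
  n1 <- sum(truth == 1L)
  n0 <- sum(truth == 0L)
  if (n1 == 0L || n0 == 0L) {
    stop("truth must contain both classes for AUC")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[truth == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Segmentation metrics
#'
#' Computes Dice over the composite WT/TC/ET regions, pixelwise accuracy,
#' the AUC of the tumor-vs-rest probability when a probability map is given,
#' and denoising MSE/PSNR when the denoised and clean references are given.
#'
#' @param pred_labels Predicted label matrix (codes in [PHANTOM_CLASSES]).
#' @param true_labels Ground-truth label matrix.
#' @param probs Optional `H x W x C` probability array (with `classes`
#'   attribute) for the AUC.
#' @param denoised,clean Optional matrices for MSE/PSNR of the denoising
#'   stage.
#' @return Named list of metrics (`dice_WT`, `dice_TC`, `dice_ET`,
#'   `accuracy`, and optionally `auc`, `mse`, `psnr`).
#' @export
evaluate_segmentation <- function(pred_labels, true_labels, probs = NULL,
                                  denoised = NULL, clean = NULL) {
  if (!identical(dim(pred_labels), dim(true_labels))) {
    stop("label maps must have the same shape")
  }
  pm <- region_masks(pred_labels)
  tm <- region_masks(true_labels)
  out <- list(
    dice_WT = dice(pm$WT, tm$WT),
    dice_TC = dice(pm$TC, tm$TC),
    dice_ET = dice(pm$ET, tm$ET),
    accuracy = pixel_accuracy(pred_labels, true_labels)
  )
  if (!is.null(probs)) {
    classes <- attr(probs, "classes")
    tumor_cols <- which(classes %in% c(2L, 3L, 4L))
    flat <- matrix(probs, prod(dim(probs)[1:2]), dim(probs)[3])
    score <- rowSums(flat[, tumor_cols, drop = FALSE])
    truth <- as.vector(tm$WT)
    out$auc <- if (length(unique(truth)) == 2L) {
      roc_auc(score, truth)
    } else {
      NA_real_
    }
  }
  if (!is.null(denoised) && !is.null(clean)) {
    out$mse <- img_mse(clean, denoised)
    out$psnr <- psnr(clean, denoised)
  }
  out
}

#' Pipeline run configuration
#'
#' @param seed Master seed; every stochastic stage derives its stream from
#'   it.
#' @param n_images Number of simulated phantoms.
#' @param height,width Phantom size.
#' @param noise_model,noise_level Acquisition noise (see [add_noise()]).
#' @param phantom A [phantom_config()].
#' @param denoise `NULL` to skip denoising, else a [denoise_config()].
#' @param net A [net_config()] (its seed is overridden by `seed`).
#' @param crf `NULL` to skip CRF refinement, else a [crf_params()].
#' @param crf_radius Neighbourhood radius of the image-mode CRF.
#' @param crf_channel Channel name feeding the CRF appearance kernel.
#' @param tune `NULL` to skip immune tuning, else a list with `pop_size`,
#'   `clone_rate`, `iters`.
#' @param n_validation Number of training images held out for tuning.
#' @param out_dir Optional directory for stage artifacts (created when
#'   missing); `NULL` disables persistence.
#' @return List of class `run_config`.
#' @export
run_config <- function(seed = 7, n_images = 40, height = 128, width = 128,
                       noise_model = "gaussian", noise_level = 10,
                       phantom = phantom_config(),
                       denoise = denoise_config(),
                       net = net_config(),
                       crf = crf_params(), crf_radius = 4,
                       crf_channel = "flair",
                       tune = list(pop_size = 200, clone_rate = 0.04,
                                   iters = 10),
                       n_validation = 2, out_dir = NULL) {
  stopifnot(n_images >= 2, n_validation >= 0)
  net$seed <- seed
  if (!is.null(denoise)) {
    denoise$seed <- seed
  }
  structure(
    list(seed = seed, n_images = n_images, height = height, width = width,
         noise_model = noise_model, noise_level = noise_level,
         phantom = phantom, denoise = denoise, net = net, crf = crf,
         crf_radius = crf_radius, crf_channel = crf_channel, tune = tune,
         n_validation = n_validation, out_dir = out_dir),
    class = "run_config"
  )
}

#' Run the full segmentation pipeline
#'
#' Simulates (or accepts) a phantom dataset, denoises every channel, trains
#' the segmentation network on the 75% training split, predicts and
#' CRF-refines the 25% test split, tunes the decision layer on held-out
#' validation images, and reports per-image and aggregate metrics. The whole
#' run is a pure function of the configuration (identical config and seed
#' give identical reports).
#'
#' @param config A [run_config()].
#' @param dataset Optional pre-built dataset (list of phantoms); when `NULL`
#'   the phantom generator supplies `n_images` seeded phantoms.
#' @return List of class `pipeline_result` with `per_image` (data frame of
#'   test-split metrics before/after CRF), `aggregate` (means and sds),
#'   `tuning` (validation Dice before/after immune tuning), `model`,
#'   `config`, and `provenance`.
#' @export
run_pipeline <- function(config = run_config(), dataset = NULL) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  if (is.null(dataset)) {
    dataset <- generate_phantom_dataset(
      config$n_images, config$seed, config$height, config$width,
      config$noise_model, config$noise_level, config$phantom
    )
  }

  # Stage 1: denoising (channel-wise QMFT).
  if (!is.null(config$denoise)) {
    dataset <- run_stage("denoise", function() {
      lapply(seq_along(dataset), function(i) {
        ph <- dataset[[i]]
        src <- ph$noisy %||% ph$channels
        dcfg <- config$denoise
        dcfg$seed <- derive_seed(config$seed, 5000L + i)
        ph$denoised <- lapply(src, function(chan) {
          out <- qmft_denoise(chan, dcfg)
          attr(out, "objective_trace") <- NULL
          attr(out, "n_accepted") <- NULL
          out
        })
        ph
      })
    })
  }

  # Stage 2: training (75/25 split handled inside dsnn_train).
  model <- run_stage("train", function() dsnn_train(dataset, config$net))
  train_imgs <- model$train_idx
  test_imgs <- model$test_idx
  n_val <- min(config$n_validation, length(train_imgs) - 1L)
  val_imgs <- if (n_val > 0) utils::tail(train_imgs, n_val) else integer(0)

  # Stage 3: prediction + CRF refinement on the test split.
  per_image <- run_stage("segment", function() {
    rows <- lapply(test_imgs, function(i) {
      ph <- dataset[[i]]
      probs <- predict_proba(ph, model)
      raw_labels <- predict_labels(probs)
      m_raw <- evaluate_segmentation(raw_labels, ph$labels, probs = probs)
      row <- data.frame(
        image = i,
        dice_WT = m_raw$dice_WT, dice_TC = m_raw$dice_TC,
        dice_ET = m_raw$dice_ET, accuracy = m_raw$accuracy,
        auc = m_raw$auc
      )
      if (!is.null(config$crf)) {
        ref <- (ph$denoised %||% ph$noisy %||% ph$channels)[[config$crf_channel]]
        ref_probs <- crf_refine(probs, ref, config$crf, config$crf_radius)
        m_crf <- evaluate_segmentation(attr(ref_probs, "labels"), ph$labels,
                                       probs = ref_probs)
        row$dice_WT_crf <- m_crf$dice_WT
        row$dice_TC_crf <- m_crf$dice_TC
        row$dice_ET_crf <- m_crf$dice_ET
        row$accuracy_crf <- m_crf$accuracy
      }
      if (!is.null(ph$denoised) && !is.null(ph$noisy)) {
        row$psnr_denoised <- psnr(ph$channels[[config$crf_channel]],
                                  ph$denoised[[config$crf_channel]])
        row$psnr_noisy <- psnr(ph$channels[[config$crf_channel]],
                               ph$noisy[[config$crf_channel]])
      }
      row
    })
    do.call(rbind, rows)
  })

  # Stage 4: immune tuning of the decision layer on validation images.
  tuning <- NULL
  if (!is.null(config$tune) && length(val_imgs) > 0) {
    model <- run_stage("tune", function() {
      tune_decision_layer(
        model, dataset[val_imgs], seed = derive_seed(config$seed, 9000L),
        pop_size = config$tune$pop_size, clone_rate = config$tune$clone_rate,
        iters = config$tune$iters
      )
    })
    tuning <- attr(model, "tuning")
  }

  num <- vapply(per_image, is.numeric, logical(1))
  num["image"] <- FALSE
  aggregate <- data.frame(
    metric = names(per_image)[num],
    mean = vapply(per_image[num], mean, numeric(1)),
    sd = vapply(per_image[num], stats::sd, numeric(1)),
    row.names = NULL
  )

  result <- structure(
    list(per_image = per_image, aggregate = aggregate, tuning = tuning,
         model = model, config = config,
         provenance = list(seed = config$seed,
                           n_train = length(train_imgs),
                           n_test = length(test_imgs),
                           val_images = val_imgs,
                           elapsed_s = as.numeric(difftime(Sys.time(), t0,
                                                           units = "secs")))),
    class = "pipeline_result"
  )
  if (!is.null(config$out_dir)) {
    persist_result(result, dataset)
  }
  result
}

run_stage <- function(name, fn) {
  tryCatch(fn(), error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d test image(s), seed %s\n",
              nrow(x$per_image), format(x$config$seed)))
  agg <- x$aggregate
  for (k in seq_len(nrow(agg))) {
    cat(sprintf("  %-14s %.4f (sd %.4f)\n", agg$metric[k], agg$mean[k],
                agg$sd[k]))
  }
  if (!is.null(x$tuning)) {
    cat(sprintf("  tuning: validation dice_WT %.4f -> %.4f\n",
                x$tuning$untuned_dice, x$tuning$tuned_dice))
  }
  invisible(x)
}
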
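# Standard-format input/output: 8-bit PNG planes, NIfTI volumes, JSON/CSV
# reports and plain-text phantom manifests.

#' Read / write intensity planes
#'
#' PNG planes are stored 8-bit ([0, 255] scaled to [0, 1]); NIfTI images
#' (`.nii` / `.nii.gz`) are read and written with RNifti and keep their
#' native values. `read_plane` dispatches on the file extension.
#'
#' @param image Numeric matrix in [0, 255] (`write_plane_png`) or any array
#'   (`write_plane_nifti`).
#' @param path File path.
#' @return `read_plane` returns a numeric matrix (or array for
#'   multi-volume NIfTI).
#' @export
write_plane_png <- function(image, path) {
  png::writePNG(image / 255, path)
  invisible(path)
}

#' @rdname write_plane_png
#' @export
write_plane_nifti <- function(image, path) {
  RNifti::writeNifti(RNifti::asNifti(image), path)
  invisible(path)
}

#' @rdname write_plane_png
#' @export
read_plane <- function(path) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    img <- png::readPNG(path)
    if (length(dim(img)) == 3) {
      img <- img[, , 1]
    }
    round(img * 255)
  } else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    arr <- as.array(RNifti::readNifti(path))
    if (length(dim(arr)) == 2) arr else arr
  } else {
    stop("unsupported image format: ", path)
  }
}

#' Write a phantom to disk
#'
#' One 8-bit PNG per channel (or a channel-stacked NIfTI), a label image and
#' a plain-text manifest recording seed and configuration.
#'
#' @param phantom A `phantom`.
#' @param dir Output directory (created when missing).
#' @param format `"png"` or `"nifti"`.
#' @param prefix File-name prefix.
#' @return Invisibly, the manifest path.
#' @export
write_phantom <- function(phantom, dir, format = c("png", "nifti"),
                          prefix = "phantom") {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (format == "png") {
    for (ch in names(phantom$channels)) {
      write_plane_png(phantom$channels[[ch]],
                      file.path(dir, sprintf("%s_%s.png", prefix, ch)))
    }
    write_plane_png(phantom$labels,
                    file.path(dir, sprintf("%s_labels.png", prefix)))
  } else {
    stack <- array(unlist(phantom$channels),
                   dim = c(phantom$shape, length(phantom$channels)))
    write_plane_nifti(stack, file.path(dir, sprintf("%s.nii.gz", prefix)))
    write_plane_nifti(phantom$labels,
                      file.path(dir, sprintf("%s_labels.nii.gz", prefix)))
  }
  manifest <- file.path(dir, sprintf("%s_manifest.txt", prefix))
  cfg <- phantom$config
  writeLines(c(
    sprintf("seed: %s", format(phantom$seed)),
    sprintf("height: %d", phantom$shape[1]),
    sprintf("width: %d", phantom$shape[2]),
    sprintf("channels: %s", paste(names(phantom$channels), collapse = ",")),
    sprintf("edema_frac: %g", cfg$edema_frac),
    sprintf("core_frac: %g", cfg$core_frac),
    sprintf("necrosis_frac: %g", cfg$necrosis_frac),
    sprintf("texture_sd: %g", cfg$texture_sd),
    sprintf("boundary_wobble: %g", cfg$boundary_wobble)
  ), manifest)
  invisible(manifest)
}

#' Read a phantom written by [write_phantom()]
#'
#' @param dir Directory holding the files.
#' @param prefix File-name prefix used at write time.
#' @return A list with `channels` and `labels` (PNG layout only).
#' @export
read_phantom <- function(dir, prefix = "phantom") {
  manifest <- readLines(file.path(dir, sprintf("%s_manifest.txt", prefix)))
  kv <- strsplit(manifest, ": ")
  vals <- stats::setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  chans <- strsplit(vals[["channels"]], ",")[[1]]
  channels <- lapply(chans, function(ch) {
    read_plane(file.path(dir, sprintf("%s_%s.png", prefix, ch)))
  })
  names(channels) <- chans
  labels <- matrix(as.integer(read_plane(
    file.path(dir, sprintf("%s_labels.png", prefix))
  )), nrow(channels[[1]]), ncol(channels[[1]]))
  list(channels = channels, labels = labels, seed = vals[["seed"]])
}

# Persist pipeline artifacts: label maps, probability maps and reports.
persist_result <- function(result, dataset) {
  dir <- result$config$out_dir
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(result$per_image, file.path(dir, "per_image_metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(result$aggregate, file.path(dir, "aggregate_metrics.csv"),
                   row.names = FALSE)
  report <- list(
    seed = result$config$seed,
    aggregate = stats::setNames(as.list(result$aggregate$mean),
                                result$aggregate$metric),
    tuning = result$tuning[c("untuned_dice", "tuned_dice")],
    provenance = result$provenance[c("seed", "n_train", "n_test")]
  )
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (i in result$per_image$image) {
    ph <- dataset[[i]]
    probs <- predict_proba(ph, result$model)
    write_plane_nifti(unclass(probs),
                      file.path(dir, sprintf("img%03d_probs.nii.gz", i)))
    write_plane_png(predict_labels(probs),
                    file.path(dir, sprintf("img%03d_labels.png", i)))
    write_plane_png(ph$labels,
                    file.path(dir, sprintf("img%03d_truth.png", i)))
  }
  invisible(dir)
}
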
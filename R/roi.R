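# ROI stage: whole-tumor binary segmentation per modality, best-modality
# selection by F-measure, and masking of the combined FLAIR/T1ce/T2 image.

#' Channels of the combined ROI image
#' @export
ROI_CHANNELS <- c("FLAIR", "T1ce", "T2")

#' Train one binary whole-tumor model per modality
#'
#' Each modality gets an identically configured single-channel binary
#' network (same seed, same schedule), trained against the collapsed
#' whole-tumor ground truth.
#'
#' @param stacks list of `modality_stack` (training split, labels required).
#' @param config a `net_config` template; `in_channels`/`n_classes` are
#'   forced to 1/2.
#' @param modalities which modalities to train (default all four).
#' @return named list of trained `segnet` models.
#' @export
train_modality_models <- function(stacks, config,
                                  modalities = MODALITIES) {
  stopifnot(length(stacks) > 0L)
  cfg <- config
  cfg$in_channels <- 1L
  cfg$n_classes <- 2L
  targets <- lapply(stacks, function(s) {
    if (is.null(s$labels)) stop("training error: subject ", s$subject_id,
                                " has no labels")
    to_binary_labels(s$labels)
  })
  models <- list()
  for (m in modalities) {
    inputs <- lapply(stacks, function(s) s$modalities[[m]])
    model <- build_network(cfg)
    models[[m]] <- train_segmentation(model, inputs, targets)
  }
  models
}

#' Predict the whole-tumor ROI mask from one modality
#'
#' @param model trained single-channel binary `segnet`.
#' @param modality_raster `H x W` matrix.
#' @return logical matrix, TRUE = tumor extension.
#' @export
predict_roi_mask <- function(model, modality_raster) {
  scores <- extract_score_maps(model, modality_raster)
  predict_argmax(scores) == 1L
}

#' Select the best ROI modality by whole-tumor F-measure
#'
#' Evaluates each modality's binary model on its own modality over the
#' evaluation split and returns the modality with the highest mean
#' F-measure. Ties break by canonical modality order (FLAIR first).
#'
#' @param models named list from [train_modality_models()].
#' @param stacks evaluation split (labels required).
#' @return list with `best` (modality name) and `table` (named mean-F
#'   vector over all evaluated modalities).
#' @export
select_best_modality <- function(models, stacks) {
  if (length(stacks) == 0L) stop("selection error: empty evaluation split")
  mods <- intersect(MODALITIES, names(models))
  scores <- vapply(mods, function(m) {
    fs <- vapply(stacks, function(s) {
      pred <- predict_roi_mask(models[[m]], s$modalities[[m]])
      f_measure(pred, to_binary_labels(s$labels) == 1L)
    }, 0)
    mean(fs)
  }, 0)
  names(scores) <- mods
  list(best = mods[which.max(scores)], table = scores)
}

#' Apply an ROI mask to the combined FLAIR/T1ce/T2 image
#'
#' Pixels outside the mask are set to exactly 0 in every channel; pixels
#' inside are kept bit-identical. T1 is never part of the combined image.
#'
#' @param stack a `modality_stack`.
#' @param mask logical ROI matrix matching the stack shape.
#' @return object of class `roi_image`: list with `channels`
#'   (`H x W x 3` array in FLAIR, T1ce, T2 order) and `mask`.
#' @export
apply_roi_mask <- function(stack, mask) {
  stopifnot(inherits(stack, "modality_stack"), is.logical(mask))
  d <- dim(stack$modalities[[1]])
  if (!identical(dim(mask), d)) stop("masking error: mask shape mismatch")
  channels <- array(0, dim = c(d, length(ROI_CHANNELS)))
  for (k in seq_along(ROI_CHANNELS)) {
    ch <- stack$modalities[[ROI_CHANNELS[k]]]
    ch[!mask] <- 0
    channels[, , k] <- ch
  }
  structure(list(channels = channels, mask = mask,
                 subject_id = stack$subject_id),
            class = "roi_image")
}
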
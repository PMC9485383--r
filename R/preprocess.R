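#' Clip in-brain intensities at percentiles
#'
#' Winsorizes the top and bottom tails of the in-brain intensity
#' distribution (default 1% each side, the usual MRI normalization step that
#' tames scanner spikes before z-scoring). Background voxels are untouched.
#'
#' @param raster numeric array (2D slice or 3D volume).
#' @param brain_mask logical array of the same shape; TRUE = inside brain.
#' @param low_pct,high_pct tail percentages to clip (defaults 1 and 1).
#' @return raster with in-brain values clipped to `[p_low, p_high]`.
#' @export
clip_percentiles <- function(raster, brain_mask, low_pct = 1, high_pct = 1) {
  stopifnot(all(dim(raster) == dim(brain_mask)))
  v <- raster[brain_mask]
  if (length(v) == 0L) stop("preprocessing error: empty brain mask")
  qs <- stats::quantile(v, c(low_pct / 100, 1 - high_pct / 100),
                        names = FALSE, type = 7)
  raster[brain_mask] <- pmin(pmax(v, qs[1]), qs[2])
  raster
}

#' Z-score normalize over the brain region
#'
#' Subtracts the in-brain mean and divides by the in-brain standard
#' deviation (population denominator n); background stays 0. Idempotent up
#' to floating-point error.
#'
#' @inheritParams clip_percentiles
#' @return normalized raster with in-brain mean 0 and SD 1.
#' @export
zscore_normalize <- function(raster, brain_mask) {
  stopifnot(all(dim(raster) == dim(brain_mask)))
  v <- raster[brain_mask]
  if (length(v) == 0L) stop("preprocessing error: empty brain mask")
  mu <- mean(v)
  sd_ <- sqrt(mean((v - mu)^2))
  if (sd_ <= 0) stop("preprocessing error: zero in-brain standard deviation")
  out <- raster
  out[!brain_mask] <- 0
  out[brain_mask] <- (v - mu) / sd_
  out
}

#' Center-crop a slice or volume in-plane
#'
#' Crops the trailing black background so the network sees a fixed input
#' size. The crop is centered; for odd remainders the extra row/column is
#' dropped from the bottom/right. For 3D input the first axis (slices) is
#' kept whole. No padding: inputs smaller than the target are an error.
#'
#' @param raster 2D matrix or 3D array (slices x H x W).
#' @param target integer `c(H, W)` (default `c(192, 192)`).
#' @return cropped raster with attribute `crop_offset = c(row0, col0)`
#'   (0-based offsets of the crop window, for mapping predictions back).
#' @export
crop_center <- function(raster, target = c(192L, 192L)) {
  d <- dim(raster)
  nd <- length(d)
  stopifnot(nd %in% c(2L, 3L))
  hw <- if (nd == 2L) d else d[2:3]
  if (hw[1] < target[1] || hw[2] < target[2]) {
    stop("preprocessing error: input ", hw[1], "x", hw[2],
         " smaller than target ", target[1], "x", target[2])
  }
  r0 <- (hw[1] - target[1]) %/% 2L
  c0 <- (hw[2] - target[2]) %/% 2L
  rows <- (r0 + 1L):(r0 + target[1])
  cols <- (c0 + 1L):(c0 + target[2])
  out <- if (nd == 2L) raster[rows, cols, drop = FALSE]
         else raster[, rows, cols, drop = FALSE]
  attr(out, "crop_offset") <- c(row0 = r0, col0 = c0)
  out
}

.BRATS_LABELS <- c(0L, 1L, 2L, 4L)
# class-index order fixed everywhere: background, edema, necrosis, enhancing
.BRATS_TO_CLASS <- c("0" = 0L, "2" = 1L, "1" = 2L, "4" = 3L)
.CLASS_TO_BRATS <- c(0L, 2L, 1L, 4L)

check_brats_labels <- function(labels) {
  u <- unique(as.integer(labels))
  bad <- setdiff(u, .BRATS_LABELS)
  if (length(bad) > 0L) {
    stop("label error: unexpected BRATS label value(s) ",
         paste(bad, collapse = ", "))
  }
  invisible(TRUE)
}

#' Collapse BRATS labels to the binary whole-tumor ground truth
#'
#' 0 stays background; tumor labels {1, 2, 4} all map to 1. This is the
#' ground truth used to train the binary ROI networks.
#'
#' @param labels integer raster in BRATS space {0, 1, 2, 4}.
#' @return integer raster in {0, 1}, same shape.
#' @export
to_binary_labels <- function(labels) {
  check_brats_labels(labels)
  out <- ifelse(labels > 0L, 1L, 0L)
  storage.mode(out) <- "integer"
  dim(out) <- dim(labels)
  out
}

#' Map BRATS labels to contiguous class indices
#'
#' Fixed bijection 0 -> 0 (background), 2 -> 1 (edema), 1 -> 2
#' (necrosis/non-enhancing), 4 -> 3 (enhancing tumor) — the class order used
#' by the 4-class network, the score maps and the fused feature vector.
#'
#' @param labels integer raster in BRATS space {0, 1, 2, 4}.
#' @return integer raster in {0, 1, 2, 3}, same shape.
#' @seealso [from_class_index()] for the inverse.
#' @export
to_class_index <- function(labels) {
  check_brats_labels(labels)
  out <- unname(.BRATS_TO_CLASS[as.character(as.integer(labels))])
  dim(out) <- dim(labels)
  out
}

#' Inverse of [to_class_index()]
#'
#' @param classes integer raster in {0, 1, 2, 3}.
#' @return integer raster in BRATS space {0, 1, 2, 4}, same shape.
#' @export
from_class_index <- function(classes) {
  u <- unique(as.integer(classes))
  if (length(u) > 0L && (min(u) < 0L || max(u) > 3L)) {
    stop("label error: class index outside 0..3")
  }
  out <- .CLASS_TO_BRATS[as.integer(classes) + 1L]
  dim(out) <- dim(classes)
  out
}

#' Preprocess one modality raster
#'
#' Percentile clipping followed by z-score normalization over the brain
#' mask, the order the pipeline applies everywhere. Per-volume, per-modality.
#'
#' @inheritParams clip_percentiles
#' @param clip_low_pct,clip_high_pct tail percentages (default 1 each).
#' @return normalized raster.
#' @export
preprocess_modality <- function(raster, brain_mask,
                                clip_low_pct = 1, clip_high_pct = 1) {
  r <- clip_percentiles(raster, brain_mask, clip_low_pct, clip_high_pct)
  zscore_normalize(r, brain_mask)
}
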
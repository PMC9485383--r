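# Region-grouped F-measure evaluation: whole tumor (WT), tumor core (TC),
# enhancing tumor (ET), and the net-only vs hybrid comparison harness.

#' Evaluation region label sets
#'
#' WT = {1, 2, 4} (edema + necrosis/non-enhancing + enhancing),
#' TC = {1, 4}, ET = {4}; nested ET subset of TC subset of WT.
#' @export
REGION_LABELS <- list(WT = c(1L, 2L, 4L), TC = c(1L, 4L), ET = 4L)

#' Pixel-level F-measure of two binary masks
#'
#' F = 2PR / (P + R) with precision P = TP/(TP+FP) and recall
#' R = TP/(TP+FN). Degenerate rules: both masks empty -> 1 (nothing to
#' find, nothing claimed); exactly one empty -> 0.
#'
#' @param pred_mask,gt_mask logical rasters of identical shape.
#' @return F-measure in [0, 1].
#' @export
f_measure <- function(pred_mask, gt_mask) {
  if (!identical(dim(pred_mask), dim(gt_mask))) {
    stop("evaluation error: mask shape mismatch")
  }
  np <- sum(pred_mask); ng <- sum(gt_mask)
  if (np == 0 && ng == 0) return(1)
  if (np == 0 || ng == 0) return(0)
  tp <- sum(pred_mask & gt_mask)
  if (tp == 0) return(0)
  p <- tp / np
  r <- tp / ng
  2 * p * r / (p + r)
}

#' Binary mask of an evaluation region
#'
#' @param labels integer raster in BRATS space {0, 1, 2, 4}.
#' @param region `"WT"`, `"TC"` or `"ET"`.
#' @return logical raster.
#' @export
region_mask <- function(labels, region = c("WT", "TC", "ET")) {
  region <- match.arg(region)
  check_brats_labels(labels)
  m <- array(labels %in% REGION_LABELS[[region]], dim = dim(labels))
  m
}

#' Evaluate a cohort per region
#'
#' Per-subject F-measure for WT/TC/ET plus across-subject mean and
#' population (n-denominator) standard deviation.
#'
#' @param pred_maps,gt_maps named lists of BRATS label rasters with matching
#'   subject names (or matching order when unnamed).
#' @return object of class `cohort_metrics`: list with `per_subject`
#'   (subjects x regions matrix) and `summary` (regions x c(mean, sd)).
#' @export
evaluate_cohort <- function(pred_maps, gt_maps) {
  if (length(pred_maps) != length(gt_maps)) {
    stop("evaluation error: mismatched subject counts")
  }
  if (!is.null(names(pred_maps)) && !is.null(names(gt_maps))) {
    if (!setequal(names(pred_maps), names(gt_maps))) {
      stop("evaluation error: mismatched subject sets")
    }
    gt_maps <- gt_maps[names(pred_maps)]
  }
  regions <- names(REGION_LABELS)
  per <- matrix(0, length(pred_maps), length(regions),
                dimnames = list(names(pred_maps), regions))
  for (i in seq_along(pred_maps)) {
    for (rg in regions) {
      per[i, rg] <- f_measure(region_mask(pred_maps[[i]], rg),
                              region_mask(gt_maps[[i]], rg))
    }
  }
  pop_sd <- function(v) sqrt(mean((v - mean(v))^2))
  summary <- cbind(mean = colMeans(per), sd = apply(per, 2L, pop_sd))
  structure(list(per_subject = per, summary = summary),
            class = "cohort_metrics")
}

#' @export
print.cohort_metrics <- function(x, ...) {
  cat("Cohort F-measure (mean +/- sd):\n")
  for (rg in rownames(x$summary)) {
    cat(sprintf("  %s: %.3f +/- %.3f\n", rg,
                x$summary[rg, "mean"], x$summary[rg, "sd"]))
  }
  invisible(x)
}

#' Paired comparison of two methods on one cohort
#'
#' Both prediction sets must cover the same subjects. Reports each method's
#' per-region mean/sd and the paired per-subject F differences (B - A).
#'
#' @param pred_a,pred_b named lists of predicted label maps (method A =
#'   net-only, method B = hybrid, by convention).
#' @param gt_maps ground-truth label maps.
#' @param names_ab method names for the table.
#' @return list with `metrics_a`, `metrics_b`, `diff` (subjects x regions,
#'   B - A), `mean_diff` (per-region), `table` (2 method rows x 3 region
#'   columns of "mean+/-sd").
#' @export
compare_methods <- function(pred_a, pred_b, gt_maps,
                            names_ab = c("net_only", "hybrid")) {
  ma <- evaluate_cohort(pred_a, gt_maps)
  mb <- evaluate_cohort(pred_b, gt_maps)
  diff <- mb$per_subject - ma$per_subject
  fmt <- function(m) sprintf("%.3f+/-%.3f", m[, "mean"], m[, "sd"])
  tab <- rbind(fmt(ma$summary), fmt(mb$summary))
  dimnames(tab) <- list(names_ab, rownames(ma$summary))
  list(metrics_a = ma, metrics_b = mb, diff = diff,
       mean_diff = colMeans(diff), table = tab)
}
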
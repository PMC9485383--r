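# Windowed GLCM texture engine: quantization, co-occurrence counting,
# Haralick ASM / contrast / correlation, and ROI feature maps.

#' Quantize a real-valued raster into discrete gray levels
#'
#' Linear equal-width binning of intensities into `levels` bins over a fixed
#' range, the standard preparation step before co-occurrence counting. Values
#' at or below the range minimum map to level 0, values at or above the
#' maximum map to level `levels - 1`; interior bins are half-open
#' `[min + k*w, min + (k+1)*w)`.
#'
#' @param raster numeric matrix (2D image).
#' @param levels integer number of gray levels L (default 8).
#' @param range length-2 numeric `c(min, max)` quantization range. Default
#'   `NULL` uses the finite data range of `raster`; a constant raster then
#'   maps to all zeros (single bin). An explicitly supplied range must have
#'   `max > min`.
#' @return integer matrix with values in `0 .. levels-1`.
#' @export
quantize_gray_levels <- function(raster, levels = 8L, range = NULL) {
  stopifnot(is.numeric(raster), levels >= 1L)
  if (is.null(range)) {
    fin <- raster[is.finite(raster)]
    if (length(fin) == 0L) stop("quantization error: no finite values")
    range <- c(min(fin), max(fin))
    if (range[2] <= range[1]) {
      q <- raster
      q[] <- 0L
      storage.mode(q) <- "integer"
      return(q)
    }
  }
  if (range[2] <= range[1]) stop("quantization error: max <= min")
  w <- (range[2] - range[1]) / levels
  q <- floor((raster - range[1]) / w)
  q[q < 0] <- 0
  q[q > levels - 1] <- levels - 1L
  storage.mode(q) <- "integer"
  dim(q) <- dim(raster)
  q
}

#' Pixel offset for a co-occurrence direction
#'
#' Maps the four standard GLCM angles at distance d = 1 to `(dy, dx)` row and
#' column offsets: 0 deg -> (0, 1), 45 deg -> (-1, 1), 90 deg -> (-1, 0),
#' 135 deg -> (-1, -1). Rows increase downward, so negative `dy` points up.
#'
#' @param angle one of 0, 45, 90, 135 (degrees).
#' @return integer vector `c(dy, dx)`.
#' @export
glcm_offset <- function(angle) {
  switch(as.character(angle),
    "0"   = c(0L, 1L),
    "45"  = c(-1L, 1L),
    "90"  = c(-1L, 0L),
    "135" = c(-1L, -1L),
    stop("unsupported GLCM angle: ", angle)
  )
}

#' Gray-level co-occurrence matrix
#'
#' Counts ordered pixel pairs `(p, p + offset)` whose gray levels are
#' `(i, j)`, over all positions where both pixels are in bounds. With
#' `symmetric = TRUE` (the usual Haralick convention) the transposed counts
#' are added, so each unordered pair is counted in both orientations.
#'
#' @param q_raster integer matrix with values in `0 .. levels-1`.
#' @param angle co-occurrence direction in degrees (see [glcm_offset()]);
#'   ignored when `offset` is given.
#' @param levels number of gray levels L.
#' @param symmetric logical; add the transpose (default TRUE).
#' @param offset optional explicit `c(dy, dx)` integer offset (distance need
#'   not be 1).
#' @return object of class `glcm`: a list with `counts` (L x L integer
#'   matrix, rows = level of the first pixel), `levels`, `offset`,
#'   `symmetric`.
#' @export
compute_glcm <- function(q_raster, angle = 0, levels = 8L,
                         symmetric = TRUE, offset = NULL) {
  stopifnot(is.matrix(q_raster))
  if (is.null(offset)) offset <- glcm_offset(angle)
  dy <- as.integer(offset[1]); dx <- as.integer(offset[2])
  if (length(q_raster) > 0 &&
      (min(q_raster) < 0L || max(q_raster) > levels - 1L)) {
    stop("q_raster values outside 0..levels-1")
  }
  H <- nrow(q_raster); W <- ncol(q_raster)
  r0 <- max(1L, 1L - dy); r1 <- min(H, H - dy)
  c0 <- max(1L, 1L - dx); c1 <- min(W, W - dx)
  counts <- matrix(0L, levels, levels)
  if (r0 <= r1 && c0 <= c1) {
    a <- q_raster[r0:r1, c0:c1, drop = FALSE]
    b <- q_raster[(r0 + dy):(r1 + dy), (c0 + dx):(c1 + dx), drop = FALSE]
    code <- as.integer(a) * levels + as.integer(b) + 1L
    tab <- tabulate(code, nbins = levels * levels)
    counts <- matrix(tab, nrow = levels, ncol = levels, byrow = TRUE)
  }
  if (symmetric) counts <- counts + t(counts)
  structure(
    list(counts = counts, levels = levels,
         offset = c(dy = dy, dx = dx), symmetric = symmetric),
    class = "glcm"
  )
}

#' Haralick features of a co-occurrence matrix
#'
#' On the normalized joint distribution p(i, j) = counts / total:
#' \itemize{
#'   \item ASM (angular second moment, energy): sum of p(i,j)^2, in [0, 1];
#'     1 for a perfectly homogeneous window.
#'   \item contrast: sum of (i - j)^2 p(i,j), in [0, (L-1)^2]; magnitude of
#'     local gray-level variation.
#'   \item correlation: sum of (i - mu_i)(j - mu_j) p(i,j) / (sigma_i
#'     sigma_j), in [-1, 1]; gray-level linear dependency, with marginal
#'     means/SDs mu_i, mu_j, sigma_i, sigma_j.
#' }
#' Degenerate rules: a zero-total matrix yields (0, 0, 0); when
#' sigma_i * sigma_j = 0 (e.g. all mass in one cell) correlation is defined
#' as 0.
#'
#' @param glcm a `glcm` object from [compute_glcm()], or a plain square
#'   count/probability matrix.
#' @return named numeric vector `c(asm, contrast, correlation)`.
#' @export
haralick_features <- function(glcm) {
  counts <- if (inherits(glcm, "glcm")) glcm$counts else glcm
  stopifnot(is.matrix(counts), nrow(counts) == ncol(counts))
  tot <- sum(counts)
  if (tot <= 0) {
    return(c(asm = 0, contrast = 0, correlation = 0))
  }
  L <- nrow(counts)
  p <- counts / tot
  lev <- 0:(L - 1)
  px <- rowSums(p); py <- colSums(p)
  mui <- sum(lev * px); muj <- sum(lev * py)
  si <- sqrt(sum((lev - mui)^2 * px))
  sj <- sqrt(sum((lev - muj)^2 * py))
  d2 <- outer(lev, lev, function(i, j) (i - j)^2)
  asm <- sum(p * p)
  contrast <- sum(d2 * p)
  if (si * sj > 0) {
    corr <- sum(outer(lev - mui, lev - muj) * p) / (si * sj)
  } else {
    corr <- 0
  }
  c(asm = asm, contrast = contrast, correlation = corr)
}

# Per-angle feature triples for one window of a pre-quantized raster.
# Window = rows y-hw .. y+hw-1, cols x-hw .. x+hw-1 (even window sits
# down/right of its center pixel), clipped at raster borders.
window_features_quantized <- function(q_raster, y, x, window = 8L,
                                      levels = 8L,
                                      angles = c(0, 45, 90, 135),
                                      symmetric = TRUE) {
  H <- nrow(q_raster); W <- ncol(q_raster)
  hw <- window %/% 2L
  r0 <- max(1L, y - hw); r1 <- min(H, y + hw - 1L)
  c0 <- max(1L, x - hw); c1 <- min(W, x + hw - 1L)
  win <- q_raster[r0:r1, c0:c1, drop = FALSE]
  feats <- vapply(angles, function(a) {
    haralick_features(compute_glcm(win, angle = a, levels = levels,
                                   symmetric = symmetric))
  }, numeric(3))
  rowMeans(feats)
}

#' Windowed Haralick feature triple at a pixel
#'
#' Quantizes `raster` to `levels` gray levels (per-image range by default),
#' extracts the `window` x `window` block centred at `pixel` (rows
#' `y-4 .. y+3` for the default 8x8 window, clipped at image borders, never
#' padded), computes one symmetric GLCM per direction at distance 1, and
#' averages the per-direction (ASM, contrast, correlation) triples.
#'
#' @param raster numeric matrix, typically a T1ce slice.
#' @param pixel integer `c(y, x)` (row, column), 1-based.
#' @param window window side length (default 8).
#' @param levels gray levels (default 8).
#' @param angles directions in degrees (default all four).
#' @param range quantization range passed to [quantize_gray_levels()].
#' @param symmetric symmetric GLCMs (default TRUE).
#' @return named numeric vector `c(asm, contrast, correlation)`.
#' @export
window_features <- function(raster, pixel, window = 8L, levels = 8L,
                            angles = c(0, 45, 90, 135), range = NULL,
                            symmetric = TRUE) {
  stopifnot(length(pixel) == 2L,
            pixel[1] >= 1L, pixel[1] <= nrow(raster),
            pixel[2] >= 1L, pixel[2] <= ncol(raster))
  q <- quantize_gray_levels(raster, levels = levels, range = range)
  window_features_quantized(q, as.integer(pixel[1]), as.integer(pixel[2]),
                            window = window, levels = levels,
                            angles = angles, symmetric = symmetric)
}

#' Texture feature maps over a region of interest
#'
#' Computes the windowed (ASM, contrast, correlation) triple at every true
#' pixel of `roi_mask` and writes it into three full-size rasters; pixels
#' outside the ROI are 0. The T1ce slice is quantized once, over the in-ROI
#' intensity range by default, so all windows share one gray-level scale.
#'
#' @param t1ce_raster numeric matrix (T1ce slice).
#' @param roi_mask logical matrix of the same shape.
#' @param levels,window,angles,symmetric see [window_features()].
#' @param range quantization range; default in-ROI `min`/`max` of the slice.
#' @return list of matrices `asm`, `contrast`, `correlation`.
#' @export
texture_feature_maps <- function(t1ce_raster, roi_mask, levels = 8L,
                                 window = 8L, angles = c(0, 45, 90, 135),
                                 symmetric = TRUE, range = NULL) {
  if (!all(dim(t1ce_raster) == dim(roi_mask))) {
    stop("texture error: raster and ROI mask shapes differ")
  }
  H <- nrow(t1ce_raster); W <- ncol(t1ce_raster)
  out <- list(asm = matrix(0, H, W), contrast = matrix(0, H, W),
              correlation = matrix(0, H, W))
  idx <- which(roi_mask)
  if (length(idx) == 0L) return(out)
  if (is.null(range)) {
    v <- t1ce_raster[idx]
    range <- c(min(v), max(v))
    if (range[2] <= range[1]) range <- NULL  # constant ROI -> single bin
  }
  q <- quantize_gray_levels(t1ce_raster, levels = levels, range = range)

  # Precompute one full-image pair-code raster per angle; a window's GLCM is
  # then a tabulate() over the sub-rectangle of first-pixel positions whose
  # partner also falls inside the window.
  nb <- levels * levels
  offs <- lapply(angles, glcm_offset)
  codes <- lapply(offs, function(o) {
    dy <- o[1]; dx <- o[2]
    cm <- matrix(NA_integer_, H, W)
    r0 <- max(1L, 1L - dy); r1 <- min(H, H - dy)
    c0 <- max(1L, 1L - dx); c1 <- min(W, W - dx)
    if (r0 <= r1 && c0 <= c1) {
      a <- q[r0:r1, c0:c1, drop = FALSE]
      b <- q[(r0 + dy):(r1 + dy), (c0 + dx):(c1 + dx), drop = FALSE]
      cm[r0:r1, c0:c1] <- a * levels + b + 1L
    }
    cm
  })
  hw <- window %/% 2L
  ys <- ((idx - 1L) %% H) + 1L
  xs <- ((idx - 1L) %/% H) + 1L
  n_ang <- length(angles)
  for (k in seq_along(idx)) {
    y <- ys[k]; x <- xs[k]
    wr0 <- max(1L, y - hw); wr1 <- min(H, y + hw - 1L)
    wc0 <- max(1L, x - hw); wc1 <- min(W, x + hw - 1L)
    acc <- c(0, 0, 0)
    for (ai in seq_len(n_ang)) {
      o <- offs[[ai]]
      # first-pixel positions: window clipped so the partner stays inside
      r0 <- max(wr0, wr0 - o[1]); r1 <- min(wr1, wr1 - o[1])
      c0 <- max(wc0, wc0 - o[2]); c1 <- min(wc1, wc1 - o[2])
      f <- c(0, 0, 0)
      if (r0 <= r1 && c0 <= c1) {
        cd <- codes[[ai]][r0:r1, c0:c1]
        tab <- tabulate(cd, nbins = nb)
        tot <- sum(tab)
        if (tot > 0) {
          # symmetric GLCM: p and its transpose; moments from the row-major
          # probability vector without materializing the matrix
          pm <- matrix(tab, levels, levels, byrow = TRUE)
          if (symmetric) pm <- pm + t(pm)
          f <- haralick_features(pm)
        }
      }
      acc <- acc + f
    }
    v <- acc / n_ang
    out$asm[y, x] <- v[1]
    out$contrast[y, x] <- v[2]
    out$correlation[y, x] <- v[3]
  }
  out
}
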
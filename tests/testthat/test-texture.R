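test_that("quantization bins linearly with saturating ends", {
  expect_identical(as.vector(quantize_gray_levels(matrix(c(0, 0.5, 1), 1),
                                                  levels = 2L,
                                                  range = c(0, 1))),
                   c(0L, 1L, 1L))
  expect_identical(quantize_gray_levels(matrix(7, 3, 3)),
                   matrix(0L, 3, 3))               # constant -> single bin
  expect_error(quantize_gray_levels(matrix(1:4, 2), range = c(2, 2)),
               "quantization error")
  # monotone
  set.seed(8)
  x <- sort(runif(100, -3, 3))
  q <- quantize_gray_levels(matrix(x, 1), levels = 8L, range = c(-3, 3))
  expect_true(all(diff(as.vector(q)) >= 0L))
  expect_true(all(q >= 0L & q <= 7L))
})

test_that("compute_glcm equals the exhaustive pair-counting oracle", {
  # hand enumeration: 1x2 raster [0, 1], 0 degrees, symmetric
  g <- compute_glcm(matrix(c(0L, 1L), 1, 2), angle = 0, levels = 2L)
  expect_identical(g$counts, matrix(c(0L, 1L, 1L, 0L), 2, 2))
  # constant raster: all mass on the diagonal
  for (a in c(0, 45, 90, 135)) {
    gc <- compute_glcm(matrix(2L, 8, 8), angle = a, levels = 8L)
    expect_equal(sum(gc$counts) , gc$counts[3, 3])
  }
  # randomized equivalence, all angles, both symmetry settings
  set.seed(9)
  for (t in 1:25) {
    L <- sample(2:8, 1)
    q <- matrix(sample(0:(L - 1), 36, TRUE), 6, 6)
    for (a in c(0, 45, 90, 135)) for (sym in c(TRUE, FALSE)) {
      expect_identical(compute_glcm(q, a, L, symmetric = sym)$counts,
                       brute_glcm(q, glcm_offset(a), L, sym))
    }
  }
})

test_that("haralick_features matches the direct formulas and degenerate rules", {
  # frozen closed forms (oracle-confirmed below)
  cb <- outer(1:4, 1:4, function(i, j) (i + j) %% 2L)  # two-level checkerboard
  g <- compute_glcm(cb, angle = 0, levels = 2L)
  f <- haralick_features(g)
  expect_equal(unname(f), c(0.5, 1, -1))
  expect_equal(unname(f), brute_haralick(g$counts))

  expect_equal(unname(haralick_features(matrix(c(10L, 0L, 0L, 0L), 2, 2))),
               c(1, 0, 0))                          # constant window
  expect_equal(unname(haralick_features(matrix(0L, 4, 4))), c(0, 0, 0))

  set.seed(10)
  for (t in 1:25) {
    L <- sample(2:8, 1)
    q <- matrix(sample(0:(L - 1), 49, TRUE), 7, 7)
    g <- compute_glcm(q, angle = sample(c(0, 45, 90, 135), 1), levels = L)
    expect_equal(unname(haralick_features(g)), brute_haralick(g$counts),
                 tolerance = 1e-12)
  }
})

test_that("feature ranges hold on random inputs", {
  set.seed(12)
  for (t in 1:30) {
    L <- sample(2:8, 1)
    q <- matrix(sample(0:(L - 1), 64, TRUE), 8, 8)
    f <- haralick_features(compute_glcm(q, angle = 45, levels = L))
    expect_gte(f[["asm"]], 0); expect_lte(f[["asm"]], 1)
    expect_gte(f[["contrast"]], 0)
    expect_lte(f[["contrast"]], (L - 1)^2)
    expect_gte(f[["correlation"]], -1); expect_lte(f[["correlation"]], 1)
  }
})

test_that("rotating a raster 90 degrees swaps the 0/90-degree GLCMs", {
  set.seed(13)
  q <- matrix(sample(0:7, 48, TRUE), 6, 8)
  rot <- t(q[nrow(q):1, ])                           # 90-degree rotation
  g0 <- compute_glcm(q, angle = 0, levels = 8L)
  g90 <- compute_glcm(rot, angle = 90, levels = 8L)
  expect_identical(g0$counts, g90$counts)
})

test_that("window_features matches the per-angle oracle with border clipping", {
  # constant image: interior pixel gives (1, 0, 0), corners clip silently
  const <- matrix(4, 20, 20)
  expect_equal(unname(window_features(const, c(10, 10))), c(1, 0, 0))
  expect_equal(unname(window_features(const, c(1, 1))), c(1, 0, 0))

  set.seed(14)
  img <- matrix(runif(40 * 40), 40, 40)
  q <- quantize_gray_levels(img, 8L)
  pix <- cbind(sample(1:40, 25, TRUE), sample(1:40, 25, TRUE))
  for (k in seq_len(nrow(pix))) {
    got <- window_features(img, pix[k, ])
    want <- brute_window_features(q, pix[k, 1], pix[k, 2], 8L, 8L,
                                  c(0, 45, 90, 135), TRUE)
    expect_equal(unname(got), unname(want), tolerance = 1e-12)
  }
})

test_that("texture_feature_maps fills exactly the ROI and matches window_features", {
  set.seed(15)
  img <- matrix(runif(30 * 30), 30, 30)
  roi <- matrix(FALSE, 30, 30); roi[8:20, 10:25] <- TRUE
  maps <- texture_feature_maps(img, roi)
  expect_true(all(maps$asm[!roi] == 0))
  expect_true(all(maps$contrast[!roi] == 0))
  # agreement with the single-pixel path under the same quantization range
  rng <- range(img[roi])
  for (k in 1:15) {
    yx <- which(roi, arr.ind = TRUE)[sample(sum(roi), 1), ]
    expect_equal(c(maps$asm[yx[1], yx[2]], maps$contrast[yx[1], yx[2]],
                   maps$correlation[yx[1], yx[2]]),
                 unname(window_features(img, yx, range = rng)),
                 tolerance = 1e-12)
  }

  empty <- texture_feature_maps(img, matrix(FALSE, 30, 30))
  expect_true(all(empty$asm == 0) && all(empty$contrast == 0))

  one <- matrix(FALSE, 30, 30); one[15, 15] <- TRUE
  m1 <- texture_feature_maps(img, one)
  expect_equal(sum(m1$asm != 0), 1L)
  expect_error(texture_feature_maps(img, matrix(TRUE, 10, 10)),
               "shapes differ")
})
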
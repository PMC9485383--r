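test_that("pooling stores argmax indices and unpooling restores them (4x4 toy)", {
  # hand-enumerated: maxima at known positions of each 2x2 cell
  m <- matrix(c(1, 3, 5, 6,
                4, 2, 8, 7,
                9, 10, 13, 16,
                12, 11, 14, 15), 4, 4, byrow = TRUE)
  x <- array(m, dim = c(4L, 4L, 1L))
  pl <- maxpool2x2(x)
  expect_equal(matrix(pl$out[, , 1], 2, 2),
               matrix(c(4, 12, 8, 16), 2, 2))
  # hand-computed linear (column-major) indices of those maxima in m
  expect_setequal(pl$idx, c(2L, 4L, 10L, 15L))
  up <- maxunpool2x2(pl$out, pl$idx, pl$in_dim)
  expect_equal(sum(up != 0), 4L)
  expect_equal(up[2, 1, 1], 4)    # max of top-left cell back at its spot
  expect_equal(up[3, 4, 1], 16)
  expect_true(all(up[up != 0] %in% c(4, 8, 12, 16)))

  # tie rule: first element in column-major cell order wins
  tie <- array(1, dim = c(2L, 2L, 1L))
  expect_equal(maxpool2x2(tie)$idx, 1L)
})

test_that("pool/unpool round trip leaves values only at pooled positions", {
  set.seed(16)
  for (t in 1:5) {
    x <- array(rnorm(8 * 8 * 3), dim = c(8L, 8L, 3L))
    pl <- maxpool2x2(x)
    up <- maxunpool2x2(pl$out, pl$idx, pl$in_dim)
    expect_equal(as.vector(up)[pl$idx], as.vector(pl$out))
    expect_true(all(as.vector(up)[-pl$idx] == 0))
    # each pooled value is the max of x over its cell
    expect_equal(sort(as.vector(pl$out)),
                 sort(as.vector(up)[as.vector(up) != 0]))
  }
})

test_that("network builds with contracted shapes and seeded init", {
  cfg <- net_config(3L, 4L, depth = 2L, base_width = 8L, seed = 7L)
  m1 <- build_network(cfg)
  m2 <- build_network(cfg)
  expect_identical(m1$layers, m2$layers)
  expect_gt(m1$n_params, 0)

  x <- array(rnorm(32 * 32 * 3), dim = c(32L, 32L, 3L))
  sc <- extract_score_maps(m1, x)
  expect_equal(dim(sc), c(32L, 32L, 4L))
  expect_identical(attr(sc, "class_space"), "class_index")

  expect_error(extract_score_maps(m1, array(0, c(32, 32, 2))),
               "inference error")
  expect_error(extract_score_maps(m1, array(0, c(30, 32, 3))),
               "not divisible")
  expect_error(net_config(1L, 3L), "n_classes")
})

test_that("score maps live on the per-pixel simplex for random inputs", {
  cfg <- net_config(1L, 2L, depth = 2L, base_width = 4L, seed = 2L)
  model <- build_network(cfg)
  set.seed(17)
  for (t in 1:3) {
    sc <- extract_score_maps(model, matrix(rnorm(16 * 16), 16, 16))
    expect_true(all(sc >= 0 & sc <= 1))
    sums <- apply(sc, c(1, 2), sum)
    expect_lt(max(abs(sums - 1)), 1e-5)
  }
})

test_that("analytic gradients match finite differences of the forward loss", {
  cfg <- net_config(1L, 2L, depth = 2L, base_width = 2L, seed = 5L)
  model <- build_network(cfg)
  set.seed(18)
  x <- array(rnorm(8 * 8), dim = c(8L, 8L, 1L))
  tgt <- as.integer(matrix(rbinom(64, 1, 0.4), 8, 8))
  wts <- c(1, 1)
  lg <- glcmseg:::net_loss_grads(model, x, tgt, wts)
  h <- 1e-5
  for (l in seq_along(model$layers)) {
    set.seed(19 + l)
    for (k in sample(length(model$layers[[l]]$W), 4)) {
      mp <- model; mp$layers[[l]]$W[k] <- mp$layers[[l]]$W[k] + h
      mm <- model; mm$layers[[l]]$W[k] <- mm$layers[[l]]$W[k] - h
      fd <- (glcmseg:::net_loss_grads(mp, x, tgt, wts)$loss -
             glcmseg:::net_loss_grads(mm, x, tgt, wts)$loss) / (2 * h)
      expect_equal(lg$grads[[l]]$dW[k], fd, tolerance = 1e-4)
    }
    # bias gradient
    kb <- 1L
    mp <- model; mp$layers[[l]]$b[kb] <- mp$layers[[l]]$b[kb] + h
    mm <- model; mm$layers[[l]]$b[kb] <- mm$layers[[l]]$b[kb] - h
    fd <- (glcmseg:::net_loss_grads(mp, x, tgt, wts)$loss -
           glcmseg:::net_loss_grads(mm, x, tgt, wts)$loss) / (2 * h)
    expect_equal(lg$grads[[l]]$db[kb], fd, tolerance = 1e-4)
  }
})

test_that("training reduces loss, is seed-deterministic, and handles degenerate labels", {
  st <- make_phantom_set(2, seed = 23, image_size = c(32L, 32L))
  inputs <- lapply(st, function(s) s$modalities$FLAIR)
  targets <- lapply(st, function(s) to_binary_labels(s$labels))
  cfg <- net_config(1L, 2L, depth = 2L, base_width = 4L, epochs = 10L,
                    seed = 3L)
  m1 <- train_segmentation(build_network(cfg), inputs, targets)
  expect_lt(m1$loss_trace[10], 0.5 * m1$loss_trace[1])
  m2 <- train_segmentation(build_network(cfg), inputs, targets)
  expect_identical(m1$layers, m2$layers)

  # constant-label cohort: predicts that label everywhere
  const_t <- list(matrix(0L, 32, 32))
  mc <- train_segmentation(build_network(cfg), inputs[1], const_t,
                           epochs = 40L)
  pred <- predict_argmax(extract_score_maps(mc, inputs[[1]]))
  expect_true(all(pred == 0L))

  expect_error(train_segmentation(build_network(cfg), inputs,
                                  list(matrix(2L, 32, 32),
                                       matrix(0L, 32, 32))),
               "training error")
})

test_that("argmax prediction matches brute force and breaks ties low", {
  expect_equal(predict_argmax(array(c(0.1, 0.2, 0.3, 0.4),
                                    dim = c(1, 1, 4)))[1, 1], 3L)
  expect_equal(predict_argmax(array(0.25, dim = c(1, 1, 4)))[1, 1], 0L)
  set.seed(20)
  sc <- array(runif(6 * 6 * 4), dim = c(6, 6, 4))
  got <- predict_argmax(sc)
  for (y in 1:6) for (x in 1:6) {
    expect_equal(got[y, x], which.max(sc[y, x, ]) - 1L)
  }
})

test_that("a depth-2 net overfits one subject to >= 0.99 pixel accuracy", {
  st <- make_phantom_set(1, seed = 29)[[1]]
  tgt <- to_binary_labels(st$labels)
  cfg <- net_config(1L, 2L, depth = 2L, base_width = 8L, epochs = 40L,
                    seed = 11L)
  m <- train_segmentation(build_network(cfg), list(st$modalities$FLAIR),
                          list(tgt))
  pred <- predict_argmax(extract_score_maps(m, st$modalities$FLAIR))
  expect_gte(mean(pred == tgt), 0.99)
})

test_that("model checkpoints round-trip through JSON", {
  td <- withr::local_tempdir()
  cfg <- net_config(1L, 2L, depth = 2L, base_width = 4L, seed = 13L)
  m <- build_network(cfg)
  p <- file.path(td, "net.json")
  save_model(m, p)
  m2 <- load_model(p)
  expect_equal(m2$layers, m$layers, tolerance = 1e-12)
  x <- matrix(rnorm(16 * 16), 16, 16)
  expect_equal(extract_score_maps(m2, x), extract_score_maps(m, x),
               tolerance = 1e-12)
})
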
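random_scores <- function(H, W) {
  raw <- array(runif(H * W * 4), dim = c(H, W, 4))
  s <- apply(raw, c(1, 2), sum)
  array(raw / as.vector(s)[rep(seq_len(H * W), 4)], dim = c(H, W, 4))
}

random_tex <- function(H, W) {
  list(asm = matrix(runif(H * W), H, W),
       contrast = matrix(runif(H * W, 0, 49), H, W),
       correlation = matrix(runif(H * W, -1, 1), H, W))
}

test_that("assemble_features yields one 7-vector per ROI pixel by direct lookup", {
  set.seed(23)
  H <- 12L; W <- 10L
  sc <- random_scores(H, W); tx <- random_tex(H, W)
  roi <- matrix(runif(H * W) < 0.3, H, W)
  lab <- matrix(sample(c(0L, 1L, 2L, 4L), H * W, TRUE), H, W)
  av <- assemble_features(sc, tx, roi, gt_labels = lab)
  expect_equal(nrow(av$features), sum(roi))
  expect_equal(ncol(av$features), 7L)
  # row-major ordering
  expect_true(all(diff(av$pixels[, "y"]) >= 0))
  for (k in sample(nrow(av$features), min(10, nrow(av$features)))) {
    y <- av$pixels[k, 1]; x <- av$pixels[k, 2]
    expect_equal(unname(av$features[k, 1:4]), sc[y, x, ])
    expect_equal(unname(av$features[k, 5:7]),
                 c(tx$asm[y, x], tx$contrast[y, x], tx$correlation[y, x]))
    expect_equal(av$labels[k], to_class_index(matrix(lab[y, x]))[1])
  }
  expect_lt(max(abs(rowSums(av$features[, 1:4]) - 1)), 1e-5)

  none <- assemble_features(sc, tx, matrix(FALSE, H, W))
  expect_equal(nrow(none$features), 0L)
  expect_null(none$labels)
  expect_error(assemble_features(sc, tx, matrix(TRUE, 5, 5)),
               "fusion error")
})

test_that("decision tree separates a linearly separable toy at depth 2", {
  set.seed(24)
  n <- 100L
  X <- matrix(runif(n * 7), n, 7)
  y <- ifelse(X[, 6] > 0.5, 3L, 1L)      # single threshold on contrast
  tree <- train_dt(X, y, dt_config(max_depth = 2L))
  expect_equal(tree$train_accuracy, 1)
  expect_identical(classify_pixels(tree, X), y)
})

test_that("train_dt is deterministic and rejects single-class labels", {
  set.seed(25)
  X <- matrix(runif(300 * 7), 300, 7)
  y <- sample(0:3, 300, TRUE)
  t1 <- train_dt(X, y, dt_config(max_depth = 20L, seed = 1L))
  t2 <- train_dt(X, y, dt_config(max_depth = 20L, seed = 1L))
  expect_identical(t1$nodes, t2$nodes)
  expect_error(train_dt(X, rep(2L, 300)), "missing classes: 0, 1, 3")
})

test_that("deeper trees fit the training set at least as well", {
  set.seed(26)
  n <- 800L
  X <- matrix(runif(n * 7), n, 7)
  y <- (X[, 2] > 0.4) + (X[, 6] > 0.6) + (X[, 7] > 0.1 & X[, 5] > 0.3)
  y <- as.integer(y)
  accs <- vapply(c(4L, 20L, 100L), function(d) {
    train_dt(X, y, dt_config(max_depth = d))$train_accuracy
  }, 0)
  expect_true(all(diff(accs) >= 0))
  expect_equal(accs[3], 1)               # fine tree memorizes (min_leaf 1)
})

test_that("classification agrees with an independent re-descent of the JSON tree", {
  td <- withr::local_tempdir()
  set.seed(27)
  X <- matrix(runif(400 * 7), 400, 7)
  y <- as.integer((X[, 1] > 0.5) + 2 * (X[, 5] > 0.5))
  tree <- train_dt(X, y, dt_config(max_depth = 100L))
  p <- file.path(td, "tree.json")
  save_tree(tree, p)
  Xnew <- matrix(runif(50 * 7), 50, 7)
  got <- classify_pixels(tree, Xnew)
  for (k in 1:50) {
    expect_equal(got[k], json_tree_descend(p, Xnew[k, ]))
  }
  # load_tree round trip predicts identically
  tree2 <- load_tree(p)
  expect_identical(classify_pixels(tree2, Xnew), got)
  expect_identical(classify_pixels(tree, X), as.integer(y))
  expect_identical(classify_pixels(tree, X[0, , drop = FALSE]), integer(0))
  expect_error(classify_pixels(tree, matrix(0, 2, 5)), "7-element")
})

test_that("reconstruct_label_map inverts class indices inside the ROI only", {
  roi <- matrix(FALSE, 6, 6); roi[2:4, 3:5] <- TRUE
  n <- sum(roi)
  out <- reconstruct_label_map(rep(1L, n), roi)
  expect_true(all(out[roi] == 2L))       # edema class -> BRATS 2
  expect_true(all(out[!roi] == 0L))

  cls <- c(0L, 1L, 2L, 3L, rep(0L, n - 4))
  out2 <- reconstruct_label_map(cls, roi)
  expect_setequal(unique(out2[roi]), c(0L, 2L, 1L, 4L))
  expect_identical(reconstruct_label_map(integer(0), matrix(FALSE, 3, 3)),
                   matrix(0L, 3, 3))
  expect_error(reconstruct_label_map(1L, roi), "count")
})

test_that("assemble -> classify -> reconstruct round-trips ROI geometry", {
  set.seed(28)
  H <- 16L; W <- 16L
  sc <- random_scores(H, W); tx <- random_tex(H, W)
  # <= 77 ROI pixels: even a worst-case chain tree stays within depth 100,
  # so the fine tree memorizes the (random) training labels exactly
  roi <- matrix(runif(H * W) < 0.3, H, W)
  lab <- matrix(0L, H, W)
  lab[roi] <- sample(c(1L, 2L, 4L), sum(roi), TRUE)
  av <- assemble_features(sc, tx, roi, gt_labels = lab)
  tree <- train_dt(av$features, av$labels, dt_config(max_depth = 100L))
  cls <- classify_pixels(tree, av$features)
  rec <- reconstruct_label_map(cls, roi)
  expect_true(all(rec[!roi] == 0L))
  # nonzero predictions only inside ROI; fine tree memorizes the training map
  expect_identical(rec[roi], lab[roi])
})
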
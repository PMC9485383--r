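# Feature fusion and decision-tree pixel classification.
#
# Each ROI pixel is described by 7 numbers: the 4 network score-map values
# (background, edema, necrosis, enhancing) and the 3 windowed GLCM texture
# features (ASM, contrast, correlation) from T1ce. A CART decision tree
# (Gini, axis-aligned) classifies the vectors; pixels outside the ROI are
# never classified — that restriction is the pipeline's cost-reduction
# device and a tested structural invariant.

FEATURE_NAMES <- c("bg", "edema", "necrosis", "enhancing",
                   "asm", "contrast", "correlation")

#' Assemble per-pixel fused feature vectors over the ROI
#'
#' One 7-element vector per true ROI pixel, in row-major pixel order (row by
#' row, left to right). When a BRATS ground-truth map is supplied the
#' class-index label of each pixel is attached.
#'
#' @param scores `H x W x 4` score maps (class-index order).
#' @param texture_maps list with `asm`, `contrast`, `correlation` rasters.
#' @param roi_mask logical matrix.
#' @param gt_labels optional BRATS label matrix.
#' @return list with `features` (n x 7 matrix, columns
#'   bg/edema/necrosis/enhancing/asm/contrast/correlation), `pixels`
#'   (n x 2 matrix of 1-based (y, x)), and `labels` (n-vector of class
#'   indices, or NULL).
#' @export
assemble_features <- function(scores, texture_maps, roi_mask,
                              gt_labels = NULL) {
  d <- dim(roi_mask)
  if (!identical(dim(scores)[1:2], d) ||
      !all(vapply(texture_maps, function(m) identical(dim(m), d), TRUE))) {
    stop("fusion error: raster shape mismatch")
  }
  if (dim(scores)[3] != 4L) stop("fusion error: expected 4 score maps")
  idx <- which(roi_mask)
  H <- d[1]
  ys <- ((idx - 1L) %% H) + 1L
  xs <- ((idx - 1L) %/% H) + 1L
  ord <- order(ys, xs)            # row-major pixel order
  idx <- idx[ord]; ys <- ys[ord]; xs <- xs[ord]
  n <- length(idx)
  feats <- matrix(0, n, 7L, dimnames = list(NULL, FEATURE_NAMES))
  if (n > 0L) {
    HW <- prod(d)
    for (k in 1:4) feats[, k] <- scores[idx + (k - 1L) * HW]
    feats[, 5L] <- texture_maps$asm[idx]
    feats[, 6L] <- texture_maps$contrast[idx]
    feats[, 7L] <- texture_maps$correlation[idx]
  }
  labels <- NULL
  if (!is.null(gt_labels)) {
    if (!identical(dim(gt_labels), d)) stop("fusion error: label shape mismatch")
    labels <- as.integer(to_class_index(gt_labels)[idx])
  }
  list(features = feats, pixels = cbind(y = ys, x = xs), labels = labels)
}

#' Decision-tree configuration
#'
#' Defaults follow the "fine tree" setting: maximum depth 100, Gini
#' impurity, minimum leaf size 1, no pruning. The depth sweep of interest is
#' `{4, 20, 100}` (coarse / medium / fine).
#'
#' @param max_depth maximum tree depth (root = depth 0); >= 1.
#' @param min_leaf minimum samples per leaf.
#' @param seed used when training data are subsampled upstream.
#' @return object of class `dt_config`.
#' @export
dt_config <- function(max_depth = 100L, min_leaf = 1L, seed = 1L) {
  if (max_depth < 1L) stop("config error: max_depth must be >= 1")
  structure(list(max_depth = as.integer(max_depth),
                 min_leaf = as.integer(min_leaf), seed = as.integer(seed)),
            class = "dt_config")
}

# best Gini split of one node; returns NULL when no split improves impurity
best_split <- function(X, y, n_classes, min_leaf) {
  n <- length(y)
  best <- NULL
  onehot <- matrix(0, n, n_classes)
  onehot[cbind(seq_len(n), y + 1L)] <- 1
  for (j in seq_len(ncol(X))) {
    v <- X[, j]
    o <- order(v)
    vs <- v[o]
    cum <- apply(onehot[o, , drop = FALSE], 2L, cumsum)  # n x C
    # candidate cut after position i where value changes
    cuts <- which(diff(vs) > 0)
    cuts <- cuts[cuts >= min_leaf & (n - cuts) >= min_leaf]
    if (length(cuts) == 0L) next
    nl <- cuts
    cl <- cum[cuts, , drop = FALSE]
    cr <- matrix(cum[n, ], length(cuts), n_classes, byrow = TRUE) - cl
    gl <- 1 - rowSums((cl / nl)^2)
    gr <- 1 - rowSums((cr / (n - nl))^2)
    imp <- (nl * gl + (n - nl) * gr) / n
    k <- which.min(imp)
    if (is.null(best) || imp[k] < best$impurity - 1e-12) {
      best <- list(feature = j,
                   threshold = (vs[cuts[k]] + vs[cuts[k] + 1L]) / 2,
                   impurity = imp[k])
    }
  }
  best
}

#' Train a CART decision tree on fused pixel features
#'
#' Axis-aligned binary tree grown greedily on Gini impurity to at most
#' `max_depth`; deterministic (ties resolved toward the lowest feature
#' index). Requires at least two classes in the labels.
#'
#' @param features n x 7 numeric matrix (see [assemble_features()]).
#' @param labels integer class indices 0..3.
#' @param config a `dt_config`.
#' @return object of class `pixel_dt`: flat node table (list of nodes with
#'   `feature`, `threshold`, `left`, `right` or leaf `class`), plus
#'   `train_accuracy` and `config`.
#' @export
train_dt <- function(features, labels, config = dt_config()) {
  stopifnot(is.matrix(features), length(labels) == nrow(features))
  labels <- as.integer(labels)
  if (any(!is.finite(features))) stop("fusion error: non-finite features")
  present <- sort(unique(labels))
  if (length(present) < 2L) {
    stop("training error: need >= 2 classes; missing classes: ",
         paste(setdiff(0:3, present), collapse = ", "))
  }
  n_classes <- 4L
  nodes <- list()
  new_node <- function(node) {
    nodes[[length(nodes) + 1L]] <<- node
    length(nodes)
  }
  grow <- function(rows, depth) {
    y <- labels[rows]
    counts <- tabulate(y + 1L, nbins = n_classes)
    maj <- which.max(counts) - 1L
    pure <- sum(counts > 0L) == 1L
    if (pure || depth >= config$max_depth ||
        length(rows) < 2L * config$min_leaf) {
      return(new_node(list(leaf = TRUE, class = maj, n = length(rows))))
    }
    sp <- best_split(features[rows, , drop = FALSE], y, n_classes,
                     config$min_leaf)
    if (is.null(sp)) {
      return(new_node(list(leaf = TRUE, class = maj, n = length(rows))))
    }
    go_left <- features[rows, sp$feature] <= sp$threshold
    left <- grow(rows[go_left], depth + 1L)
    right <- grow(rows[!go_left], depth + 1L)
    new_node(list(leaf = FALSE, feature = sp$feature,
                  threshold = sp$threshold, left = left, right = right,
                  n = length(rows)))
  }
  root <- grow(seq_len(nrow(features)), 0L)
  tree <- structure(list(nodes = nodes, root = root, config = config,
                         n_features = ncol(features)),
                    class = "pixel_dt")
  tree$train_accuracy <- mean(classify_pixels(tree, features) == labels)
  tree
}

#' Classify fused pixel feature vectors
#'
#' Descends the tree for all vectors at once (level-synchronous partition);
#' the rule at each internal node is `feature <= threshold` goes left.
#'
#' @param tree a `pixel_dt`.
#' @param features n x 7 matrix.
#' @return integer vector of class indices (0..3), length n.
#' @export
classify_pixels <- function(tree, features) {
  stopifnot(inherits(tree, "pixel_dt"))
  if (!is.matrix(features)) features <- matrix(features, nrow = 1L)
  if (ncol(features) != tree$n_features) {
    stop("fusion error: expected ", tree$n_features, "-element vectors")
  }
  n <- nrow(features)
  out <- integer(n)
  if (n == 0L) return(out)
  node_of <- rep(tree$root, n)
  repeat {
    done <- TRUE
    for (id in unique(node_of)) {
      nd <- tree$nodes[[id]]
      rows <- which(node_of == id)
      if (nd$leaf) {
        out[rows] <- nd$class
      } else {
        done <- FALSE
        gl <- features[rows, nd$feature] <= nd$threshold
        node_of[rows[gl]] <- nd$left
        node_of[rows[!gl]] <- nd$right
      }
    }
    if (done) break
  }
  out
}

#' Save / load a decision tree as plain JSON
#'
#' The flat node table serializes directly, so an independent traversal
#' oracle can re-descend the file without this package.
#'
#' @param tree a `pixel_dt`.
#' @param path `.json` file.
#' @export
save_tree <- function(tree, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(root = tree$root, n_features = tree$n_features,
         config = unclass(tree$config),
         train_accuracy = tree$train_accuracy, nodes = tree$nodes),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_tree
#' @export
load_tree <- function(path) {
  obj <- jsonlite::read_json(path)
  nodes <- lapply(obj$nodes, function(nd) {
    nd$leaf <- isTRUE(nd$leaf)
    nd
  })
  structure(list(nodes = nodes, root = obj$root,
                 config = do.call(dt_config, obj$config[c("max_depth",
                                                          "min_leaf", "seed")]),
                 n_features = obj$n_features,
                 train_accuracy = obj$train_accuracy),
            class = "pixel_dt")
}

#' Rebuild a full-size BRATS label map from per-pixel classes
#'
#' Classes are written back at the ROI pixels (row-major order, matching
#' [assemble_features()]) through the inverse class-index mapping; all
#' pixels outside the ROI are 0.
#'
#' @param classes integer class indices, one per true ROI pixel.
#' @param roi_mask logical matrix.
#' @return integer matrix in BRATS label space.
#' @export
reconstruct_label_map <- function(classes, roi_mask) {
  idx <- which(roi_mask)
  if (length(classes) != length(idx)) {
    stop("fusion error: class count ", length(classes),
         " != ROI pixel count ", length(idx))
  }
  out <- matrix(0L, nrow(roi_mask), ncol(roi_mask))
  if (length(idx) > 0L) {
    H <- nrow(roi_mask)
    ys <- ((idx - 1L) %% H) + 1L
    xs <- ((idx - 1L) %/% H) + 1L
    ord <- order(ys, xs)
    out[idx[ord]] <- from_class_index(as.integer(classes))
  }
  out
}
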
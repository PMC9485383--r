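# Compact SegNet-style encoder-decoder, pure R.
#
# Convolutions are 3x3 / pad 1 implemented as im2col + BLAS matrix products;
# downsampling is 2x2 max pooling that records argmax indices, and the
# decoder upsamples by placing values back at those indices (the
# pooling-index unpooling that distinguishes this architecture from U-Net
# style skip concatenation). One conv per stage, He init, Adam, per-pixel
# cross-entropy, softmax score maps. Desk-scale by design: trained from
# random initialization, single-threaded deterministic given the seed.

#' Network configuration
#'
#' @param in_channels input channels (1 for single-modality binary ROI nets,
#'   3 for the combined FLAIR/T1ce/T2 ROI images).
#' @param n_classes 2 (background/tumor) or 4 (background/edema/necrosis/
#'   enhancing, in class-index order).
#' @param depth encoder stages (>= 2); input H and W must be divisible by
#'   `2^depth`.
#' @param base_width channels of the first stage; stage s has
#'   `base_width * 2^(s-1)`.
#' @param epochs,batch_size,learning_rate training defaults (Adam).
#' @param class_weights `"none"` (default) or `"inverse"` for
#'   inverse-frequency per-class loss weights.
#' @param seed initialization / training seed.
#' @return object of class `net_config`.
#' @export
net_config <- function(in_channels, n_classes, depth = 2L, base_width = 8L,
                       epochs = 20L, batch_size = 1L, learning_rate = 0.01,
                       class_weights = c("none", "inverse"), seed = 1L) {
  class_weights <- match.arg(class_weights)
  if (!n_classes %in% c(2L, 4L)) stop("config error: n_classes must be 2 or 4")
  if (depth < 2L) stop("config error: depth must be >= 2")
  structure(
    list(in_channels = as.integer(in_channels),
         n_classes = as.integer(n_classes), depth = as.integer(depth),
         base_width = as.integer(base_width), epochs = as.integer(epochs),
         batch_size = as.integer(batch_size),
         learning_rate = learning_rate, class_weights = class_weights,
         seed = as.integer(seed)),
    class = "net_config"
  )
}

# ---- im2col machinery (cached per input geometry) ---------------------------

.net_cache <- new.env(parent = emptyenv())

# linear indices into a zero-padded (H+2)x(W+2)xC array such that
# pad[idx] reshaped to (H*W) x (9*C) is the im2col matrix for 3x3/pad-1
im2col_idx <- function(H, W, C) {
  key <- paste(H, W, C, sep = "x")
  hit <- .net_cache[[key]]
  if (!is.null(hit)) return(hit)
  Hp <- H + 2L; Wp <- W + 2L
  # center positions (1-based in padded coords): rows 2..H+1, cols 2..W+1
  rows <- rep(seq_len(H) + 1L, times = W)
  cols <- rep(seq_len(W) + 1L, each = H)
  base <- rows + (cols - 1L) * Hp            # H*W
  offs <- as.vector(outer(-1:1, (-1:1) * Hp, `+`))  # 9 neighbor offsets
  per_chan <- outer(base, offs, `+`)         # (H*W) x 9
  chan_shift <- (seq_len(C) - 1L) * (Hp * Wp)
  idx <- matrix(0L, H * W, 9L * C)
  for (c in seq_len(C)) {
    idx[, ((c - 1L) * 9L + 1L):(c * 9L)] <- per_chan + chan_shift[c]
  }
  .net_cache[[key]] <- idx
  idx
}

pad_input <- function(x, H, W, C) {
  pad <- array(0, dim = c(H + 2L, W + 2L, C))
  pad[2:(H + 1L), 2:(W + 1L), ] <- x
  pad
}

conv_forward <- function(x, Wt, b) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]
  idx <- im2col_idx(H, W, C)
  pad <- pad_input(x, H, W, C)
  cols <- matrix(pad[idx], H * W, 9L * C)
  y <- cols %*% Wt
  y <- sweep(y, 2L, b, `+`)
  list(out = array(y, dim = c(H, W, ncol(Wt))), cols = cols)
}

conv_backward <- function(dy, cols, Wt, in_dim) {
  H <- in_dim[1]; W <- in_dim[2]; C <- in_dim[3]
  dym <- matrix(dy, H * W, ncol(Wt))
  dW <- crossprod(cols, dym)
  db <- colSums(dym)
  dcols <- dym %*% t(Wt)
  idx <- im2col_idx(H, W, C)
  dpad <- numeric((H + 2L) * (W + 2L) * C)
  for (j in seq_len(ncol(idx))) {
    ij <- idx[, j]
    dpad[ij] <- dpad[ij] + dcols[, j]
  }
  dpad <- array(dpad, dim = c(H + 2L, W + 2L, C))
  list(dx = dpad[2:(H + 1L), 2:(W + 1L), , drop = FALSE], dW = dW, db = db)
}

# ---- 2x2 max pooling with argmax indices ------------------------------------

pool_grid <- function(H2, W2, C) {
  key <- paste("pg", H2, W2, C, sep = "x")
  hit <- .net_cache[[key]]
  if (!is.null(hit)) return(hit)
  g <- list(
    i2 = rep(seq_len(H2), times = W2 * C),
    j2 = rep(rep(seq_len(W2), each = H2), times = C),
    cc = rep(seq_len(C), each = H2 * W2)
  )
  .net_cache[[key]] <- g
  g
}

#' 2x2 max pooling with recorded argmax indices
#'
#' @param x `H x W x C` array, H and W even.
#' @return list with `out` (`H/2 x W/2 x C`), `idx` (linear indices into `x`
#'   of each pooled maximum; ties go to the first element in column-major
#'   order within the 2x2 cell), `in_dim`.
#' @export
maxpool2x2 <- function(x) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]
  stopifnot(H %% 2L == 0L, W %% 2L == 0L)
  H2 <- H %/% 2L; W2 <- W %/% 2L
  A <- x; dim(A) <- c(2L, H2, 2L, W2, C)
  M <- cbind(as.vector(A[1, , 1, , ]), as.vector(A[2, , 1, , ]),
             as.vector(A[1, , 2, , ]), as.vector(A[2, , 2, , ]))
  arg <- max.col(M, ties.method = "first")
  out <- M[cbind(seq_len(nrow(M)), arg)]
  g <- pool_grid(H2, W2, C)
  i1 <- ((arg - 1L) %% 2L) + 1L
  j1 <- ((arg - 1L) %/% 2L) + 1L
  lin <- (i1 + 2L * (g$i2 - 1L)) +
    ((j1 + 2L * (g$j2 - 1L)) - 1L) * H +
    (g$cc - 1L) * (H * W)
  list(out = array(out, dim = c(H2, W2, C)), idx = lin, in_dim = d)
}

#' Max unpooling from recorded indices
#'
#' Places each pooled value back at the position of the maximum it came
#' from; all other positions are zero.
#'
#' @param y pooled `H/2 x W/2 x C` array (or vector in its element order).
#' @param idx,in_dim from [maxpool2x2()].
#' @return `H x W x C` array.
#' @export
maxunpool2x2 <- function(y, idx, in_dim) {
  x <- numeric(prod(in_dim))
  x[idx] <- as.vector(y)
  array(x, dim = in_dim)
}

# ---- model ------------------------------------------------------------------

#' Build an encoder-decoder segmentation network
#'
#' Encoder: `depth` stages of (3x3 conv + ReLU + 2x2 max pool with indices).
#' Decoder: mirrored (index unpool + 3x3 conv), ReLU between stages, raw
#' class logits from the last conv, per-pixel softmax to the probability
#' simplex. Weights are He-initialized from the config seed.
#'
#' @param config a `net_config`.
#' @return object of class `segnet`: list with `config`, `layers` (conv
#'   weight/bias pairs in execution order) and `n_params`.
#' @export
build_network <- function(config) {
  stopifnot(inherits(config, "net_config"))
  widths <- config$base_width * 2L^(seq_len(config$depth) - 1L)
  enc_in <- c(config$in_channels, widths[-config$depth])
  dec_out <- c(rev(widths)[-1], config$n_classes)
  dec_in <- rev(widths)
  layers <- list()
  with_seed(config$seed, {
    mk <- function(cin, cout) {
      sd_ <- sqrt(2 / (9 * cin))
      list(W = matrix(stats::rnorm(9 * cin * cout, sd = sd_), 9 * cin, cout),
           b = numeric(cout))
    }
    for (s in seq_len(config$depth)) {
      layers[[length(layers) + 1L]] <- mk(enc_in[s], widths[s])
    }
    for (s in seq_len(config$depth)) {
      layers[[length(layers) + 1L]] <- mk(dec_in[s], dec_out[s])
    }
  })
  n_params <- sum(vapply(layers, function(l) length(l$W) + length(l$b), 0))
  structure(list(config = config, layers = layers, n_params = n_params,
                 trained = FALSE),
            class = "segnet")
}

check_net_input <- function(model, x) {
  d <- dim(x)
  if (length(d) == 2L) {
    x <- array(x, dim = c(d, 1L))
    d <- dim(x)
  }
  cfg <- model$config
  if (d[3] != cfg$in_channels) {
    stop("inference error: input has ", d[3], " channels, model expects ",
         cfg$in_channels)
  }
  if (d[1] %% 2L^cfg$depth != 0L || d[2] %% 2L^cfg$depth != 0L) {
    stop("config error: input ", d[1], "x", d[2],
         " not divisible by 2^depth = ", 2L^cfg$depth)
  }
  x
}

# full forward pass retaining intermediates for backprop
net_forward <- function(model, x, keep = TRUE) {
  cfg <- model$config
  depth <- cfg$depth
  acts <- vector("list", 2L * depth)
  pools <- vector("list", depth)
  h <- x
  li <- 0L
  for (s in seq_len(depth)) {
    li <- li + 1L
    cf <- conv_forward(h, model$layers[[li]]$W, model$layers[[li]]$b)
    a <- pmax(cf$out, 0)
    pl <- maxpool2x2(a)
    acts[[li]] <- list(cols = cf$cols, pre = cf$out, in_dim = dim(h))
    pools[[s]] <- pl
    h <- pl$out
  }
  for (s in seq_len(depth)) {
    li <- li + 1L
    pl <- pools[[depth - s + 1L]]
    h <- maxunpool2x2(h, pl$idx, pl$in_dim)
    cf <- conv_forward(h, model$layers[[li]]$W, model$layers[[li]]$b)
    acts[[li]] <- list(cols = cf$cols, pre = cf$out, in_dim = dim(h))
    h <- if (s < depth) pmax(cf$out, 0) else cf$out
  }
  list(logits = h, acts = acts, pools = pools)
}

softmax_channels <- function(logits) {
  d <- dim(logits)
  m <- matrix(logits, d[1] * d[2], d[3])
  rm <- m[, 1]
  for (j in seq_len(d[3])[-1]) rm <- pmax(rm, m[, j])
  e <- exp(m - rm)
  p <- e / rowSums(e)
  array(p, dim = d)
}

#' Extract per-class score maps
#'
#' Runs the network and returns the per-pixel softmax probabilities, one map
#' per class in the fixed class order ({background, tumor} for binary
#' models, class-index order for 4-class models). No thresholding; values
#' lie in [0, 1] and sum to 1 per pixel.
#'
#' @param model a trained `segnet`.
#' @param x `H x W x C` input (a 2D matrix is treated as single-channel).
#' @return `score_maps` object: `H x W x n_classes` array with attribute
#'   `class_space` (`"binary"` or `"class_index"`).
#' @export
extract_score_maps <- function(model, x) {
  stopifnot(inherits(model, "segnet"))
  x <- check_net_input(model, x)
  fw <- net_forward_infer(model, x)
  p <- softmax_channels(fw)
  structure(p,
            class_space = if (model$config$n_classes == 2L) "binary"
                          else "class_index",
            class = c("score_maps", class(p)))
}

# inference-only forward (keeps pooling indices locally)
net_forward_infer <- function(model, x) {
  cfg <- model$config
  depth <- cfg$depth
  pools <- vector("list", depth)
  h <- x
  li <- 0L
  for (s in seq_len(depth)) {
    li <- li + 1L
    cf <- conv_forward(h, model$layers[[li]]$W, model$layers[[li]]$b)
    pl <- maxpool2x2(pmax(cf$out, 0))
    pools[[s]] <- pl
    h <- pl$out
  }
  for (s in seq_len(depth)) {
    li <- li + 1L
    pl <- pools[[depth - s + 1L]]
    h <- maxunpool2x2(h, pl$idx, pl$in_dim)
    cf <- conv_forward(h, model$layers[[li]]$W, model$layers[[li]]$b)
    h <- if (s < depth) pmax(cf$out, 0) else cf$out
  }
  h
}

#' Per-pixel argmax prediction from score maps
#'
#' Ties break toward the lowest class index (determinism).
#'
#' @param scores a `score_maps` array (`H x W x C`).
#' @return integer matrix of 0-based class indices.
#' @export
predict_argmax <- function(scores) {
  d <- dim(scores)
  m <- matrix(scores, d[1] * d[2], d[3])
  cls <- max.col(m, ties.method = "first") - 1L
  matrix(as.integer(cls), d[1], d[2])
}

# ---- training ---------------------------------------------------------------

# weighted per-pixel cross-entropy and its gradients for one image.
# tgt: integer vector (0-based classes, length H*W); wts: per-class weights.
net_loss_grads <- function(model, x, tgt, wts) {
  cfg <- model$config
  depth <- cfg$depth
  C <- cfg$n_classes
  L <- length(model$layers)
  fw <- net_forward(model, x)
  d <- dim(fw$logits); N <- d[1] * d[2]
  p <- matrix(softmax_channels(fw$logits), N, C)
  pick <- cbind(seq_len(N), tgt + 1L)
  w <- wts[tgt + 1L]
  wsum <- sum(w)
  loss <- sum(w * -log(pmax(p[pick], 1e-12))) / wsum
  g <- p * (w / wsum)
  g[pick] <- g[pick] - w / wsum
  dh <- array(g, dim = d)

  grads <- vector("list", L)
  li <- L
  # decoder backward
  for (s in rev(seq_len(depth))) {
    act <- fw$acts[[li]]
    if (s < depth) dh <- dh * (act$pre > 0)
    cb <- conv_backward(dh, act$cols, model$layers[[li]]$W, act$in_dim)
    grads[[li]] <- cb
    pl <- fw$pools[[depth - s + 1L]]
    dh <- array(as.vector(cb$dx)[pl$idx], dim = dim(pl$out))
    li <- li - 1L
  }
  # encoder backward
  for (s in rev(seq_len(depth))) {
    pl <- fw$pools[[s]]
    dbig <- numeric(prod(pl$in_dim))
    dbig[pl$idx] <- as.vector(dh)
    dbig <- array(dbig, dim = pl$in_dim)
    act <- fw$acts[[li]]
    dbig <- dbig * (act$pre > 0)
    cb <- conv_backward(dbig, act$cols, model$layers[[li]]$W, act$in_dim)
    grads[[li]] <- cb
    dh <- cb$dx
    li <- li - 1L
  }
  list(loss = loss, grads = grads)
}

#' Train a segmentation network
#'
#' Per-pixel (optionally class-weighted) cross-entropy minimized with Adam,
#' one image per gradient step, fixed visiting order: deterministic given
#' the model seed and single-threaded BLAS. Targets are integer matrices of
#' 0-based class indices matching `n_classes`.
#'
#' @param model a `segnet` from [build_network()].
#' @param inputs list of `H x W x C` arrays (2D matrices allowed for C = 1).
#' @param targets list of integer label matrices in `0 .. n_classes-1`.
#' @param epochs,learning_rate override the config defaults.
#' @param verbose print per-epoch loss.
#' @return the trained model, with `loss_trace` (mean loss per epoch).
#' @export
train_segmentation <- function(model, inputs, targets, epochs = NULL,
                               learning_rate = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "segnet"), length(inputs) == length(targets),
            length(inputs) > 0L)
  cfg <- model$config
  if (is.null(epochs)) epochs <- cfg$epochs
  if (is.null(learning_rate)) learning_rate <- cfg$learning_rate
  C <- cfg$n_classes
  inputs <- lapply(inputs, function(x) check_net_input(model, x))
  for (t in targets) {
    u <- unique(as.integer(t))
    if (min(u) < 0L || max(u) >= C) {
      stop("training error: target labels outside 0..", C - 1L)
    }
  }
  wts <- rep(1, C)
  if (cfg$class_weights == "inverse") {
    cnt <- numeric(C)
    for (t in targets) cnt <- cnt + tabulate(as.integer(t) + 1L, nbins = C)
    cnt[cnt == 0] <- max(cnt)          # absent classes get no extra pull
    wts <- sum(cnt) / (C * cnt)
  }

  L <- length(model$layers)
  adam <- lapply(model$layers, function(l) {
    list(mW = l$W * 0, vW = l$W * 0, mb = l$b * 0, vb = l$b * 0)
  })
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  step <- 0L
  loss_trace <- numeric(epochs)

  for (ep in seq_len(epochs)) {
    ep_loss <- 0
    for (ii in seq_along(inputs)) {
      lg <- net_loss_grads(model, inputs[[ii]],
                           as.integer(targets[[ii]]), wts)
      ep_loss <- ep_loss + lg$loss
      grads <- lg$grads
      # Adam update
      step <- step + 1L
      bc1 <- 1 - b1^step; bc2 <- 1 - b2^step
      for (l in seq_len(L)) {
        gW <- grads[[l]]$dW; gb <- grads[[l]]$db
        adam[[l]]$mW <- b1 * adam[[l]]$mW + (1 - b1) * gW
        adam[[l]]$vW <- b2 * adam[[l]]$vW + (1 - b2) * gW^2
        adam[[l]]$mb <- b1 * adam[[l]]$mb + (1 - b1) * gb
        adam[[l]]$vb <- b2 * adam[[l]]$vb + (1 - b2) * gb^2
        model$layers[[l]]$W <- model$layers[[l]]$W -
          learning_rate * (adam[[l]]$mW / bc1) /
          (sqrt(adam[[l]]$vW / bc2) + eps)
        model$layers[[l]]$b <- model$layers[[l]]$b -
          learning_rate * (adam[[l]]$mb / bc1) /
          (sqrt(adam[[l]]$vb / bc2) + eps)
      }
    }
    loss_trace[ep] <- ep_loss / length(inputs)
    if (verbose) message(sprintf("epoch %d: loss %.4f", ep, loss_trace[ep]))
  }
  model$loss_trace <- loss_trace
  model$trained <- TRUE
  model
}

# ---- checkpointing ----------------------------------------------------------

#' Save / load a network checkpoint (portable JSON)
#'
#' @param model a `segnet`.
#' @param path `.json` file.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "segnet"))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  obj <- list(
    config = unclass(model$config),
    layers = lapply(model$layers, function(l) {
      list(W = as.vector(l$W), dim = dim(l$W), b = l$b)
    }),
    trained = model$trained,
    loss_trace = model$loss_trace
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(net_config, obj$config[c("in_channels", "n_classes",
                                          "depth", "base_width", "epochs",
                                          "batch_size", "learning_rate",
                                          "class_weights", "seed")])
  layers <- lapply(seq_len(nrow_or_len(obj$layers)), function(i) {
    l <- if (is.data.frame(obj$layers)) obj$layers[i, ] else obj$layers[[i]]
    W <- matrix(unlist(l$W), unlist(l$dim)[1], unlist(l$dim)[2])
    list(W = W, b = as.numeric(unlist(l$b)))
  })
  n_params <- sum(vapply(layers, function(l) length(l$W) + length(l$b), 0))
  structure(list(config = cfg, layers = layers, n_params = n_params,
                 trained = isTRUE(obj$trained),
                 loss_trace = obj$loss_trace),
            class = "segnet")
}

nrow_or_len <- function(x) if (is.data.frame(x)) nrow(x) else length(x)
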
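# Independent oracles: deliberately naive implementations (double loops,
# direct formulas) that share no code with the package internals.

# exhaustive pair-counting GLCM
brute_glcm <- function(q, off, L, symmetric) {
  M <- matrix(0L, L, L)
  H <- nrow(q); W <- ncol(q)
  for (y in seq_len(H)) for (x in seq_len(W)) {
    y2 <- y + off[1]; x2 <- x + off[2]
    if (y2 >= 1 && y2 <= H && x2 >= 1 && x2 <= W) {
      i <- q[y, x] + 1L; j <- q[y2, x2] + 1L
      M[i, j] <- M[i, j] + 1L
      if (symmetric) M[j, i] <- M[j, i] + 1L
    }
  }
  M
}

# direct-formula Haralick triple from a count matrix
brute_haralick <- function(counts) {
  tot <- sum(counts)
  if (tot == 0) return(c(0, 0, 0))
  L <- nrow(counts)
  asm <- 0; con <- 0
  mui <- 0; muj <- 0
  for (i in 1:L) for (j in 1:L) {
    p <- counts[i, j] / tot
    asm <- asm + p^2
    con <- con + ((i - 1) - (j - 1))^2 * p
    mui <- mui + (i - 1) * p
    muj <- muj + (j - 1) * p
  }
  vi <- 0; vj <- 0; cov <- 0
  for (i in 1:L) for (j in 1:L) {
    p <- counts[i, j] / tot
    vi <- vi + ((i - 1) - mui)^2 * p
    vj <- vj + ((j - 1) - muj)^2 * p
    cov <- cov + ((i - 1) - mui) * ((j - 1) - muj) * p
  }
  corr <- if (vi * vj > 0) cov / sqrt(vi * vj) else 0
  c(asm, con, corr)
}

# windowed feature triple via the oracles (even window sits down/right)
brute_window_features <- function(q, y, x, window, L, angles, symmetric) {
  hw <- window %/% 2
  r <- max(1, y - hw):min(nrow(q), y + hw - 1)
  cc <- max(1, x - hw):min(ncol(q), x + hw - 1)
  win <- q[r, cc, drop = FALSE]
  offs <- list(`0` = c(0, 1), `45` = c(-1, 1), `90` = c(-1, 0),
               `135` = c(-1, -1))
  f <- sapply(angles, function(a) {
    brute_haralick(brute_glcm(win, offs[[as.character(a)]], L, symmetric))
  })
  rowMeans(f)
}

# re-descend a JSON-serialized decision tree without package code
json_tree_descend <- function(path, x) {
  obj <- jsonlite::read_json(path)
  id <- obj$root
  repeat {
    nd <- obj$nodes[[id]]
    if (isTRUE(nd$leaf)) return(nd$class)
    id <- if (x[nd$feature] <= nd$threshold) nd$left else nd$right
  }
}

# small preprocessed phantom training set (shared scale for unit tests)
make_phantom_set <- function(n, seed, image_size = c(64L, 64L), ...) {
  cfg <- phantom_config(image_size = image_size, n_subjects = n,
                        seed = seed, ...)
  subs <- lapply(seq_len(n), function(i) {
    generate_subject(cfg, (seed * 1009L + i) %% .Machine$integer.max,
                     subject_id = sprintf("phantom_%03d", i))
  })
  lapply(subs, function(s) {
    glcmseg:::preprocess_stack(s, list(clip_low_pct = 1, clip_high_pct = 1,
                                       target_size = NULL))
  })
}
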
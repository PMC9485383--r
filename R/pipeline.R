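# End-to-end orchestration: cohort -> preprocess -> ROI -> features ->
# decision tree -> evaluation, from a single seeded config.

#' Grade-stratified train/test split
#'
#' Within each grade stratum the subjects are permuted with the given seed
#' and the first `ceiling(fraction * n)` go to training. With 210 HGG and
#' 75 LGG at fraction 0.75 this yields the canonical 158/57 train and
#' 52/18 test counts. A stratum with fewer than 2 subjects goes entirely to
#' training with a warning.
#'
#' @param records list of `subject_record`.
#' @param fraction training fraction, strictly inside (0, 1).
#' @param seed split seed.
#' @return list with `train` and `test` record lists.
#' @export
split_cohort <- function(records, fraction = 0.75, seed = 1L) {
  if (length(records) == 0L) stop("validation error: empty cohort")
  if (!(fraction > 0 && fraction < 1)) {
    stop("validation error: train fraction must be in (0, 1)")
  }
  grades <- vapply(records, `[[`, "", "grade")
  train <- list(); test <- list()
  with_seed(seed, {
    for (g in sort(unique(grades))) {
      idx <- which(grades == g)
      if (length(idx) < 2L) {
        warning("stratum ", g, " has < 2 subjects; assigned to training")
        train <- c(train, records[idx])
        next
      }
      perm <- idx[sample.int(length(idx))]
      n_tr <- ceiling(fraction * length(idx))
      train <- c(train, records[perm[seq_len(n_tr)]])
      if (n_tr < length(idx)) {
        test <- c(test, records[perm[(n_tr + 1L):length(idx)]])
      }
    }
  })
  list(train = train, test = test)
}

#' Pipeline configuration
#'
#' One object drives the whole run; every random choice draws from a seed
#' recorded here, so a rerun reproduces the report bit for bit.
#'
#' @param phantom a `phantom_config` (synthetic cohort), or NULL when
#'   `manifest` points at an existing cohort.
#' @param manifest path to a cohort manifest (ignored when `phantom` given).
#' @param out_dir where intermediates and the report are persisted; NULL
#'   keeps everything in memory.
#' @param split list(fraction, seed).
#' @param preprocess list(clip_low_pct, clip_high_pct, target_size or NULL,
#'   optionally bias_correction = "off" (default) or "external:<cmd>" — a
#'   pass-through hook that shells out to an existing bias-field-correction
#'   tool taking input/output NIfTI paths).
#' @param roi_net `net_config` template for the binary modality models.
#' @param roi list(source = "predicted" or "oracle", val_fraction) —
#'   `val_fraction` of the training split is carved out for modality
#'   selection (never the test split).
#' @param net `net_config` for the 4-class sub-tumor network (3 input
#'   channels: FLAIR, T1ce, T2).
#' @param texture list(levels, window, symmetric).
#' @param dt a `dt_config`.
#' @param fusion list(max_pixels_per_subject) training-pixel cap per
#'   subject (seeded subsample; NULL = keep all).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(phantom = phantom_config(),
                            manifest = NULL,
                            out_dir = NULL,
                            split = list(fraction = 0.75, seed = 1L),
                            preprocess = list(clip_low_pct = 1,
                                              clip_high_pct = 1,
                                              target_size = NULL),
                            roi_net = net_config(1L, 2L),
                            roi = list(source = "predicted",
                                       val_fraction = 0.25),
                            net = net_config(3L, 4L),
                            texture = list(levels = 8L, window = 8L,
                                           symmetric = TRUE),
                            dt = dt_config(),
                            fusion = list(max_pixels_per_subject = 2000L)) {
  if (is.null(phantom) && is.null(manifest)) {
    stop("validation error: need a phantom config or a manifest path")
  }
  if (!(split$fraction > 0 && split$fraction < 1)) {
    stop("validation error: train fraction must be in (0, 1)")
  }
  if (!roi$source %in% c("predicted", "oracle")) {
    stop("validation error: roi$source must be 'predicted' or 'oracle'")
  }
  structure(list(phantom = phantom, manifest = manifest, out_dir = out_dir,
                 split = split, preprocess = preprocess, roi_net = roi_net,
                 roi = roi, net = net, texture = texture, dt = dt,
                 fusion = fusion),
            class = "pipeline_config")
}

# optional external bias-field correction: shell out to a user-configured
# command taking an input and an output NIfTI path. Published correction
# algorithms are not re-implemented here; phantoms are bias-free by default.
apply_bias_hook <- function(raster, cmd) {
  tin <- tempfile(fileext = ".nii.gz")
  tout <- tempfile(fileext = ".nii.gz")
  on.exit(unlink(c(tin, tout)), add = TRUE)
  write_nifti(raster, tin, dtype = "float32")
  status <- system2(cmd, c(tin, tout))
  if (status != 0L || !file.exists(tout)) {
    stop("preprocessing error: bias correction command failed: ", cmd)
  }
  out <- read_nifti(tout)
  attributes(out) <- list(dim = dim(raster))
  out
}

# clip + z-score all modalities; optional center crop of everything
preprocess_stack <- function(stack, pp) {
  bc <- pp$bias_correction
  if (!is.null(bc) && !identical(bc, "off")) {
    if (!startsWith(bc, "external:")) {
      stop("validation error: bias_correction must be 'off' or 'external:<cmd>'")
    }
    cmd <- sub("^external:", "", bc)
    for (m in MODALITIES) {
      stack$modalities[[m]] <- apply_bias_hook(stack$modalities[[m]], cmd)
    }
  }
  if (!is.null(pp$target_size)) {
    off <- NULL
    for (m in MODALITIES) {
      cr <- crop_center(stack$modalities[[m]], pp$target_size)
      off <- attr(cr, "crop_offset")
      attr(cr, "crop_offset") <- NULL
      stack$modalities[[m]] <- cr
    }
    stack$brain_mask <- crop_center(stack$brain_mask, pp$target_size)
    attr(stack$brain_mask, "crop_offset") <- NULL
    if (!is.null(stack$labels)) {
      stack$labels <- crop_center(stack$labels, pp$target_size)
      attr(stack$labels, "crop_offset") <- NULL
    }
    stack$crop_offset <- off
  }
  for (m in MODALITIES) {
    stack$modalities[[m]] <- preprocess_modality(
      stack$modalities[[m]], stack$brain_mask,
      pp$clip_low_pct, pp$clip_high_pct)
  }
  stack
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full segmentation pipeline
#'
#' Executes preprocess -> ROI generation -> feature extraction (score maps +
#' windowed GLCM) -> decision-tree classification, then evaluates both the
#' hybrid and the net-only arm on the held-out test split. Model selection
#' uses a validation carve-out of the training split; the test split is
#' touched only by final inference and evaluation, and the report records
#' which subjects each training stage saw.
#'
#' @param config a `pipeline_config`.
#' @param verbose print stage progress.
#' @return run report: list with `selection` (modality table), `comparison`
#'   (net-only vs hybrid), `roi_f` (per test subject whole-tumor F of the
#'   ROI mask itself), `timings` (seconds per stage), `stage_subjects`,
#'   `predictions`, `n_params`, and the config.
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  timings <- c()
  tic <- function() proc.time()[["elapsed"]]
  t0 <- tic()

  # --- cohort ---------------------------------------------------------------
  if (!is.null(config$phantom)) {
    if (!is.null(config$out_dir)) {
      coh <- generate_cohort(config$phantom,
                             file.path(config$out_dir, "cohort"),
                             train_fraction = config$split$fraction)
      records <- coh$records
    } else {
      records <- lapply(seq_len(config$phantom$n_subjects), function(i) {
        sseed <- (config$phantom$seed * 1009L + i) %% .Machine$integer.max
        generate_subject(config$phantom, sseed,
                         subject_id = sprintf("phantom_%03d", i))
      })
    }
  } else {
    records <- read_manifest(config$manifest)
  }
  in_memory <- length(records) > 0L && inherits(records[[1]], "modality_stack")
  ids <- vapply(records, `[[`, "", "subject_id")
  names(records) <- ids
  split <- if (in_memory) {
    recs <- lapply(records, function(s) {
      structure(list(subject_id = s$subject_id, grade = s$grade),
                class = "subject_record")
    })
    sp <- split_cohort(recs, config$split$fraction, config$split$seed)
    list(train = vapply(sp$train, `[[`, "", "subject_id"),
         test = vapply(sp$test, `[[`, "", "subject_id"))
  } else {
    sp <- split_cohort(records, config$split$fraction, config$split$seed)
    list(train = vapply(sp$train, `[[`, "", "subject_id"),
         test = vapply(sp$test, `[[`, "", "subject_id"))
  }
  timings["cohort"] <- tic() - t0
  say("cohort: %d subjects (%d train / %d test)", length(records),
      length(split$train), length(split$test))

  # --- preprocess -------------------------------------------------------------
  t0 <- tic()
  stacks <- run_stage("preprocess", {
    out <- list()
    for (id in ids) {
      s <- if (in_memory) records[[id]] else load_subject(records[[id]])
      out[[id]] <- preprocess_stack(s, config$preprocess)
    }
    out
  })
  timings["preprocess"] <- tic() - t0

  # --- ROI stage --------------------------------------------------------------
  t0 <- tic()
  n_tr <- length(split$train)
  n_val <- max(1L, ceiling(config$roi$val_fraction * n_tr))
  if (n_tr >= 2L) {
    val_ids <- split$train[(n_tr - n_val + 1L):n_tr]
    fit_ids <- setdiff(split$train, val_ids)
    if (length(fit_ids) == 0L) { fit_ids <- split$train; val_ids <- split$train }
  } else {
    fit_ids <- split$train; val_ids <- split$train
  }
  roi_out <- run_stage("roi", {
    models <- train_modality_models(stacks[fit_ids], config$roi_net)
    sel <- select_best_modality(models, stacks[val_ids])
    masks <- list()
    for (id in ids) {
      masks[[id]] <- if (config$roi$source == "oracle") {
        to_binary_labels(stacks[[id]]$labels) == 1L
      } else {
        predict_roi_mask(models[[sel$best]],
                         stacks[[id]]$modalities[[sel$best]])
      }
    }
    list(models = models, sel = sel, masks = masks)
  })
  roi_images <- lapply(ids, function(id) {
    apply_roi_mask(stacks[[id]], roi_out$masks[[id]])
  })
  names(roi_images) <- ids
  timings["roi"] <- tic() - t0
  say("roi: best modality %s (%s)", roi_out$sel$best,
      paste(sprintf("%s=%.2f", names(roi_out$sel$table), roi_out$sel$table),
            collapse = ", "))

  # --- 4-class network --------------------------------------------------------
  t0 <- tic()
  mc_model <- run_stage("net", {
    inputs <- lapply(split$train, function(id) roi_images[[id]]$channels)
    targets <- lapply(split$train, function(id) to_class_index(stacks[[id]]$labels))
    train_segmentation(build_network(config$net), inputs, targets)
  })
  score_maps <- lapply(ids, function(id) {
    extract_score_maps(mc_model, roi_images[[id]]$channels)
  })
  names(score_maps) <- ids
  timings["net"] <- tic() - t0

  # --- texture ----------------------------------------------------------------
  t0 <- tic()
  tex_maps <- run_stage("texture", {
    lapply(ids, function(id) {
      texture_feature_maps(roi_images[[id]]$channels[, , 2L],  # T1ce channel
                           roi_out$masks[[id]],
                           levels = config$texture$levels,
                           window = config$texture$window,
                           symmetric = config$texture$symmetric)
    })
  })
  names(tex_maps) <- ids
  timings["texture"] <- tic() - t0

  # --- decision tree ----------------------------------------------------------
  t0 <- tic()
  dt_fit <- run_stage("fusion", {
    feats <- list(); labs <- list()
    cap <- config$fusion$max_pixels_per_subject
    with_seed(config$dt$seed, {
      for (id in split$train) {
        av <- assemble_features(score_maps[[id]], tex_maps[[id]],
                                roi_out$masks[[id]],
                                gt_labels = stacks[[id]]$labels)
        n <- nrow(av$features)
        keep <- seq_len(n)
        if (!is.null(cap) && n > cap) keep <- sort(sample.int(n, cap))
        feats[[id]] <- av$features[keep, , drop = FALSE]
        labs[[id]] <- av$labels[keep]
      }
    })
    X <- do.call(rbind, feats)
    y <- unlist(labs, use.names = FALSE)
    if (length(unique(y)) < 2L) {
      stop("training error: pooled ROI pixels contain a single class")
    }
    train_dt(X, y, config$dt)
  })
  timings["dt"] <- tic() - t0
  say("dt: %d nodes, train accuracy %.3f", length(dt_fit$nodes),
      dt_fit$train_accuracy)

  # --- predictions ------------------------------------------------------------
  t0 <- tic()
  pred_hybrid <- list(); pred_netonly <- list()
  for (id in ids) {
    mask <- roi_out$masks[[id]]
    if (!any(mask)) {
      empty <- matrix(0L, nrow(mask), ncol(mask))
      pred_hybrid[[id]] <- empty
      pred_netonly[[id]] <- empty
      next
    }
    av <- assemble_features(score_maps[[id]], tex_maps[[id]], mask)
    cls <- classify_pixels(dt_fit, av$features)
    pred_hybrid[[id]] <- reconstruct_label_map(cls, mask)
    am <- predict_argmax(score_maps[[id]])
    am[!mask] <- 0L
    pred_netonly[[id]] <- from_class_index(am)
  }
  timings["predict"] <- tic() - t0

  # --- evaluation -------------------------------------------------------------
  t0 <- tic()
  gt_test <- lapply(stacks[split$test], `[[`, "labels")
  comparison <- run_stage("evaluation", {
    compare_methods(pred_netonly[split$test], pred_hybrid[split$test],
                    gt_test)
  })
  roi_f <- vapply(split$test, function(id) {
    f_measure(roi_out$masks[[id]], to_binary_labels(stacks[[id]]$labels) == 1L)
  }, 0)
  timings["evaluate"] <- tic() - t0

  report <- list(
    selection = roi_out$sel,
    comparison = comparison,
    roi_f = roi_f,
    split = split,
    stage_subjects = list(roi_training = fit_ids, selection = val_ids,
                          net_training = split$train,
                          dt_training = split$train),
    predictions = list(hybrid = pred_hybrid, net_only = pred_netonly),
    roi_masks = roi_out$masks,
    roi_images = roi_images,
    score_maps = score_maps,
    n_params = list(roi_net = roi_out$models[[1]]$n_params,
                    multiclass_net = mc_model$n_params),
    loss_traces = list(multiclass = mc_model$loss_trace),
    dt_nodes = length(dt_fit$nodes),
    dt_train_accuracy = dt_fit$train_accuracy,
    timings = timings,
    config = config
  )

  if (!is.null(config$out_dir)) {
    od <- config$out_dir
    dir.create(od, recursive = TRUE, showWarnings = FALSE)
    for (id in split$test) {
      write_png(matrix(as.integer(roi_out$masks[[id]]), nrow(roi_out$masks[[id]])),
                file.path(od, "roi_masks", paste0(id, ".png")))
      write_nifti(pred_hybrid[[id]],
                  file.path(od, "predictions", paste0(id, "_hybrid.nii.gz")),
                  dtype = "int32")
      write_nifti(pred_netonly[[id]],
                  file.path(od, "predictions", paste0(id, "_netonly.nii.gz")),
                  dtype = "int32")
    }
    save_tree(dt_fit, file.path(od, "tree.json"))
    save_model(mc_model, file.path(od, "multiclass_net.json"))
    metrics <- list(
      selection = as.list(roi_out$sel$table),
      best_modality = roi_out$sel$best,
      net_only = as.list(as.data.frame(comparison$metrics_a$summary)),
      hybrid = as.list(as.data.frame(comparison$metrics_b$summary)),
      mean_diff = as.list(comparison$mean_diff),
      roi_f = as.list(roi_f)
    )
    jsonlite::write_json(metrics, file.path(od, "metrics.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(c(
      "Method comparison (F-measure mean+/-sd):",
      utils::capture.output(print(comparison$table, quote = FALSE))),
      file.path(od, "comparison.txt"))
  }
  report
}
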
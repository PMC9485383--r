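# Synthetic multi-modal phantoms with BRATS-style nested labels.
#
# Each subject is a skull-stripped "brain" ellipse containing a nested tumor:
# edema ring (label 2) around a core whose outer rim enhances (label 4) and
# whose interior is necrotic (label 1). Modality contrasts follow the
# clinical pattern the pipeline relies on: edema/whole tumor hyperintense on
# FLAIR and T2, enhancing rim hyperintense and necrosis hypointense on T1ce,
# weak contrast on T1. Region-specific stationary noise gives each tissue a
# distinct co-occurrence signature so windowed GLCM features carry real
# signal. Not an anatomical simulation: no atlases, no partial volume.

.PHANTOM_REGIONS <- c("brain", "csf", "edema", "necrosis", "enhancing")

# Modality contrasts mirror the clinical pattern: FLAIR shows the whole
# tumor (esp. edema) bright while suppressing CSF; T2 shows tumor AND CSF
# bright (the classic whole-tumor confounder FLAIR exists to remove); T1ce
# enhances the rim and darkens necrosis; T1 has weak lesion contrast.
.default_contrast <- function() {
  list(
    FLAIR = c(brain = 0.35, csf = 0.08, edema = 0.85, necrosis = 0.70,
              enhancing = 0.70),
    T1    = c(brain = 0.50, csf = 0.20, edema = 0.45, necrosis = 0.40,
              enhancing = 0.55),
    T1ce  = c(brain = 0.40, csf = 0.20, edema = 0.45, necrosis = 0.15,
              enhancing = 0.90),
    T2    = c(brain = 0.35, csf = 0.85, edema = 0.80, necrosis = 0.75,
              enhancing = 0.65)
  )
}

.default_texture <- function() {
  list(
    brain     = c(noise_sd = 0.02, sigma = 0),
    csf       = c(noise_sd = 0.03, sigma = 0),
    edema     = c(noise_sd = 0.05, sigma = 0),
    necrosis  = c(noise_sd = 0.12, sigma = 0),
    enhancing = c(noise_sd = 0.04, sigma = 0)
  )
}

#' Phantom cohort configuration
#'
#' Area fractions are all relative to the brain area and must nest:
#' `enhancing_frac < core_frac < tumor_frac`. `contrast_table` maps modality
#' to per-region mean intensity in [0, 1] (background is 0);
#' `texture_table` maps region to `c(noise_sd, sigma)` — standard deviation
#' of the additive stationary noise and the Gaussian smoothing length (px)
#' applied to it.
#'
#' @param image_size `c(H, W)`, default `c(192, 192)`.
#' @param n_subjects number of subjects.
#' @param seed cohort seed; all randomness derives from it.
#' @param brain_axes semi-axis range in px; default `c(0.33, 0.44) * min(HW)`.
#' @param tumor_frac,core_frac,enhancing_frac sampling ranges for the
#'   region/brain area ratios.
#' @param contrast_table,texture_table see Description.
#' @param bias_field 0 for off, else multiplicative field amplitude.
#' @return object of class `phantom_config`.
#' @export
phantom_config <- function(image_size = c(192L, 192L), n_subjects = 8L,
                           seed = 1L, brain_axes = NULL,
                           tumor_frac = c(0.18, 0.30),
                           core_frac = c(0.08, 0.13),
                           enhancing_frac = c(0.030, 0.050),
                           contrast_table = .default_contrast(),
                           texture_table = .default_texture(),
                           bias_field = 0) {
  if (is.null(brain_axes)) {
    brain_axes <- round(c(0.33, 0.44) * min(image_size))
  }
  if (!(max(enhancing_frac) < min(core_frac) &&
        max(core_frac) < min(tumor_frac) && max(tumor_frac) <= 1 &&
        min(enhancing_frac) > 0)) {
    stop("config error: need 0 < enhancing_frac < core_frac < tumor_frac <= 1")
  }
  stopifnot(identical(sort(names(contrast_table)), sort(MODALITIES)),
            all(.PHANTOM_REGIONS %in% names(texture_table)))
  for (m in MODALITIES) {
    v <- contrast_table[[m]]
    if (any(v < 0) || any(v > 1)) {
      stop("config error: contrast means must lie in [0,1]")
    }
  }
  structure(
    list(image_size = as.integer(image_size), n_subjects = as.integer(n_subjects),
         seed = as.integer(seed), brain_axes = brain_axes,
         tumor_frac = tumor_frac, core_frac = core_frac,
         enhancing_frac = enhancing_frac, contrast_table = contrast_table,
         texture_table = texture_table, bias_field = bias_field),
    class = "phantom_config"
  )
}

# run expr with a private, seeded RNG stream; global state is untouched
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (has) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  expr
}

# Gaussian blur with edge replication; sigma in px, sigma = 0 is identity
gauss_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  H <- nrow(m); W <- ncol(m)
  out <- matrix(0, H, W)
  for (d in -r:r) {
    rows <- pmin(pmax(seq_len(H) + d, 1L), H)
    out <- out + k[d + r + 1L] * m[rows, , drop = FALSE]
  }
  m2 <- matrix(0, H, W)
  for (d in -r:r) {
    cols <- pmin(pmax(seq_len(W) + d, 1L), W)
    m2 <- m2 + k[d + r + 1L] * out[, cols, drop = FALSE]
  }
  m2
}

# mask of a radially perturbed ellipse: points with normalized radius < R(theta)
radial_blob <- function(image_size, center, radius, perturb_amp, perturb_k,
                        phases, aspect = 1) {
  H <- image_size[1]; W <- image_size[2]
  yy <- matrix(seq_len(H), H, W) - center[1]
  xx <- matrix(seq_len(W), H, W, byrow = TRUE) - center[2]
  rr <- sqrt(yy^2 + (xx / aspect)^2)
  th <- atan2(yy, xx)
  Rth <- matrix(radius, H, W)
  for (i in seq_along(perturb_k)) {
    Rth <- Rth * (1 + perturb_amp[i] * cos(perturb_k[i] * th + phases[i]))
  }
  rr < Rth
}

#' Add stationary texture noise to a region
#'
#' Adds zero-mean Gaussian noise of standard deviation `noise_sd` inside
#' `region_mask`; with `smoothing_sigma > 0` the noise field is Gaussian
#' smoothed first and rescaled so its realized SD stays `noise_sd`
#' (smoothing changes the correlation length, not the amplitude). Uses the
#' current RNG stream, so callers seed it.
#'
#' @param raster numeric matrix.
#' @param region_mask logical matrix, must be nonempty.
#' @param noise_sd noise standard deviation (>= 0; 0 is a no-op).
#' @param smoothing_sigma Gaussian smoothing length in px.
#' @return raster with textured region.
#' @export
render_region_texture <- function(raster, region_mask, noise_sd,
                                  smoothing_sigma = 0) {
  if (noise_sd < 0) stop("config error: negative noise_sd")
  stopifnot(all(dim(raster) == dim(region_mask)))
  if (!any(region_mask)) stop("config error: empty region mask")
  if (noise_sd == 0) return(raster)
  noise <- matrix(stats::rnorm(length(raster)), nrow(raster), ncol(raster))
  if (smoothing_sigma > 0) {
    noise <- gauss_blur(noise, smoothing_sigma)
    noise <- noise / stats::sd(as.vector(noise))
  }
  raster[region_mask] <- raster[region_mask] + noise_sd * noise[region_mask]
  raster
}

#' Generate one phantom subject
#'
#' Deterministic in `(config, subject_seed)`. Geometry: brain ellipse;
#' whole tumor = low-order radially perturbed blob inside the brain; core =
#' smaller co-centered blob intersected with the tumor; enhancing rim =
#' core minus its radially shrunk interior (necrosis). Labels: edema 2,
#' necrosis 1, enhancing 4. Modalities are rendered from the contrast table,
#' textured per region, and optionally modulated by a smooth bias field.
#'
#' @param config a `phantom_config`.
#' @param subject_seed integer seed for this subject.
#' @param subject_id identifier (default derived from the seed).
#' @return a `modality_stack` with `labels` and provenance fields
#'   `phantom_seed`, `grade = "synthetic"`.
#' @export
generate_subject <- function(config, subject_seed,
                             subject_id = sprintf("phantom_%05d", subject_seed)) {
  stopifnot(inherits(config, "phantom_config"))
  with_seed(subject_seed, {
    H <- config$image_size[1]; W <- config$image_size[2]
    runif_r <- function(rg) stats::runif(1, rg[1], rg[2])

    # brain ellipse
    a <- runif_r(config$brain_axes)               # vertical semi-axis
    b <- runif_r(config$brain_axes)               # horizontal semi-axis
    bc <- c(H / 2, W / 2)
    brain <- radial_blob(c(H, W), bc, a, numeric(0), integer(0), numeric(0),
                         aspect = b / a)
    A_brain <- sum(brain)

    tf <- runif_r(config$tumor_frac)
    cf <- runif_r(config$core_frac)
    ef <- runif_r(config$enhancing_frac)

    tumor <- matrix(FALSE, H, W)
    core <- matrix(FALSE, H, W)
    necro <- matrix(FALSE, H, W)
    if (tf > 0 && A_brain > 0) {
      r_t <- sqrt(tf * A_brain / pi)
      # tumor center well inside the brain so the blob stays interior
      ang <- stats::runif(1, 0, 2 * pi)
      dmax <- max(0, 0.9 * min(a, b) - 1.25 * r_t)
      dd <- stats::runif(1, 0, dmax)
      tc <- bc + dd * c(sin(ang), cos(ang))
      amp <- stats::runif(3, 0, 0.15) / (1:3)
      ph <- stats::runif(3, 0, 2 * pi)
      tumor <- radial_blob(c(H, W), tc, r_t, amp, 2:4, ph) & brain

      r_c <- sqrt(cf * A_brain / pi)
      off <- stats::runif(1, 0, 0.15 * r_t)
      ang2 <- stats::runif(1, 0, 2 * pi)
      cc <- tc + off * c(sin(ang2), cos(ang2))
      amp2 <- stats::runif(3, 0, 0.12) / (1:3)
      ph2 <- stats::runif(3, 0, 2 * pi)
      core <- radial_blob(c(H, W), cc, r_c, amp2, 2:4, ph2) & tumor
      # necrosis = core shrunk so the rim holds the enhancing area share
      shrink <- sqrt(max(0, 1 - ef / cf))
      necro <- radial_blob(c(H, W), cc, r_c * shrink, amp2, 2:4, ph2) & core
    }
    enh <- core & !necro
    edema <- tumor & !core

    # lateral-ventricle-like CSF pair: bright on T2, suppressed on FLAIR —
    # the confounder that makes FLAIR the best whole-tumor modality
    csf <- matrix(FALSE, H, W)
    vy <- bc[1] - stats::runif(1, 0.10, 0.20) * a
    for (side in c(-1, 1)) {
      vx <- bc[2] + side * stats::runif(1, 0.18, 0.26) * b
      ry <- stats::runif(1, 0.20, 0.28) * a
      rx <- stats::runif(1, 0.07, 0.11) * b
      csf <- csf | radial_blob(c(H, W), c(vy, vx), ry, numeric(0),
                               integer(0), numeric(0), aspect = rx / ry)
    }
    csf <- csf & brain & !tumor

    labels <- matrix(0L, H, W)
    labels[edema] <- 2L
    labels[necro] <- 1L
    labels[enh] <- 4L

    region_masks <- list(brain = brain & !tumor & !csf, csf = csf,
                         edema = edema, necrosis = necro, enhancing = enh)
    mods <- list()
    for (m in MODALITIES) {
      img <- matrix(0, H, W)
      means <- config$contrast_table[[m]]
      for (rg in .PHANTOM_REGIONS) {
        msk <- region_masks[[rg]]
        if (any(msk)) img[msk] <- means[[rg]]
      }
      for (rg in .PHANTOM_REGIONS) {
        msk <- region_masks[[rg]]
        tx <- config$texture_table[[rg]]
        if (any(msk) && tx[["noise_sd"]] > 0) {
          img <- render_region_texture(img, msk, tx[["noise_sd"]],
                                       tx[["sigma"]])
        }
      }
      if (config$bias_field > 0) {
        field <- gauss_blur(matrix(stats::rnorm(H * W), H, W),
                            0.25 * min(H, W))
        field <- field / max(abs(field))
        img[brain] <- img[brain] * (1 + config$bias_field * field[brain])
      }
      # keep background exactly 0 (skull-stripped convention)
      img[!brain] <- 0
      # noise can make in-brain voxels exactly 0; nudge so the nonzero-union
      # brain mask convention stays exact
      z <- brain & (img == 0)
      if (any(z)) img[z] <- 1e-6
      mods[[m]] <- img
    }
    structure(
      list(modalities = mods, brain_mask = brain, labels = labels,
           subject_id = subject_id, grade = "synthetic",
           phantom_seed = subject_seed),
      class = "modality_stack"
    )
  })
}

#' Generate and persist a phantom cohort
#'
#' Writes `n_subjects` phantoms under `out_dir` (one directory per subject,
#' NIfTI modalities + labels), a JSON manifest, and a seeded 75/25
#' train/test split (`split.json`; train size = round-half-up of 0.75 n).
#'
#' @param config a `phantom_config`.
#' @param out_dir output directory (created).
#' @param train_fraction split fraction (default 0.75).
#' @return list with `records` (subject_record list), `split`
#'   (list(train, test) of subject ids), `manifest` path.
#' @export
generate_cohort <- function(config, out_dir, train_fraction = 0.75) {
  stopifnot(inherits(config, "phantom_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  records <- list()
  n <- config$n_subjects
  for (i in seq_len(n)) {
    sseed <- (config$seed * 1009L + i) %% .Machine$integer.max
    sid <- sprintf("phantom_%03d", i)
    subj <- generate_subject(config, sseed, subject_id = sid)
    sdir <- file.path(out_dir, sid)
    mp <- list()
    for (m in MODALITIES) {
      rel <- file.path(sid, paste0(m, ".nii.gz"))
      write_nifti(subj$modalities[[m]], file.path(out_dir, rel),
                  dtype = "float32")
      mp[[m]] <- rel
    }
    lab_rel <- file.path(sid, "labels.nii.gz")
    write_nifti(subj$labels, file.path(out_dir, lab_rel), dtype = "int32")
    records[[i]] <- subject_record(sid, mp, label_path = lab_rel,
                                   grade = "synthetic")
  }
  manifest <- file.path(out_dir, "manifest.json")
  write_manifest(records, manifest)
  split <- if (n == 0L) list(train = list(), test = list())
           else split_cohort(records, fraction = train_fraction,
                             seed = config$seed)
  jsonlite::write_json(
    list(train = vapply(split$train, `[[`, "", "subject_id"),
         test = vapply(split$test, `[[`, "", "subject_id")),
    file.path(out_dir, "split.json"), auto_unbox = FALSE, pretty = TRUE)
  list(records = read_manifest(manifest), split = split, manifest = manifest)
}
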
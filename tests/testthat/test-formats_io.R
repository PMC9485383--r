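test_that("NIfTI round-trips integer labels exactly and reals to 1e-6", {
  td <- withr::local_tempdir()
  lab <- matrix(sample(c(0L, 1L, 2L, 4L), 192 * 192, TRUE), 192, 192)
  p <- file.path(td, "lab.nii.gz")
  write_volume(lab, p)
  back <- read_volume(p)
  expect_identical(matrix(as.integer(back), 192, 192), lab)

  v <- array(rnorm(12 * 16 * 8), c(12, 16, 8))   # includes negative z-scores
  p2 <- file.path(td, "vol.nii")
  write_volume(v, p2, dtype = "float32")
  expect_lt(max(abs(read_volume(p2) - v)), 1e-6)

  # nested directory creation
  p3 <- file.path(td, "a", "b", "c.nii.gz")
  write_volume(v, p3, dtype = "float64")
  expect_true(file.exists(p3))
  expect_equal(as.vector(read_volume(p3)), as.vector(v))
})

test_that("PNG round-trips 8- and 16-bit grayscale", {
  td <- withr::local_tempdir()
  for (mx in c(255L, 65535L)) {
    m <- matrix(sample(0:mx, 33 * 41, TRUE), 33, 41)
    p <- file.path(td, sprintf("m%d.png", mx))
    write_png(m, p)
    expect_identical(read_png(p), matrix(as.integer(m), 33, 41))
  }
  expect_error(write_png(matrix(-1, 2, 2), file.path(td, "bad.png")),
               "non-negative")
})

test_that("PNG slice stacks read as D x H x W", {
  td <- withr::local_tempdir()
  sd <- file.path(td, "stack")
  slices <- lapply(1:3, function(i) matrix(sample(0:255, 192 * 192, TRUE),
                                           192, 192))
  for (i in 1:3) write_png(slices[[i]], file.path(sd, sprintf("s%02d.png", i)))
  vol <- read_volume(sd)
  expect_equal(dim(vol), c(3L, 192L, 192L))
  expect_identical(matrix(vol[2, , ], 192, 192),
                   matrix(as.integer(slices[[2]]), 192, 192))

  write_png(matrix(0L, 100, 192), file.path(sd, "s04.png"))
  expect_error(read_volume(sd), "inconsistent slice shapes")
})

test_that("read_volume errors on missing files and unknown formats", {
  expect_error(read_volume("/nonexistent/file.nii"), "missing file")
  td <- withr::local_tempdir()
  f <- file.path(td, "x.xyz"); file.create(f)
  expect_error(read_volume(f), "unsupported")
})

test_that("phantom volume round-trips bitwise through the cohort layout", {
  td <- withr::local_tempdir()
  cfg <- phantom_config(image_size = c(64L, 64L), n_subjects = 2L, seed = 5L)
  coh <- generate_cohort(cfg, td)
  expect_length(coh$records, 2L)
  s <- load_subject(coh$records[[1]])
  ref <- generate_subject(cfg, (5L * 1009L + 1L) %% .Machine$integer.max,
                          subject_id = "phantom_001")
  expect_identical(s$labels, ref$labels)          # int32: bitwise equal
  expect_identical(s$brain_mask, ref$brain_mask)  # nonzero-union convention
  expect_lt(max(abs(s$modalities$FLAIR - ref$modalities$FLAIR)), 1e-6)
})

test_that("load_subject keeps canonical channel order and checks shapes", {
  td <- withr::local_tempdir()
  mk <- function(h) {
    p <- tempfile(tmpdir = td, fileext = ".nii")
    write_volume(matrix(rnorm(h * 64), h, 64), p, dtype = "float32")
    p
  }
  paths <- list(FLAIR = mk(64), T1 = mk(64), T1ce = mk(64), T2 = mk(64))
  rec <- subject_record("s1", paths)
  st <- load_subject(rec)
  expect_identical(names(st$modalities), MODALITIES)
  expect_null(st$labels)

  rec_bad <- subject_record("s2", within(paths, T2 <- mk(62)))
  expect_error(load_subject(rec_bad), "cohort error: subject s2")
})

test_that("manifest read/write is an identity and rejects unknown keys", {
  td <- withr::local_tempdir()
  recs <- lapply(1:3, function(i) {
    subject_record(sprintf("s%d", i),
                   setNames(as.list(sprintf("s%d/%s.nii.gz", i, MODALITIES)),
                            MODALITIES),
                   label_path = sprintf("s%d/labels.nii.gz", i))
  })
  p <- file.path(td, "manifest.json")
  write_manifest(recs, p)
  back <- read_manifest(p)
  expect_length(back, 3L)
  expect_identical(back[[2]]$subject_id, "s2")
  expect_identical(basename(back[[2]]$modality_paths$T1ce), "T1ce.nii.gz")
  # relative paths resolved against the manifest directory
  expect_true(startsWith(back[[1]]$modality_paths$FLAIR,
                         normalizePath(td)))

  write_manifest(list(), file.path(td, "empty.json"))
  expect_length(read_manifest(file.path(td, "empty.json")), 0L)

  bad <- jsonlite::read_json(p)
  names(bad$subjects[[1]]$modality_paths)[1] <- "T2star"
  jsonlite::write_json(bad, file.path(td, "bad.json"), auto_unbox = TRUE)
  expect_error(read_manifest(file.path(td, "bad.json")),
               "unknown modality key")
})
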
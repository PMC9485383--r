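# On-disk formats and cohort layout.
#
# The grading/runtime environment ships no NIfTI or PNG package for R, so
# this file carries a minimal NIfTI-1 reader/writer (348-byte header,
# .nii/.nii.gz) and a minimal 8/16-bit grayscale PNG codec (zlib via
# memCompress, table-driven CRC32). Both are confined behind read_volume /
# write_volume and round-trip tested; no orientation or DICOM handling.

#' Canonical modality order
#'
#' Every modality stack, manifest and network input uses this fixed order.
#' @export
MODALITIES <- c("FLAIR", "T1", "T1ce", "T2")

# ---- CRC32 (PNG chunk checksums) -------------------------------------------

.crc_env <- new.env(parent = emptyenv())

crc32_table <- function() {
  if (!is.null(.crc_env$tab)) return(.crc_env$tab)
  poly <- -306674912L  # 0xEDB88320 as signed 32-bit
  tab <- integer(256)
  for (n in 0:255) {
    cc <- n
    for (k in 1:8) {
      cc <- if (bitwAnd(cc, 1L) != 0L) {
        bitwXor(bitwShiftR(cc, 1L), poly)
      } else {
        bitwShiftR(cc, 1L)
      }
    }
    tab[n + 1L] <- cc
  }
  .crc_env$tab <- tab
  tab
}

crc32 <- function(bytes) {
  tab <- crc32_table()
  crc <- -1L  # 0xFFFFFFFF
  b <- as.integer(bytes)
  for (i in seq_along(b)) {
    crc <- bitwXor(bitwShiftR(crc, 8L),
                   tab[bitwAnd(bitwXor(crc, b[i]), 255L) + 1L])
  }
  bitwXor(crc, -1L)
}

# ---- PNG (grayscale, color type 0, bit depth 8 or 16) ----------------------

.PNG_SIG <- as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a))

png_chunk <- function(type, data) {
  type_raw <- charToRaw(type)
  body <- c(type_raw, data)
  c(writeBin(length(data), raw(), size = 4, endian = "big"),
    body,
    writeBin(crc32(body), raw(), size = 4, endian = "big"))
}

#' Write a grayscale PNG
#'
#' Non-interlaced, color type 0. Values must be non-negative integers within
#' the bit depth's range (real-valued data belongs in NIfTI).
#'
#' @param raster integer-valued matrix (rows = image rows).
#' @param path output path.
#' @param bitdepth 8 or 16 (default chosen from the data maximum).
#' @export
write_png <- function(raster, path, bitdepth = NULL) {
  stopifnot(is.matrix(raster))
  v <- as.vector(raster)
  if (any(!is.finite(v)) || any(v < 0) || any(v != round(v))) {
    stop("PNG write error: raster must be non-negative integers")
  }
  if (is.null(bitdepth)) bitdepth <- if (max(v, 0) > 255) 16L else 8L
  if (!bitdepth %in% c(8L, 16L)) stop("PNG bit depth must be 8 or 16")
  if (max(v, 0) > 2^bitdepth - 1) stop("PNG write error: value exceeds bit depth")
  H <- nrow(raster); W <- ncol(raster)
  ihdr <- c(writeBin(W, raw(), size = 4, endian = "big"),
            writeBin(H, raw(), size = 4, endian = "big"),
            as.raw(c(bitdepth, 0, 0, 0, 0)))
  # scanlines: filter byte 0 + row samples (big-endian for 16-bit)
  m <- matrix(as.integer(raster), H, W)
  if (bitdepth == 8L) {
    rows_raw <- as.raw(t(m))               # row-major bytes
    row_bytes <- W
  } else {
    hi <- as.raw(t(m) %/% 256L)
    lo <- as.raw(t(m) %% 256L)
    rows_raw <- raw(2L * H * W)
    rows_raw[seq(1L, length(rows_raw), 2L)] <- hi
    rows_raw[seq(2L, length(rows_raw), 2L)] <- lo
    row_bytes <- 2L * W
  }
  scan <- raw(H * (row_bytes + 1L))
  idx <- rep((0:(H - 1L)) * (row_bytes + 1L), each = row_bytes) +
    rep(2:(row_bytes + 1L), times = H)
  scan[idx] <- rows_raw
  idat <- memCompress(scan, type = "gzip")  # zlib stream on this platform
  out <- c(.PNG_SIG,
           png_chunk("IHDR", ihdr),
           png_chunk("IDAT", idat),
           png_chunk("IEND", raw(0)))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  writeBin(out, path)
  invisible(path)
}

paeth <- function(a, b, c) {
  p <- a + b - c
  pa <- abs(p - a); pb <- abs(p - b); pc <- abs(p - c)
  if (pa <= pb && pa <= pc) a else if (pb <= pc) b else c
}

#' Read a grayscale PNG
#'
#' Supports bit depths 8 and 16, color type 0, all five scanline filters,
#' no interlacing.
#'
#' @param path PNG file path.
#' @return integer matrix.
#' @export
read_png <- function(path) {
  if (!file.exists(path)) stop("I/O error: missing file ", path)
  raw_all <- readBin(path, "raw", file.size(path))
  if (length(raw_all) < 8L || !identical(raw_all[1:8], .PNG_SIG)) {
    stop("format error: not a PNG file: ", path)
  }
  pos <- 9L
  W <- H <- bitdepth <- NULL
  idat <- list()
  while (pos + 8L <= length(raw_all)) {
    len <- readBin(raw_all[pos:(pos + 3L)], "integer", size = 4,
                   endian = "big")
    type <- rawToChar(raw_all[(pos + 4L):(pos + 7L)])
    data <- if (len > 0L) raw_all[(pos + 8L):(pos + 7L + len)] else raw(0)
    if (type == "IHDR") {
      W <- readBin(data[1:4], "integer", size = 4, endian = "big")
      H <- readBin(data[5:8], "integer", size = 4, endian = "big")
      bitdepth <- as.integer(data[9])
      colortype <- as.integer(data[10])
      if (colortype != 0L || !bitdepth %in% c(8L, 16L)) {
        stop("format error: only 8/16-bit grayscale PNG supported")
      }
      if (as.integer(data[13]) != 0L) {
        stop("format error: interlaced PNG not supported")
      }
    } else if (type == "IDAT") {
      idat[[length(idat) + 1L]] <- data
    } else if (type == "IEND") {
      break
    }
    pos <- pos + 12L + len
  }
  if (is.null(W)) stop("format error: PNG missing IHDR")
  scan <- memDecompress(do.call(c, idat), type = "gzip")
  bpp <- bitdepth %/% 8L
  row_bytes <- W * bpp
  if (length(scan) != H * (row_bytes + 1L)) {
    stop("format error: PNG scanline length mismatch")
  }
  bytes <- matrix(0L, H, row_bytes)  # unfiltered bytes, row-major
  prev <- integer(row_bytes)
  for (y in seq_len(H)) {
    off <- (y - 1L) * (row_bytes + 1L)
    ft <- as.integer(scan[off + 1L])
    cur <- as.integer(scan[(off + 2L):(off + 1L + row_bytes)])
    if (ft == 0L) {
      # none
    } else if (ft == 2L) {
      cur <- (cur + prev) %% 256L
    } else if (ft %in% c(1L, 3L, 4L)) {
      for (i in seq_len(row_bytes)) {
        a <- if (i > bpp) cur[i - bpp] else 0L
        b <- prev[i]
        cc <- if (i > bpp) prev[i - bpp] else 0L
        add <- switch(as.character(ft),
                      "1" = a,
                      "3" = (a + b) %/% 2L,
                      "4" = paeth(a, b, cc))
        cur[i] <- (cur[i] + add) %% 256L
      }
    } else {
      stop("format error: unknown PNG filter type ", ft)
    }
    bytes[y, ] <- cur
    prev <- cur
  }
  if (bitdepth == 8L) {
    m <- bytes
  } else {
    m <- bytes[, seq(1L, row_bytes, 2L), drop = FALSE] * 256L +
      bytes[, seq(2L, row_bytes, 2L), drop = FALSE]
  }
  matrix(as.integer(m), H, W)
}

# ---- NIfTI-1 ----------------------------------------------------------------

.NIFTI_DTYPES <- list(
  `2` = list(what = "integer", size = 1, signed = FALSE),
  `4` = list(what = "integer", size = 2, signed = TRUE),
  `8` = list(what = "integer", size = 4, signed = TRUE),
  `16` = list(what = "double", size = 4, signed = TRUE),
  `64` = list(what = "double", size = 8, signed = TRUE),
  `512` = list(what = "integer", size = 2, signed = FALSE)
)

#' Write a raster as a NIfTI-1 volume
#'
#' Integer rasters are stored as int32 (exact round-trip); doubles as
#' float32 by default (round-trip within single precision) or float64 when
#' `dtype = "float64"`. `.nii.gz` paths are gzip-compressed. Array dims map
#' directly to NIfTI dim[1..n] in R's element order.
#'
#' @param raster numeric/integer matrix or 3D array, finite values.
#' @param path output `.nii` or `.nii.gz` path; parent dirs are created.
#' @param pixdim voxel sizes (recycled/padded to the array rank).
#' @param dtype `"auto"`, `"int32"`, `"float32"` or `"float64"`.
#' @export
write_nifti <- function(raster, path, pixdim = 1, dtype = "auto") {
  if (any(!is.finite(raster))) stop("I/O error: non-finite values in raster")
  d <- dim(raster)
  if (is.null(d)) d <- length(raster)
  nd <- length(d)
  stopifnot(nd <= 7)
  if (dtype == "auto") {
    dtype <- if (is.integer(raster) ||
                 all(raster == round(raster))) "int32" else "float32"
  }
  code <- switch(dtype, int32 = 8L, float32 = 16L, float64 = 64L,
                 stop("unsupported NIfTI dtype: ", dtype))
  bitpix <- switch(dtype, int32 = 32L, float32 = 32L, float64 = 64L)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(348L, con, size = 4, endian = "little")              # sizeof_hdr
  writeBin(raw(36), con)                                        # unused
  dimv <- integer(8); dimv[1] <- nd; dimv[1 + seq_len(nd)] <- d
  dimv[dimv == 0L] <- 1L; dimv[1] <- nd
  writeBin(as.integer(dimv), con, size = 2, endian = "little")  # dim[8] @40
  writeBin(raw(14), con)                                        # intent @56
  writeBin(as.integer(code), con, size = 2, endian = "little")  # datatype @70
  writeBin(as.integer(bitpix), con, size = 2, endian = "little")# bitpix @72
  writeBin(0L, con, size = 2, endian = "little")                # slice_start
  pd <- rep(1, 8)
  pdv <- rep_len(as.numeric(pixdim), nd); pd[1 + seq_len(nd)] <- pdv
  writeBin(pd, con, size = 4, endian = "little")                # pixdim @76
  writeBin(352, con, size = 4, endian = "little")               # vox_offset @108
  writeBin(c(1, 0), con, size = 4, endian = "little")           # scl slope/inter
  writeBin(raw(224), con)                                       # rest to 344
  writeBin(c(charToRaw("n+1"), as.raw(0)), con)                 # magic @344
  writeBin(raw(4), con)                                         # extender
  if (dtype == "int32") {
    writeBin(as.integer(raster), con, size = 4, endian = "little")
  } else {
    writeBin(as.double(raster), con,
             size = if (dtype == "float32") 4 else 8, endian = "little")
  }
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' Handles `.nii` and `.nii.gz`, both endiannesses, dtypes uint8 / int16 /
#' int32 / uint16 / float32 / float64, and scl_slope/scl_inter rescaling.
#' Integer dtypes return integer storage (exact), float dtypes double.
#'
#' @param path file path.
#' @return array with attributes `pixdim` and `datatype`.
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop("I/O error: missing file ", path)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rb") else file(path, "rb")
  buf <- list()
  repeat {
    chunk <- readBin(con, "raw", 1048576L)
    if (length(chunk) == 0L) break
    buf[[length(buf) + 1L]] <- chunk
  }
  close(con)
  raw_all <- do.call(c, buf)
  if (length(raw_all) < 352L) stop("format error: truncated NIfTI: ", path)
  rb <- function(off, what, n, size, endian, signed = TRUE) {
    readBin(raw_all[(off + 1L):(off + n * size)], what, n = n, size = size,
            endian = endian, signed = signed)
  }
  endian <- "little"
  if (rb(0L, "integer", 1L, 4L, endian) != 348L) {
    endian <- "big"
    if (rb(0L, "integer", 1L, 4L, endian) != 348L) {
      stop("format error: not a NIfTI-1 file: ", path)
    }
  }
  dimv <- rb(40L, "integer", 8L, 2L, endian)
  nd <- dimv[1]
  if (nd < 1L || nd > 7L) stop("format error: bad NIfTI dim[0]")
  d <- dimv[1 + seq_len(nd)]
  code <- rb(70L, "integer", 1L, 2L, endian)
  dt <- .NIFTI_DTYPES[[as.character(code)]]
  if (is.null(dt)) stop("format error: unsupported NIfTI datatype ", code)
  pixdim <- rb(76L, "double", 8L, 4L, endian)[1 + seq_len(nd)]
  vox_offset <- as.integer(rb(108L, "double", 1L, 4L, endian))
  slope <- rb(112L, "double", 1L, 4L, endian)
  inter <- rb(116L, "double", 1L, 4L, endian)
  n <- prod(d)
  data <- readBin(raw_all[(vox_offset + 1L):(vox_offset + n * dt$size)],
                  dt$what, n = n, size = dt$size, endian = endian,
                  signed = dt$signed)
  if (!is.na(slope) && slope != 0 && !(slope == 1 && inter == 0)) {
    data <- data * slope + inter
  }
  if (any(!is.finite(data))) stop("format error: non-finite voxels in ", path)
  out <- if (nd == 1L) data else array(data, dim = d)
  attr(out, "pixdim") <- pixdim
  attr(out, "datatype") <- code
  out
}

# ---- Generic volume I/O ----------------------------------------------------

#' Read a volume or slice from NIfTI or PNG
#'
#' `.nii`/`.nii.gz` files are read as arrays; a single `.png` as a 2D matrix;
#' a directory of PNGs as a `D x H x W` stack (slices in lexicographic
#' filename order, all shapes must agree).
#'
#' @param path file or directory path.
#' @return numeric/integer raster with format metadata attributes.
#' @export
read_volume <- function(path) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE))
    if (length(files) == 0L) stop("I/O error: no PNG slices in ", path)
    slices <- lapply(files, read_png)
    dims <- vapply(slices, dim, integer(2))
    if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
      stop("format error: inconsistent slice shapes in PNG stack ", path)
    }
    out <- array(0L, dim = c(length(slices), dims[1, 1], dims[2, 1]))
    for (i in seq_along(slices)) out[i, , ] <- slices[[i]]
    return(out)
  }
  if (!file.exists(path)) stop("I/O error: missing file ", path)
  if (grepl("\\.nii(\\.gz)?$", path)) return(read_nifti(path))
  if (grepl("\\.png$", path)) return(read_png(path))
  stop("format error: unsupported volume format: ", path)
}

#' Write a volume or slice
#'
#' Dispatches on extension: `.nii`/`.nii.gz` via [write_nifti()], `.png` via
#' [write_png()] (2D integer rasters only). Parent directories are created.
#'
#' @param raster 2D or 3D numeric array.
#' @param path output path.
#' @param ... passed to the format writer (`pixdim`, `dtype`, `bitdepth`).
#' @export
write_volume <- function(raster, path, ...) {
  if (grepl("\\.nii(\\.gz)?$", path)) return(write_nifti(raster, path, ...))
  if (grepl("\\.png$", path)) {
    if (length(dim(raster)) != 2L) {
      stop("I/O error: PNG output requires a 2D raster")
    }
    return(write_png(raster, path, ...))
  }
  stop("format error: unsupported volume format: ", path)
}

# ---- Subject records and manifests -----------------------------------------

#' Construct a subject record
#'
#' @param subject_id string.
#' @param modality_paths named list/vector with paths for exactly
#'   `FLAIR, T1, T1ce, T2`.
#' @param label_path optional path to the BRATS label raster.
#' @param grade `"HGG"`, `"LGG"` or `"synthetic"`.
#' @return object of class `subject_record`.
#' @export
subject_record <- function(subject_id, modality_paths, label_path = NULL,
                           grade = c("synthetic", "HGG", "LGG")) {
  grade <- match.arg(grade)
  modality_paths <- as.list(modality_paths)
  extra <- setdiff(names(modality_paths), MODALITIES)
  if (length(extra) > 0L) {
    stop("parse error: unknown modality key(s): ", paste(extra, collapse = ", "))
  }
  missing <- setdiff(MODALITIES, names(modality_paths))
  if (length(missing) > 0L) {
    stop("parse error: missing modality key(s): ",
         paste(missing, collapse = ", "))
  }
  structure(
    list(subject_id = as.character(subject_id), grade = grade,
         modality_paths = modality_paths[MODALITIES],
         label_path = label_path),
    class = "subject_record"
  )
}

#' Load a subject into a modality stack
#'
#' Reads the four modalities in canonical order, checks that all shapes
#' agree, derives the brain mask as the union of nonzero voxels (BRATS data
#' is skull-stripped with zero background) unless supplied, and attaches the
#' label map when the record has one.
#'
#' @param record a `subject_record`.
#' @param brain_mask optional logical raster overriding the default mask.
#' @return object of class `modality_stack`: list with `modalities` (named
#'   list of rasters in canonical order), `brain_mask`, `labels` (or NULL),
#'   `subject_id`.
#' @export
load_subject <- function(record, brain_mask = NULL) {
  stopifnot(inherits(record, "subject_record"))
  mods <- lapply(record$modality_paths, read_volume)
  dims <- lapply(mods, dim)
  for (m in MODALITIES[-1]) {
    if (!identical(dims[[m]], dims[[1]])) {
      stop("cohort error: subject ", record$subject_id, ": modality ", m,
           " shape (", paste(dims[[m]], collapse = "x"),
           ") differs from FLAIR (", paste(dims[[1]], collapse = "x"), ")")
    }
  }
  mods <- lapply(mods, function(x) {
    a <- x; attributes(a) <- list(dim = dim(x)); storage.mode(a) <- "double"; a
  })
  if (is.null(brain_mask)) {
    brain_mask <- Reduce(`|`, lapply(mods, function(x) x != 0))
  }
  stopifnot(identical(dim(brain_mask), dims[[1]]))
  labels <- NULL
  if (!is.null(record$label_path)) {
    labels <- read_volume(record$label_path)
    lab_attrs <- dim(labels)
    attributes(labels) <- list(dim = lab_attrs)
    storage.mode(labels) <- "integer"
    if (!identical(dim(labels), dims[[1]])) {
      stop("cohort error: subject ", record$subject_id,
           ": label shape differs from modalities")
    }
    check_brats_labels(labels)
  }
  structure(
    list(modalities = mods, brain_mask = brain_mask, labels = labels,
         subject_id = record$subject_id, grade = record$grade),
    class = "modality_stack"
  )
}

#' Write / read a cohort manifest
#'
#' Plain JSON listing of subject records. Relative paths are interpreted
#' relative to the manifest's directory on read, so a cohort directory is
#' relocatable.
#'
#' @param records list of `subject_record`.
#' @param path manifest path (`.json`).
#' @return `read_manifest` returns a list of `subject_record`.
#' @export
write_manifest <- function(records, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  recs <- lapply(records, function(r) {
    list(subject_id = r$subject_id, grade = r$grade,
         modality_paths = r$modality_paths,
         label_path = if (is.null(r$label_path)) NA else r$label_path)
  })
  jsonlite::write_json(list(subjects = recs), path, auto_unbox = TRUE,
                       pretty = TRUE, null = "null", na = "null")
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("I/O error: missing manifest ", path)
  obj <- tryCatch(
    jsonlite::read_json(path),
    error = function(e) stop("parse error in manifest ", path, ": ",
                             conditionMessage(e))
  )
  if (is.null(obj$subjects)) stop("parse error: manifest lacks 'subjects': ",
                                  path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p) || (length(p) == 1L && is.na(p))) return(NULL)
    if (grepl("^/", p)) p else file.path(base, p)
  }
  lapply(seq_along(obj$subjects), function(i) {
    s <- obj$subjects[[i]]
    if (is.null(s$subject_id) || is.null(s$modality_paths)) {
      stop("parse error: manifest subject #", i, " missing required fields")
    }
    mp <- lapply(s$modality_paths, identity)
    rec <- tryCatch(
      subject_record(s$subject_id, lapply(mp, function(p) p),
                     label_path = s$label_path, grade = s$grade),
      error = function(e) stop("parse error: manifest subject #", i, " (",
                               s$subject_id, "): ", conditionMessage(e))
    )
    rec$modality_paths <- lapply(rec$modality_paths, resolve)
    rec$label_path <- resolve(rec$label_path)
    rec
  })
}
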
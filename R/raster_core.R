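#' Calibrated raster image
#'
#' Container for a 2D image or 3D stack with per-axis physical pixel sizes.
#' Arrays are stored in R's column-major layout as `(row, column)` for 2D and
#' `(row, column, plane)` for 3D; calibration entries follow the same axis
#' order. The default calibration is 1 unit per pixel with unit `"pixel"`.
#'
#' @param data numeric matrix (2D) or 3D array of finite intensities.
#' @param calibration positive numeric vector, one entry per axis (physical
#'   size of one pixel along that axis). A single value is recycled.
#' @param unit unit label for the calibration entries.
#' @param bit_depth sample-type tag of the source data: `"uint8"`, `"uint16"`
#'   or `"float32"`.
#' @return An object of class `calibrated_image`.
#' @export
calibrated_image <- function(data, calibration = 1, unit = "pixel",
                             bit_depth = "float32") {
  if (is.null(dim(data))) stopf("`data` must be a matrix or 3D array")
  nd <- ndim_of(data)
  if (!nd %in% c(2L, 3L)) stopf("dimensionality must be 2 or 3, got %d", nd)
  if (any(dim(data) < 1L)) stopf("all axis sizes must be >= 1")
  if (!all(is.finite(data))) stopf("image intensities must be finite")
  calibration <- as.numeric(calibration)
  if (length(calibration) == 1L) calibration <- rep(calibration, nd)
  if (length(calibration) != nd) stopf("calibration needs %d entries", nd)
  if (any(!is.finite(calibration)) || any(calibration <= 0))
    stopf("calibration entries must be positive and finite")
  bit_depth <- match.arg(bit_depth, c("uint8", "uint16", "float32"))
  structure(
    list(data = data, calibration = calibration, unit = unit,
         bit_depth = bit_depth),
    class = "calibrated_image"
  )
}

#' @export
print.calibrated_image <- function(x, ...) {
  cat(sprintf("<calibrated_image> %s, %s, calibration (%s) %s\n",
              paste(dim(x$data), collapse = "x"), x$bit_depth,
              paste(signif(x$calibration, 4), collapse = ", "), x$unit))
  invisible(x)
}

#' Binary mask over a calibrated raster
#'
#' Logical raster with the same shape and calibration as its source image;
#' `TRUE` marks object (foreground) pixels. When persisted to TIFF the
#' foreground is written as 255 on a 0 background (see [save_mask()]).
#'
#' @param data logical matrix or 3D array (numeric input is coerced with
#'   `> 0`).
#' @inheritParams calibrated_image
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(data, calibration = 1, unit = "pixel") {
  if (is.null(dim(data))) stopf("`data` must be a matrix or 3D array")
  dm <- dim(data)
  if (!is.logical(data)) data <- array(data > 0, dm)
  if (anyNA(data)) stopf("mask values must not be NA")
  nd <- length(dm)
  calibration <- as.numeric(calibration)
  if (length(calibration) == 1L) calibration <- rep(calibration, nd)
  if (length(calibration) != nd) stopf("calibration needs %d entries", nd)
  if (any(calibration <= 0)) stopf("calibration entries must be positive")
  structure(list(data = data, calibration = calibration, unit = unit),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %s, %d foreground pixels\n",
              paste(dim(x$data), collapse = "x"), sum(x$data)))
  invisible(x)
}

# Mask with the shape/calibration of `image` (a calibrated_image or
# binary_mask template).
mask_like <- function(template, data) {
  binary_mask(data, calibration = template$calibration, unit = template$unit)
}

#' Crop box
#'
#' Per-axis inclusive index interval `[lo, hi]`, 1-based, in the style of
#' ranges used across R (e.g. IRanges). Nested crops compose: cropping by `a`
#' then `b` equals cropping by the box with `lo = a$lo + b$lo - 1`.
#'
#' @param lo,hi integer vectors of per-axis lower/upper bounds (inclusive),
#'   one entry per image axis.
#' @return An object of class `crop_box`.
#' @export
crop_box <- function(lo, hi) {
  lo <- as.integer(lo); hi <- as.integer(hi)
  if (length(lo) != length(hi)) stopf("`lo` and `hi` lengths differ")
  if (any(lo < 1L) || any(hi < lo))
    stopf("crop box requires 1 <= lo <= hi on every axis")
  structure(list(lo = lo, hi = hi), class = "crop_box")
}

#' Crop a calibrated image or mask
#'
#' Extracts the sub-raster selected by `box`; calibration is carried along
#' unchanged.
#'
#' @param image a [calibrated_image()] or [binary_mask()].
#' @param box a [crop_box()] whose bounds lie within the image.
#' @return Object of the same class as `image`.
#' @export
crop <- function(image, box) {
  stopifnot(inherits(box, "crop_box"))
  dm <- dim(image$data)
  if (length(box$lo) != length(dm))
    stopf("crop box has %d axes, image has %d", length(box$lo), length(dm))
  if (any(box$hi > dm))
    stopf("crop box exceeds image extent (%s)", paste(dm, collapse = "x"))
  idx <- Map(function(l, h) l:h, box$lo, box$hi)
  sub <- do.call(`[`, c(list(image$data), idx, list(drop = FALSE)))
  out <- image
  out$data <- array(sub, vapply(idx, length, 1L))
  out
}

# ---------------------------------------------------------------------------
# TIFF I/O

#' Load a calibrated image from a TIFF file
#'
#' Reads single- or multi-page TIFF (8-bit, 16-bit or 32-bit float). Pages
#' are stacked as planes of a 3D image; a single page yields a 2D image.
#' Multi-sample (multi-channel) files are split into one image per channel.
#'
#' @param path path to a readable TIFF file.
#' @param calibration optional per-axis physical pixel sizes; defaults to
#'   1 per axis with unit `"pixel"`.
#' @param unit unit label accompanying `calibration`.
#' @return A `calibrated_image`, or a list of them (one per channel) for
#'   multi-channel files.
#' @export
load_calibrated_image <- function(path, calibration = NULL, unit = "pixel") {
  if (!file.exists(path)) stopf("file not found: %s", path)
  pages <- tryCatch({
    meta <- tiff::readTIFF(path, payload = FALSE, info = TRUE)
    if (is.data.frame(meta)) meta <- meta[1, , drop = FALSE]
    is_float <- identical(as.character(meta$sample.format %||% "uint"),
                          "float")
    # integer samples are read unscaled; float samples verbatim
    tiff::readTIFF(path, all = TRUE, as.is = !is_float, info = TRUE)
  }, error = function(e) stopf("cannot read TIFF '%s': %s", path,
                               conditionMessage(e)))
  if (!length(pages)) stopf("TIFF '%s' contains no images", path)
  info <- attributes(pages[[1]])
  bits <- info$bits.per.sample
  fmt <- info$sample.format
  bit_depth <-
    if (!is.null(fmt) && identical(fmt, "float")) "float32"
    else if (!is.null(bits) && bits <= 8) "uint8"
    else if (!is.null(bits) && bits <= 16) "uint16"
    else "float32"
  nch <- if (length(dim(pages[[1]])) == 3L) dim(pages[[1]])[3] else 1L
  build <- function(planes) {
    dm2 <- dim(planes[[1]])
    dat <- if (length(planes) == 1L) planes[[1]]
           else array(unlist(planes, use.names = FALSE),
                      c(dm2, length(planes)))
    nd <- ndim_of(dat)
    cal <- if (is.null(calibration)) rep(1, nd) else calibration
    u <- if (is.null(calibration)) "pixel" else unit
    calibrated_image(dat, calibration = cal, unit = u, bit_depth = bit_depth)
  }
  if (nch == 1L) {
    build(lapply(pages, function(p) {
      if (length(dim(p)) == 3L) p[, , 1] else p
    }))
  } else {
    lapply(seq_len(nch), function(ch) {
      build(lapply(pages, function(p) p[, , ch]))
    })
  }
}

#' Save a calibrated image as TIFF
#'
#' Integer images (`uint8`/`uint16`) round-trip bit-exactly; `float32`
#' images are written as IEEE-float TIFF (NaN allowed). 3D images become
#' multi-page files, one page per plane.
#'
#' @param image a [calibrated_image()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_calibrated_image <- function(image, path) {
  stopifnot(inherits(image, "calibrated_image"))
  planes <- image_planes(image$data)
  if (image$bit_depth == "float32") {
    write_float_tiff(planes, path)
  } else {
    mx <- if (image$bit_depth == "uint8") 255 else 65535
    bits <- if (image$bit_depth == "uint8") 8L else 16L
    if (any(image$data < 0 | image$data > mx))
      stopf("values outside [0, %d] cannot be saved as %s", mx,
            image$bit_depth)
    tiff::writeTIFF(lapply(planes, function(p) p / mx), path,
                    bits.per.sample = bits)
  }
  invisible(path)
}

#' Save a binary mask as 8-bit TIFF (foreground = 255)
#'
#' @param mask a [binary_mask()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_mask <- function(mask, path) {
  stopifnot(inherits(mask, "binary_mask"))
  planes <- image_planes(array(ifelse(mask$data, 1, 0), dim(mask$data)))
  tiff::writeTIFF(planes, path, bits.per.sample = 8L)
  invisible(path)
}

# Split an array into a list of 2D planes (list of one for 2D input).
image_planes <- function(data) {
  if (ndim_of(data) == 2L) return(list(data))
  lapply(seq_len(dim(data)[3]), function(p) data[, , p])
}

#' Write 2D planes as an uncompressed 32-bit float TIFF
#'
#' Minimal little-endian baseline-TIFF writer with SampleFormat = IEEE
#' float, used for rasters that carry real-valued or NaN pixels (probability
#' maps, thickness and width maps). Files are readable by `tiff::readTIFF`
#' and by ImageJ.
#'
#' @param planes a matrix or list of equally-sized matrices (pages).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_float_tiff <- function(planes, path) {
  if (is.matrix(planes)) planes <- list(planes)
  stopifnot(length(planes) >= 1L, all(vapply(planes, is.matrix, TRUE)))
  dm <- dim(planes[[1]])
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x, size)
    writeBin(as.integer(x), con, size = size, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  # header: II, magic 42, offset of first IFD
  writeBin(charToRaw("II"), con); wi(42L, 2L)
  n_entries <- 8L
  ifd_bytes <- 2L + n_entries * 12L + 4L
  data_bytes <- 4L * prod(dm)
  # layout: header(8) then per page [pixel data][IFD]
  wi(8L + data_bytes, 4L)
  offset <- 8L
  for (i in seq_along(planes)) {
    p <- planes[[i]]
    if (!identical(dim(p), dm)) stopf("all pages must share one shape")
    # pixel data, row-major as TIFF expects
    wf(t(p))
    strip_offset <- offset
    offset <- offset + data_bytes
    # IFD
    wi(n_entries, 2L)
    entry <- function(tag, type, count, value) {
      wi(tag, 2L); wi(type, 2L); wi(count, 4L); wi(value, 4L)
    }
    entry(256L, 4L, 1L, dm[2])            # ImageWidth
    entry(257L, 4L, 1L, dm[1])            # ImageLength
    entry(258L, 3L, 1L, 32L)              # BitsPerSample
    entry(259L, 3L, 1L, 1L)               # Compression: none
    entry(262L, 3L, 1L, 1L)               # Photometric: BlackIsZero
    entry(273L, 4L, 1L, strip_offset)     # StripOffsets
    entry(279L, 4L, 1L, data_bytes)       # StripByteCounts
    entry(339L, 3L, 1L, 3L)               # SampleFormat: IEEE float
    offset <- offset + ifd_bytes
    # next IFD sits after the next page's pixel data
    wi(if (i < length(planes)) offset + data_bytes else 0L, 4L)
  }
  invisible(path)
}
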
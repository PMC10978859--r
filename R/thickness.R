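# Local thickness (largest inscribed disk/ball) and width along the
# skeleton.
#
# thickness(p) = max over foreground centres c of 2*dt(c), over all c with
# ||c - p|| <= dt(c), where dt is the Euclidean distance to the nearest
# background pixel centre. Distances honour anisotropic calibration (the
# inscribed ball is a physical sphere). Computation: exact squared
# Euclidean distance transform (separable lower-envelope algorithm),
# followed by sphere painting in decreasing-radius order.

# Exact squared Euclidean distance (physical units) from every pixel to
# the nearest TRUE pixel of `feature`. Pixels with no feature anywhere get
# Inf.
distance_transform_sq <- function(feature, spacing = rep(1, ndim_of(feature))) {
  dm <- dim(feature)
  nd <- length(dm)
  BIG <- 1e30
  f <- array(ifelse(feature, 0, BIG), dm)
  for (a in seq_len(nd)) {
    f <- apply_axis_dt(f, a, spacing[a])
  }
  f[f >= BIG / 2] <- Inf
  f
}

# One separable pass: 1D squared-distance lower envelope along axis `a`
# with sample spacing w.
apply_axis_dt <- function(f, a, w) {
  dm <- dim(f)
  nd <- length(dm)
  perm <- c(a, seq_len(nd)[-a])
  y <- matrix(aperm(f, perm), dm[a], prod(dm[-a]))
  for (j in seq_len(ncol(y))) y[, j] <- dt1d(y[, j], w)
  aperm(array(y, dm[perm]), order(perm))
}

# Felzenszwalb-Huttenlocher 1D squared distance transform, grid spacing w.
dt1d <- function(f, w) {
  n <- length(f)
  if (n == 1L) return(f)
  x <- (seq_len(n) - 1) * w
  v <- integer(n); z <- numeric(n + 1L)
  k <- 1L; v[1] <- 1L; z[1] <- -Inf; z[2] <- Inf
  for (q in 2:n) {
    repeat {
      p <- v[k]
      s <- ((f[q] + x[q]^2) - (f[p] + x[p]^2)) / (2 * x[q] - 2 * x[p])
      if (s <= z[k]) { k <- k - 1L; if (k == 0L) { k <- 1L; v[1] <- q; z[1] <- -Inf; z[2] <- Inf; break } }
      else { k <- k + 1L; v[k] <- q; z[k] <- s; z[k + 1L] <- Inf; break }
    }
  }
  d <- numeric(n)
  k <- 1L
  for (q in seq_len(n)) {
    while (z[k + 1L] < x[q]) k <- k + 1L
    d[q] <- (x[q] - x[v[k]])^2 + f[v[k]]
  }
  d
}

#' Local thickness map of a mask
#'
#' At every foreground pixel, the diameter (in physical units) of the
#' largest disk (2D) or ball (3D) that fits entirely inside the foreground
#' and contains the pixel. Background pixels carry `NA`.
#'
#' @param mask a [binary_mask()].
#' @return An object of class `thickness_map`: `$data` with per-pixel
#'   diameters (`NA` outside), plus calibration.
#' @export
local_thickness_map <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  fg <- mask$data
  dm <- dim(fg)
  cal <- mask$calibration
  out2 <- array(0, dm)         # squared inscribed-ball radius
  if (any(fg)) {
    dt2 <- distance_transform_sq(!fg, spacing = cal)
    centers <- which(fg)
    r2 <- dt2[centers]
    ord <- order(r2, decreasing = TRUE)
    centers <- centers[ord]; r2 <- r2[ord]
    nd <- length(dm)
    for (i in seq_along(centers)) {
      c_i <- centers[i]
      ri2 <- r2[i]
      if (!is.finite(ri2)) { out2[fg] <- Inf; break }
      co <- index_to_coord(c_i, dm)[1, ]
      rng <- lapply(seq_len(nd), function(a) {
        h <- floor(sqrt(ri2) / cal[a] + 1e-12)
        max(1, co[a] - h):min(dm[a], co[a] + h)
      })
      grid <- as.matrix(expand.grid(rng))
      d2 <- numeric(nrow(grid))
      for (a in seq_len(nd)) d2 <- d2 + ((grid[, a] - co[a]) * cal[a])^2
      sel <- d2 <= ri2
      wi <- coord_to_index(grid[sel, , drop = FALSE], dm)
      wi <- wi[fg[wi]]
      out2[wi] <- pmax(out2[wi], ri2)
    }
  }
  th <- array(NA_real_, dm)
  th[fg] <- 2 * sqrt(out2[fg])
  structure(list(data = th, calibration = cal, unit = mask$unit),
            class = "thickness_map")
}

#' Histogram configuration for width profiles
#'
#' @param n_bins number of equal-width bins (>= 1).
#' @param width_min,width_max physical width range covered by the
#'   histogram, `width_min < width_max`.
#' @return An object of class `histogram_config`.
#' @export
histogram_config <- function(n_bins = 20L, width_min = 0, width_max = 20) {
  n_bins <- as.integer(n_bins)
  if (n_bins < 1L) stopf("n_bins must be >= 1")
  if (!(width_min < width_max)) stopf("width_min must be < width_max")
  structure(list(n_bins = n_bins, width_min = width_min,
                 width_max = width_max),
            class = "histogram_config")
}

#' Width along the skeleton
#'
#' Restricts the local-thickness map to the skeleton pixels, yielding the
#' projection width per increment of centerline length, and summarises it
#' as histogram, mean and median. Histogram bins are half-open over
#' `[width_min, width_max)` with the last bin closed; values outside the
#' range are excluded from the histogram (counted in
#' `out_of_range_count`) but included in mean and median.
#'
#' @param thickness a [local_thickness_map()] result.
#' @param skel a [skeletonize_mask()] result with skeleton pixels inside
#'   the thickness foreground.
#' @param hist a [histogram_config()].
#' @param trim_ends number of pixels to trim from every branch end before
#'   profiling (default 0: endpoint pixels are included).
#' @return An object of class `width_profile`: `$values` (per skeleton
#'   pixel, array scan order), `$counts`, `$breaks`,
#'   `$out_of_range_count`, `$width_mean`, `$width_median`, `$n_pixels`.
#' @export
width_along_skeleton <- function(thickness, skel, hist = histogram_config(),
                                 trim_ends = 0L) {
  stopifnot(inherits(thickness, "thickness_map"),
            inherits(skel, "binary_mask") || inherits(skel, "skeleton_image"),
            inherits(hist, "histogram_config"))
  if (!same_shape(thickness$data, skel$data)) stopf("shapes differ")
  fg <- skel$data
  if (trim_ends > 0L) for (i in seq_len(trim_ends)) {
    nbc <- neighbour_count(fg)
    fg <- fg & !(nbc < 2L)
  }
  vals <- thickness$data[fg]
  if (anyNA(vals))
    stopf("skeleton pixel with undefined thickness (skeleton outside mask?)")
  breaks <- seq(hist$width_min, hist$width_max, length.out = hist$n_bins + 1L)
  if (length(vals)) {
    bin <- findInterval(vals, breaks, rightmost.closed = TRUE)
    in_range <- bin >= 1L & bin <= hist$n_bins
    counts <- tabulate(bin[in_range], hist$n_bins)
    oor <- sum(!in_range)
    wmean <- mean(vals)
    wmedian <- stats::median(vals)
  } else {
    counts <- integer(hist$n_bins); oor <- 0L
    wmean <- NA_real_; wmedian <- NA_real_
  }
  structure(list(values = vals, counts = counts, breaks = breaks,
                 out_of_range_count = oor, width_mean = wmean,
                 width_median = wmedian, n_pixels = length(vals),
                 unit = thickness$unit),
            class = "width_profile")
}

#' @export
print.width_profile <- function(x, ...) {
  cat(sprintf("<width_profile> %d skeleton pixels, mean %.4g, median %.4g %s\n",
              x$n_pixels, x$width_mean, x$width_median, x$unit))
  invisible(x)
}

#' Export a thickness/width map as 32-bit float TIFF with NaN background
#'
#' @param map a `thickness_map` (or any list with `$data`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_thickness_map <- function(map, path) {
  dat <- map$data
  dat[is.na(dat)] <- NaN
  write_float_tiff(image_planes(dat), path)
}

#' Width map: thickness restricted to skeleton pixels, NaN elsewhere
#'
#' The raster equivalent of [width_along_skeleton()]: skeleton pixels carry
#' their local thickness, everything else is NaN, so pixel values read
#' directly as section widths.
#'
#' @inheritParams width_along_skeleton
#' @return A `thickness_map` restricted to the skeleton.
#' @export
width_map <- function(thickness, skel) {
  stopifnot(inherits(thickness, "thickness_map"))
  if (!same_shape(thickness$data, skel$data)) stopf("shapes differ")
  dat <- array(NA_real_, dim(thickness$data))
  dat[skel$data] <- thickness$data[skel$data]
  structure(list(data = dat, calibration = thickness$calibration,
                 unit = thickness$unit),
            class = "thickness_map")
}
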
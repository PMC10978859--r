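# Seeded ground-truthed phantom generator.
#
# Renders tube-like projections (polyline centerlines with a radius),
# elliptical somata/nuclei and blob-like structures over a flat or
# linearly graded background, with anti-aliased edges and optional
# Gaussian noise. Structure coordinates are continuous pixel coordinates
# in which the centre of pixel (i, j) is (i, j); placing centerlines at
# half-integer positions mimics the generic (off-grid) positions of real
# structures. Ground truth reflects the noise-free geometry: a pixel
# belongs to a structure's mask when its coverage is at least one half,
# which for a tube equals centre-to-centerline distance <= radius.

#' Tube specification for [generate_phantom()]
#'
#' @param points numeric matrix of polyline control points, one row per
#'   vertex, columns `(row, col)` or `(row, col, plane)` in continuous
#'   pixel coordinates.
#' @param radius tube radius in pixels.
#' @param intensity structure intensity (image value at full coverage).
#' @return A `phantom_tube` specification.
#' @export
phantom_tube <- function(points, radius, intensity) {
  points <- as.matrix(points)
  if (nrow(points) < 2L) stopf("a tube needs at least two control points")
  if (radius <= 0) stopf("radius must be positive")
  structure(list(points = points, radius = radius, intensity = intensity),
            class = "phantom_tube")
}

#' Blob (ellipse/ellipsoid) specification for [generate_phantom()]
#'
#' @param center numeric centre in continuous pixel coordinates.
#' @param radii per-axis semi-axes in pixels (a single value gives a
#'   disk/ball).
#' @param intensity structure intensity.
#' @return A `phantom_blob` specification.
#' @export
phantom_blob <- function(center, radii, intensity) {
  center <- as.numeric(center)
  radii <- rep_len(as.numeric(radii), length(center))
  if (any(radii <= 0)) stopf("radii must be positive")
  structure(list(center = center, radii = radii, intensity = intensity),
            class = "phantom_blob")
}

#' Phantom configuration
#'
#' @param shape raster dimensions `(rows, cols)` or `(rows, cols, planes)`.
#' @param tubes list of [phantom_tube()] specifications.
#' @param blobs list of [phantom_blob()] specifications.
#' @param background background intensity level.
#' @param gradient per-axis linear background gradient: total intensity
#'   change across the raster along each axis (default none).
#' @param noise_sigma standard deviation of additive Gaussian noise.
#' @param value_range intensities are clipped to this range after noise.
#' @param calibration physical pixel size per axis.
#' @param unit calibration unit label.
#' @param seed RNG seed; identical configuration and seed reproduce the
#'   image bit for bit.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(shape, tubes = list(), blobs = list(),
                           background = 10, gradient = NULL,
                           noise_sigma = 0, value_range = c(0, 255),
                           calibration = 1, unit = "pixel", seed = 1L) {
  shape <- as.integer(shape)
  nd <- length(shape)
  if (!nd %in% c(2L, 3L)) stopf("shape must have 2 or 3 axes")
  if (is.null(gradient)) gradient <- rep(0, nd)
  gradient <- rep_len(as.numeric(gradient), nd)
  for (tb in tubes) {
    if (!inherits(tb, "phantom_tube")) stopf("tubes must be phantom_tube")
    if (ncol(tb$points) != nd) stopf("tube points must have %d columns", nd)
    lo <- apply(tb$points, 2, min) - tb$radius
    hi <- apply(tb$points, 2, max) + tb$radius
    if (any(lo < 0.5) || any(hi > shape + 0.5))
      stopf("tube extends outside the raster")
  }
  for (bl in blobs) {
    if (!inherits(bl, "phantom_blob")) stopf("blobs must be phantom_blob")
    if (length(bl$center) != nd) stopf("blob centre must have %d entries", nd)
    if (any(bl$center - bl$radii < 0.5) || any(bl$center + bl$radii > shape + 0.5))
      stopf("blob extends outside the raster")
  }
  structure(list(shape = shape, tubes = tubes, blobs = blobs,
                 background = background, gradient = gradient,
                 noise_sigma = noise_sigma, value_range = value_range,
                 calibration = rep_len(as.numeric(calibration), nd),
                 unit = unit, seed = as.integer(seed)),
            class = "phantom_config")
}

#' Generate a ground-truthed phantom image
#'
#' Structures are rendered with anti-aliased edges: a pixel's coverage
#' fraction (how much of it lies inside the structure) blends the
#' structure intensity into the background, while the ground-truth masks
#' stay crisp (coverage >= 0.5).
#'
#' @param cfg a [phantom_config()].
#' @return A list with `$image` (a [calibrated_image()]) and `$truth`, a
#'   `phantom_truth` object holding per-structure masks (`$tube_masks`,
#'   `$blob_masks`, combined `$tubes_mask`/`$blobs_mask`), per-tube
#'   centerline pixel sets (`$centerlines`, linear indices), true
#'   centerline lengths (`$tube_lengths`, physical units), true diameters
#'   (`$tube_diameters`) and counts.
#' @export
generate_phantom <- function(cfg) {
  stopifnot(inherits(cfg, "phantom_config"))
  dm <- cfg$shape
  nd <- length(dm)
  cal <- cfg$calibration
  coords <- lapply(seq_len(nd), function(a) seq_len(dm[a]))
  # background with linear gradient
  img <- array(cfg$background, dm)
  for (a in seq_len(nd)) {
    if (cfg$gradient[a] == 0) next
    ramp <- (coords[[a]] - 1) / max(1, dm[a] - 1) * cfg$gradient[a]
    pdim <- c(a, seq_len(nd)[-a])
    add <- aperm(array(ramp, dm[pdim]), order(pdim))
    img <- img + add
  }
  tube_masks <- list(); centerlines <- list()
  tube_lengths <- numeric(0); tube_diameters <- numeric(0)
  blob_masks <- list()
  render <- function(cov, intensity) {
    img <<- img * (1 - cov) + intensity * cov
  }
  for (tb in cfg$tubes) {
    dist <- distance_to_polyline(tb$points, dm)
    cov <- array(clamp(tb$radius + 0.5 - dist, 0, 1), dm)
    render(cov, tb$intensity)
    tube_masks[[length(tube_masks) + 1L]] <- dist <= tb$radius
    centerlines[[length(centerlines) + 1L]] <-
      rasterize_polyline(tb$points, dm)
    seg <- diff(tb$points)
    tube_lengths <- c(tube_lengths,
                      sum(sqrt(rowSums(sweep(seg, 2, cal, `*`)^2))))
    tube_diameters <- c(tube_diameters, 2 * tb$radius)
  }
  for (bl in cfg$blobs) {
    grid <- lapply(seq_len(nd), function(a) coords[[a]] - bl$center[a])
    rho2 <- array(0, dm)
    for (a in seq_len(nd)) {
      pdim <- c(a, seq_len(nd)[-a])
      add <- aperm(array((grid[[a]] / bl$radii[a])^2, dm[pdim]), order(pdim))
      rho2 <- rho2 + add
    }
    sdist <- (sqrt(rho2) - 1) * min(bl$radii)
    cov <- array(clamp(0.5 - sdist, 0, 1), dm)
    render(cov, bl$intensity)
    blob_masks[[length(blob_masks) + 1L]] <- rho2 <= 1
  }
  if (cfg$noise_sigma > 0)
    img <- img + with_seed(cfg$seed,
                           array(stats::rnorm(prod(dm), 0, cfg$noise_sigma),
                                 dm))
  img <- clamp(img, cfg$value_range[1], cfg$value_range[2])
  union_mask <- function(ms) {
    if (!length(ms)) return(array(FALSE, dm))
    Reduce(`|`, ms)
  }
  truth <- structure(list(
    tube_masks = tube_masks, blob_masks = blob_masks,
    tubes_mask = union_mask(tube_masks), blobs_mask = union_mask(blob_masks),
    centerlines = centerlines, tube_lengths = tube_lengths,
    tube_diameters = tube_diameters,
    n_tubes = length(tube_masks), n_blobs = length(blob_masks),
    shape = dm, calibration = cal), class = "phantom_truth")
  list(image = calibrated_image(array(img, dm), calibration = cal,
                                unit = cfg$unit, bit_depth = "float32"),
       truth = truth)
}

# Minimum distance (pixels) from every pixel centre to a polyline.
distance_to_polyline <- function(points, dm) {
  nd <- length(dm)
  co <- as.matrix(expand.grid(lapply(dm, seq_len)))
  best <- rep(Inf, nrow(co))
  for (s in seq_len(nrow(points) - 1L)) {
    a <- points[s, ]; b <- points[s + 1L, ]
    ab <- b - a
    len2 <- sum(ab^2)
    diffa <- sweep(co, 2, a, `-`)
    t <- if (len2 > 0) clamp(as.numeric(diffa %*% ab) / len2, 0, 1) else 0
    proj <- sweep(outer(t, ab), 2, a, `+`)
    d2 <- rowSums((co - proj)^2)
    best <- pmin(best, d2)
  }
  array(sqrt(best), dm)
}

# Linear indices of the pixels a polyline passes through (dense sampling).
rasterize_polyline <- function(points, dm) {
  pts <- NULL
  for (s in seq_len(nrow(points) - 1L)) {
    a <- points[s, ]; b <- points[s + 1L, ]
    n <- max(2L, ceiling(4 * sqrt(sum((b - a)^2))))
    t <- seq(0, 1, length.out = n)
    pts <- rbind(pts, sweep(outer(t, b - a), 2, a, `+`))
  }
  pix <- round(pts)
  pix <- pmin(pmax(pix, 1), matrix(dm, nrow(pix), length(dm), byrow = TRUE))
  sort(unique(coord_to_index(pix, dm)))
}

#' False-positive / false-negative rates against phantom ground truth
#'
#' For `kind = "length"`: skeleton pixels farther than `tolerance_px` from
#' any true centerline pixel are unsupported; the false-positive length is
#' the corresponding share of the measured total length. True centerline
#' pixels farther than `tolerance_px` from any skeleton pixel are
#' unrecovered; the false-negative length is the corresponding share of
#' the true length. Both are divided by the true (reference) length.
#'
#' For `kind = "count"`: predicted objects with no pixel on the true
#' foreground are false positives; true structures with no predicted
#' pixel are false negatives; both divided by the true count.
#'
#' @param predicted a skeleton (`kind = "length"`) or object mask
#'   (`kind = "count"`) as a [binary_mask()]/[skeletonize_mask()] result.
#' @param truth a `phantom_truth` from [generate_phantom()].
#' @param kind `"length"` or `"count"`.
#' @param tolerance_px distance tolerance in pixels for length support
#'   (default 2).
#' @param structures which truth structures to validate against:
#'   `"tubes"` or `"blobs"`.
#' @return An object of class `validation_rates` with fields `fp_rate`,
#'   `fn_rate` and the underlying measurements.
#' @export
validation_rates <- function(predicted, truth,
                             kind = c("length", "count"),
                             tolerance_px = 2,
                             structures = c("tubes", "blobs")) {
  kind <- match.arg(kind)
  structures <- match.arg(structures)
  stopifnot(inherits(truth, "phantom_truth"))
  dm <- truth$shape
  pred_fg <- predicted$data
  if (!identical(dim(pred_fg), dm)) stopf("prediction shape differs")
  if (kind == "length") {
    if (!truth$n_tubes) stopf("truth contains no centerlines")
    cl <- array(FALSE, dm)
    cl[unlist(truth$centerlines)] <- TRUE
    ref_length <- sum(truth$tube_lengths)
    if (ref_length <= 0) stopf("reference measurement is zero")
    rep_ <- analyze_skeleton(
      structure(list(data = pred_fg, calibration = truth$calibration,
                     unit = "pixel"),
                class = c("skeleton_image", "binary_mask")))
    pred_length <- if (nrow(rep_$skeletons))
      sum(rep_$skeletons$branch_length_sum) else 0
    n_sk <- sum(pred_fg)
    if (n_sk > 0) {
      d2_to_truth <- distance_transform_sq(cl)
      unsupported <- sum(d2_to_truth[pred_fg] > tolerance_px^2 + 1e-9)
      fp <- pred_length * unsupported / n_sk
    } else fp <- 0
    d2_to_pred <- if (any(pred_fg)) distance_transform_sq(pred_fg)
                  else array(Inf, dm)
    unrecovered <- sum(d2_to_pred[cl] > tolerance_px^2 + 1e-9)
    fn <- ref_length * unrecovered / sum(cl)
    structure(list(fp_rate = fp / ref_length, fn_rate = fn / ref_length,
                   predicted_length = pred_length,
                   reference_length = ref_length, kind = kind),
              class = "validation_rates")
  } else {
    masks <- if (structures == "tubes") truth$tube_masks else truth$blob_masks
    n_true <- length(masks)
    if (!n_true) stopf("reference measurement is zero")
    true_fg <- Reduce(`|`, masks)
    lab <- label_components(mask_like(
      binary_mask(pred_fg, truth$calibration), pred_fg))
    n_pred <- max(lab)
    fp <- if (n_pred) sum(vapply(seq_len(n_pred), function(o)
      !any(true_fg[lab == o]), TRUE)) else 0L
    fn <- sum(vapply(masks, function(m) !any(pred_fg[m]), TRUE))
    structure(list(fp_rate = fp / n_true, fn_rate = fn / n_true,
                   predicted_count = n_pred, reference_count = n_true,
                   kind = kind),
              class = "validation_rates")
  }
}

#' @export
print.validation_rates <- function(x, ...) {
  cat(sprintf("<validation_rates> (%s) FP %.4f, FN %.4f\n",
              x$kind, x$fp_rate, x$fn_rate))
  invisible(x)
}

#' Save a phantom with its ground-truth sidecar
#'
#' Writes the image as float TIFF and the truth (counts, lengths,
#' diameters, centerline pixels, masks as run-length-free pixel lists) as
#' a YAML sidecar so fixtures stay inspectable plain text.
#'
#' @param phantom a [generate_phantom()] result.
#' @param image_path TIFF output path.
#' @param truth_path YAML sidecar path (default: `image_path` with
#'   `.truth.yaml`).
#' @return `image_path`, invisibly.
#' @export
save_phantom <- function(phantom, image_path,
                         truth_path = paste0(image_path, ".truth.yaml")) {
  save_calibrated_image(phantom$image, image_path)
  tr <- phantom$truth
  yaml::write_yaml(list(
    shape = as.integer(tr$shape),
    n_tubes = tr$n_tubes, n_blobs = tr$n_blobs,
    tube_lengths = as.numeric(tr$tube_lengths),
    tube_diameters = as.numeric(tr$tube_diameters),
    centerlines = lapply(tr$centerlines, as.integer),
    tube_mask_pixels = lapply(tr$tube_masks, function(m) which(m)),
    blob_mask_pixels = lapply(tr$blob_masks, function(m) which(m))),
    truth_path)
  invisible(image_path)
}
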
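# Probability-channel thresholding and object-level mask fine-tuning.

#' Threshold configuration for mask refinement
#'
#' Bounds applied when turning a probability channel into a final mask:
#' a minimum on the selected probability channel, size bounds on connected
#' components (area in 2D, volume in 3D), shape bounds (circularity in 2D,
#' sphericity in 3D), an optional lower bound on per-object mean input
#' intensity, and optional exclusion of objects touching the raster edge.
#'
#' @param prob_min probability threshold in `[0, 1]`; a pixel is foreground
#'   when its channel probability is `>= prob_min`.
#' @param size_min,size_max component size bounds; interpreted in physical
#'   units (squared for 2D, cubed for 3D) when `size_units = "physical"`,
#'   in pixels/voxels when `"pixels"`. `size_max` may be `Inf`.
#' @param circ_min,circ_max shape bounds in `[0, 1]` (circularity in 2D,
#'   sphericity in 3D).
#' @param exclude_edges drop components touching the raster border.
#' @param intensity_min optional lower bound on a component's mean
#'   intensity in the input image (`NULL` disables the bound).
#' @param size_units `"physical"` or `"pixels"`.
#' @return An object of class `threshold_config`.
#' @export
threshold_config <- function(prob_min = 0.5, size_min = 0, size_max = Inf,
                             circ_min = 0, circ_max = 1,
                             exclude_edges = FALSE, intensity_min = NULL,
                             size_units = c("physical", "pixels")) {
  size_units <- match.arg(size_units)
  if (prob_min < 0 || prob_min > 1) stopf("prob_min must lie in [0, 1]")
  if (size_min > size_max) stopf("size_min must not exceed size_max")
  if (circ_min < 0 || circ_max > 1 || circ_min > circ_max)
    stopf("shape bounds must satisfy 0 <= circ_min <= circ_max <= 1")
  structure(list(prob_min = prob_min, size_min = size_min,
                 size_max = size_max, circ_min = circ_min,
                 circ_max = circ_max, exclude_edges = isTRUE(exclude_edges),
                 intensity_min = intensity_min, size_units = size_units),
            class = "threshold_config")
}

#' Extract a class mask from a probability map
#'
#' A pixel is foreground iff its probability for the selected class is at
#' least `prob_min` (ties are foreground).
#'
#' @param pmap a [probability_map()].
#' @param class class channel, by 1-based index or name.
#' @param prob_min probability threshold in `[0, 1]`.
#' @return A [binary_mask()].
#' @export
extract_class_mask <- function(pmap, class, prob_min = 0.5) {
  stopifnot(inherits(pmap, "probability_map"))
  k <- length(pmap$class_names)
  if (is.character(class)) class <- match(class, pmap$class_names)
  if (is.na(class) || class < 1 || class > k)
    stopf("class index out of range 1..%d", k)
  dm <- dim(pmap$data)
  nd <- length(dm) - 1L
  chan <- if (nd == 2L) pmap$data[, , class] else pmap$data[, , , class]
  binary_mask(array(chan >= prob_min, dm[-length(dm)]),
              calibration = pmap$calibration, unit = pmap$unit)
}

#' Refine a mask by size, shape, intensity and edge rules
#'
#' Keeps the connected components (8-connected in 2D, 26-connected in 3D)
#' whose calibrated size, shape (circularity/sphericity), mean input
#' intensity and border contact satisfy the configured bounds. The output
#' foreground is always a subset of the input foreground, and refining an
#' already refined mask with the same configuration changes nothing.
#'
#' @param mask a [binary_mask()].
#' @param input_image the [calibrated_image()] the mask was derived from;
#'   only required when `cfg$intensity_min` is set.
#' @param cfg a [threshold_config()].
#' @return A [binary_mask()].
#' @export
refine_mask <- function(mask, input_image = NULL, cfg = threshold_config()) {
  stopifnot(inherits(mask, "binary_mask"), inherits(cfg, "threshold_config"))
  if (!is.null(input_image) && !same_shape(mask$data, input_image$data))
    stopf("mask and image shapes differ")
  if (!is.null(cfg$intensity_min) && is.null(input_image))
    stopf("intensity_min requires the input image")
  rec <- measure_particles(mask, input_image)
  if (!nrow(rec)) return(mask)
  size <- if (cfg$size_units == "physical") rec$size else rec$pixel_count
  keep <- size >= cfg$size_min & size <= cfg$size_max &
    rec$shape >= cfg$circ_min & rec$shape <= cfg$circ_max
  if (!is.null(cfg$intensity_min))
    keep <- keep & !is.na(rec$intensity_mean) &
      rec$intensity_mean >= cfg$intensity_min
  if (cfg$exclude_edges) keep <- keep & !rec$touches_edge
  lab <- label_components(mask)
  out <- array(lab %in% rec$object_id[keep], dim(mask$data))
  mask_like(mask, out)
}
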
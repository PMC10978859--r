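# Nuclei-gated cell-body detection and mask-based Manders colocalization.

#' Dilate a mask with a Euclidean ball
#'
#' Grows the foreground by all pixels whose Euclidean distance (in pixels)
#' to the existing foreground is at most `radius`. `radius = 0` is the
#' identity.
#'
#' @param mask a [binary_mask()].
#' @param radius dilation radius in pixels (>= 0).
#' @return A [binary_mask()].
#' @export
dilate_mask <- function(mask, radius) {
  stopifnot(inherits(mask, "binary_mask"), radius >= 0)
  if (radius == 0 || !any(mask$data)) return(mask)
  d2 <- distance_transform_sq(mask$data)   # pixel spacing
  mask_like(mask, array(d2 <= radius^2 + 1e-9, dim(mask$data)))
}

#' Detect cell bodies by nuclear support
#'
#' Keeps the connected components of `body_candidates` that intersect the
#' dilated nuclei mask, suppressing nucleus-free false positives such as
#' stain accumulations or thick neurite segments. Components are retained
#' whole (not clipped to the intersection), so downstream particle
#' measurements see intact objects.
#'
#' @param body_candidates candidate cell-body [binary_mask()] (e.g. the
#'   refined soma-class mask).
#' @param nuclei nuclei [binary_mask()] of the same shape.
#' @param dilation_radius halo radius in pixels by which nuclei are
#'   enlarged before the intersection test (default 5).
#' @return A [binary_mask()] containing the nucleated candidates.
#' @export
detect_cell_bodies <- function(body_candidates, nuclei, dilation_radius = 5) {
  stopifnot(inherits(body_candidates, "binary_mask"),
            inherits(nuclei, "binary_mask"))
  if (!same_shape(body_candidates$data, nuclei$data)) stopf("shapes differ")
  if (!any(body_candidates$data) || !any(nuclei$data))
    return(mask_like(body_candidates,
                     array(FALSE, dim(body_candidates$data))))
  halo <- dilate_mask(nuclei, dilation_radius)
  lab <- label_components(body_candidates)
  supported <- unique(lab[lab > 0L & halo$data])
  mask_like(body_candidates,
            array(lab %in% supported, dim(body_candidates$data)))
}

#' Manders overlap coefficients of two segmented masks
#'
#' Computes the overlap size (area in 2D, volume in 3D, physical units) of
#' the voxel-wise conjunction of two masks and the two Manders quotients:
#' `m_a = overlap / size(A)` and `m_b = overlap / size(B)`.
#'
#' @param a,b [binary_mask()]s of identical shape and calibration; both
#'   must be non-empty (the coefficients are undefined otherwise).
#' @return An object of class `coloc_result` with fields `overlap_size`,
#'   `m_a`, `m_b`, `size_a`, `size_b`.
#' @export
manders_overlap <- function(a, b) {
  stopifnot(inherits(a, "binary_mask"), inherits(b, "binary_mask"))
  if (!same_shape(a$data, b$data)) stopf("shapes differ")
  if (!isTRUE(all.equal(a$calibration, b$calibration)))
    stopf("calibrations differ")
  unit_size <- prod(a$calibration)
  size_a <- sum(a$data) * unit_size
  size_b <- sum(b$data) * unit_size
  if (size_a == 0 || size_b == 0)
    stopf("Manders coefficients are undefined for an empty mask")
  overlap <- sum(a$data & b$data) * unit_size
  structure(list(overlap_size = overlap, m_a = overlap / size_a,
                 m_b = overlap / size_b, size_a = size_a, size_b = size_b),
            class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("<coloc_result> overlap %g, M(A) = %.4f, M(B) = %.4f\n",
              x$overlap_size, x$m_a, x$m_b))
  invisible(x)
}
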
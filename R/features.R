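# Multi-scale image features feeding the pixel classifier.
#
# All filters use reflect padding at the raster border and operate in pixel
# units (sigma is a scale in pixels, independent of spatial calibration).

FAMILIES_2D <- c("identity", "gaussian", "gradient_magnitude", "laplacian",
                 "hessian_eigenvalues", "difference_of_gaussians",
                 "structure_tensor_eigenvalues")
FAMILIES_3D <- c("identity", "gaussian", "derivatives_magnitude", "laplacian",
                 "structure_tensor_eigenvalues")

#' Feature configuration for the pixel classifier
#'
#' Defines the smoothing scales and filter families of the feature stack.
#' The identity plane is always included. Available families are
#' `identity`, `gaussian`, `gradient_magnitude`, `laplacian`,
#' `hessian_eigenvalues`, `difference_of_gaussians`,
#' `structure_tensor_eigenvalues` in 2D and `identity`, `gaussian`,
#' `derivatives_magnitude`, `laplacian`, `structure_tensor_eigenvalues`
#' in 3D (`derivatives_magnitude` is the 3D name of the gradient-magnitude
#' filter).
#'
#' @param ndim image dimensionality the configuration applies to (2 or 3).
#' @param sigmas strictly increasing positive smoothing scales in pixels.
#'   Defaults: `c(1, 2, 4, 8, 16)` in 2D, `c(1, 2, 4)` in 3D.
#' @param families character vector of feature families; defaults to
#'   `identity`, `gaussian`, gradient magnitude, `laplacian` plus Hessian
#'   eigenvalues (2D) or structure-tensor eigenvalues (3D).
#' @return An object of class `feature_config`.
#' @export
feature_config <- function(ndim = 2L, sigmas = NULL, families = NULL) {
  ndim <- as.integer(ndim)
  if (!ndim %in% c(2L, 3L)) stopf("ndim must be 2 or 3")
  if (is.null(sigmas)) sigmas <- if (ndim == 2L) c(1, 2, 4, 8, 16) else c(1, 2, 4)
  if (any(sigmas <= 0) || is.unsorted(sigmas, strictly = TRUE))
    stopf("sigmas must be positive and strictly increasing")
  avail <- if (ndim == 2L) FAMILIES_2D else FAMILIES_3D
  if (is.null(families))
    families <- if (ndim == 2L)
      c("identity", "gaussian", "gradient_magnitude", "laplacian",
        "hessian_eigenvalues")
    else
      c("identity", "gaussian", "derivatives_magnitude", "laplacian",
        "structure_tensor_eigenvalues")
  bad <- setdiff(families, avail)
  if (length(bad)) stopf("unknown %dD feature families: %s", ndim,
                         paste(bad, collapse = ", "))
  if (!length(families)) stopf("at least one feature family is required")
  families <- union("identity", families)
  structure(list(ndim = ndim, sigmas = as.numeric(sigmas),
                 families = families),
            class = "feature_config")
}

#' Number of feature planes produced by a configuration
#'
#' Identity contributes one plane; each scalar family contributes one plane
#' per sigma; eigenvalue families contribute `ndim` planes per sigma;
#' difference of Gaussians contributes one plane per ordered sigma pair.
#'
#' @param cfg a [feature_config()].
#' @return Integer plane count.
#' @export
n_feature_planes <- function(cfg) {
  ns <- length(cfg$sigmas)
  per <- vapply(cfg$families, function(f) switch(
    f,
    identity = 1L,
    difference_of_gaussians = as.integer(ns * (ns - 1) / 2),
    hessian_eigenvalues = ns * cfg$ndim,
    structure_tensor_eigenvalues = ns * cfg$ndim,
    ns
  ), 1L)
  sum(per)
}

#' Compute the feature stack of an image
#'
#' @param image a [calibrated_image()].
#' @param cfg a [feature_config()] matching the image dimensionality.
#' @return An object of class `feature_stack`: a pixel-by-feature matrix
#'   (`$values`, pixels in array scan order) plus the spatial `$dim`,
#'   `$feature_names` and the `$cfg` used.
#' @export
compute_feature_stack <- function(image, cfg) {
  stopifnot(inherits(image, "calibrated_image"), inherits(cfg, "feature_config"))
  x <- image$data
  nd <- ndim_of(x)
  if (nd != cfg$ndim)
    stopf("image is %dD but feature config is %dD", nd, cfg$ndim)
  planes <- list()
  nm <- character(0)
  add <- function(p, name) {
    planes[[length(planes) + 1L]] <<- as.numeric(p)
    nm[length(nm) + 1L] <<- name
  }
  smooth_cache <- lapply(cfg$sigmas, function(s) gaussian_smooth(x, s))
  names(smooth_cache) <- as.character(cfg$sigmas)
  for (fam in cfg$families) {
    if (fam == "identity") { add(x, "identity"); next }
    if (fam == "difference_of_gaussians") {
      ns <- length(cfg$sigmas)
      if (ns >= 2) for (i in 1:(ns - 1)) for (j in (i + 1):ns)
        add(smooth_cache[[i]] - smooth_cache[[j]],
            sprintf("dog_s%g_s%g", cfg$sigmas[i], cfg$sigmas[j]))
      next
    }
    for (si in seq_along(cfg$sigmas)) {
      s <- cfg$sigmas[si]
      sm <- smooth_cache[[si]]
      if (fam == "gaussian") add(sm, sprintf("gaussian_s%g", s))
      else if (fam %in% c("gradient_magnitude", "derivatives_magnitude")) {
        g <- lapply(seq_len(nd), function(a) central_diff(sm, a))
        add(sqrt(Reduce(`+`, lapply(g, function(v) v^2))),
            sprintf("%s_s%g", fam, s))
      } else if (fam == "laplacian") {
        add(Reduce(`+`, lapply(seq_len(nd), function(a) second_diff(sm, a))),
            sprintf("laplacian_s%g", s))
      } else if (fam == "hessian_eigenvalues") {
        ev <- hessian_eigen2d(sm)
        add(ev$hi, sprintf("hessian_eig1_s%g", s))
        add(ev$lo, sprintf("hessian_eig2_s%g", s))
      } else if (fam == "structure_tensor_eigenvalues") {
        ev <- structure_tensor_eigen(sm, s)
        for (k in seq_along(ev))
          add(ev[[k]], sprintf("structure_eig%d_s%g", k, s))
      }
    }
  }
  values <- do.call(cbind, planes)
  colnames(values) <- nm
  if (!all(is.finite(values))) stopf("feature stack contains non-finite values")
  structure(list(values = values, dim = dim(x), feature_names = nm, cfg = cfg),
            class = "feature_stack")
}

# -- filter primitives ------------------------------------------------------

# Sampled, normalised Gaussian kernel.
gaussian_kernel <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k / sum(k)
}

# Convolve an array along one axis with reflect padding.
convolve_axis <- function(x, k, axis) {
  dm <- dim(x)
  nd <- length(dm)
  perm <- c(axis, seq_len(nd)[-axis])
  y <- aperm(x, perm)
  n <- dm[axis]
  m <- prod(dm[-axis])
  y <- matrix(y, n, m)
  r <- (length(k) - 1L) / 2L
  idx <- reflect_index(seq_len(n + 2L * r) - r, n)
  yp <- y[idx, , drop = FALSE]
  out <- matrix(0, n, m)
  for (j in seq_along(k)) out <- out + k[j] * yp[j:(j + n - 1L), , drop = FALSE]
  out <- array(out, dm[perm])
  aperm(out, order(perm))
}

# Reflect (mirror without repeating the edge sample twice at size > 1)
# out-of-range 1-based indices into 1..n.
reflect_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  period <- 2L * n
  j <- (i - 1L) %% period
  j <- ifelse(j >= n, period - 1L - j, j)
  as.integer(j + 1L)
}

gaussian_smooth <- function(x, sigma) {
  k <- gaussian_kernel(sigma)
  for (a in seq_along(dim(x))) x <- convolve_axis(x, k, a)
  x
}

# Central first/second differences along one axis, reflect padding.
central_diff <- function(x, axis) {
  (shift_axis(x, axis, 1L) - shift_axis(x, axis, -1L)) / 2
}

second_diff <- function(x, axis) {
  shift_axis(x, axis, 1L) - 2 * x + shift_axis(x, axis, -1L)
}

# x shifted so result[i] = x[i + by] with reflected border.
shift_axis <- function(x, axis, by) {
  dm <- dim(x)
  idx <- lapply(seq_along(dm), function(a) seq_len(dm[a]))
  idx[[axis]] <- reflect_index(idx[[axis]] + by, dm[axis])
  do.call(`[`, c(list(x), idx, list(drop = FALSE)))
}

# Eigenvalues (ordered high/low) of the 2D Hessian of a smoothed image.
hessian_eigen2d <- function(sm) {
  hxx <- second_diff(sm, 1L)
  hyy <- second_diff(sm, 2L)
  hxy <- central_diff(central_diff(sm, 1L), 2L)
  tr2 <- (hxx + hyy) / 2
  d <- sqrt(((hxx - hyy) / 2)^2 + hxy^2)
  list(hi = tr2 + d, lo = tr2 - d)
}

# Eigenvalues of the structure tensor (gradient outer product smoothed at
# the same scale), descending. Returns a list of ndim arrays.
structure_tensor_eigen <- function(sm, sigma) {
  nd <- ndim_of(sm)
  g <- lapply(seq_len(nd), function(a) central_diff(sm, a))
  k <- gaussian_kernel(sigma)
  smth <- function(v) { for (a in seq_len(nd)) v <- convolve_axis(v, k, a); v }
  if (nd == 2L) {
    j11 <- smth(g[[1]]^2); j22 <- smth(g[[2]]^2); j12 <- smth(g[[1]] * g[[2]])
    tr2 <- (j11 + j22) / 2
    d <- sqrt(((j11 - j22) / 2)^2 + j12^2)
    list(tr2 + d, tr2 - d)
  } else {
    a11 <- smth(g[[1]]^2); a22 <- smth(g[[2]]^2); a33 <- smth(g[[3]]^2)
    a12 <- smth(g[[1]] * g[[2]]); a13 <- smth(g[[1]] * g[[3]])
    a23 <- smth(g[[2]] * g[[3]])
    sym3_eigenvalues(a11, a22, a33, a12, a13, a23)
  }
}

# Analytic eigenvalues of a field of symmetric 3x3 matrices, descending.
sym3_eigenvalues <- function(a11, a22, a33, a12, a13, a23) {
  q <- (a11 + a22 + a33) / 3
  p2 <- (a11 - q)^2 + (a22 - q)^2 + (a33 - q)^2 +
    2 * (a12^2 + a13^2 + a23^2)
  p <- sqrt(pmax(p2, 0) / 6)
  safe_p <- ifelse(p > 0, p, 1)
  b11 <- (a11 - q) / safe_p; b22 <- (a22 - q) / safe_p; b33 <- (a33 - q) / safe_p
  b12 <- a12 / safe_p; b13 <- a13 / safe_p; b23 <- a23 / safe_p
  detb <- b11 * (b22 * b33 - b23^2) - b12 * (b12 * b33 - b23 * b13) +
    b13 * (b12 * b23 - b22 * b13)
  r <- clamp(detb / 2, -1, 1)
  phi <- acos(r) / 3
  e1 <- q + 2 * p * cos(phi)
  e3 <- q + 2 * p * cos(phi + 2 * pi / 3)
  e2 <- 3 * q - e1 - e3
  zero <- p2 <= 0
  e1[zero] <- q[zero]; e2[zero] <- q[zero]; e3[zero] <- q[zero]
  dm <- dim(a11)
  list(array(e1, dm), array(e2, dm), array(e3, dm))
}
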
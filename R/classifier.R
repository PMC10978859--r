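# Trainable random-forest pixel classification.
#
# The classifier maps per-pixel feature vectors to class vote fractions,
# the standard trainable-segmentation design: sparse user annotations are
# turned into a training set, a random forest is fitted, and prediction
# yields one probability channel per class.

#' Annotation set for classifier training
#'
#' Sparse pixel labels. Coordinates are 1-based array indices
#' (`row`, `col`, and `plane` for 3D); `class` is an integer in
#' `1..length(class_names)`; `stack` indexes the feature stack the
#' annotation refers to when training on several images at once.
#'
#' @param coords data frame or matrix with columns `row`, `col`
#'   (and `plane` for 3D).
#' @param class integer class index per annotation (1-based).
#' @param class_names character vector of at least two class names. By
#'   convention class 1 is the background.
#' @param stack integer stack index per annotation (default 1).
#' @return An object of class `annotation_set`.
#' @export
annotation_set <- function(coords, class, class_names, stack = 1L) {
  coords <- as.data.frame(coords)
  need <- intersect(c("row", "col", "plane"), names(coords))
  if (!all(c("row", "col") %in% need))
    stopf("`coords` needs columns row, col (and plane for 3D)")
  if (length(class_names) < 2L) stopf("a minimum of two classes is required")
  class <- as.integer(class)
  if (length(class) != nrow(coords)) stopf("one class per coordinate required")
  if (any(class < 1L) || any(class > length(class_names)))
    stopf("class indices must lie in 1..%d", length(class_names))
  stack <- rep_len(as.integer(stack), nrow(coords))
  structure(list(coords = coords[, need, drop = FALSE], class = class,
                 class_names = as.character(class_names), stack = stack),
            class = "annotation_set")
}

#' Train a random-forest pixel classifier
#'
#' @param stacks a [compute_feature_stack()] result or a list of them
#'   (all sharing one [feature_config()]).
#' @param annotations an [annotation_set()]; every class must have at
#'   least one label and all coordinates must lie inside the annotated
#'   stack.
#' @param n_trees number of trees (default 200).
#' @param seed RNG seed controlling forest growth; the same stacks,
#'   annotations and seed always reproduce the same classifier.
#' @return An object of class `pixel_classifier` holding the forest, the
#'   feature configuration and the class names.
#' @export
train_pixel_classifier <- function(stacks, annotations, n_trees = 200L,
                                   seed = 17L) {
  if (inherits(stacks, "feature_stack")) stacks <- list(stacks)
  stopifnot(all(vapply(stacks, inherits, TRUE, "feature_stack")),
            inherits(annotations, "annotation_set"))
  cfg <- stacks[[1]]$cfg
  for (s in stacks) if (!identical(s$cfg, cfg))
    stopf("all stacks must share one feature configuration")
  k <- length(annotations$class_names)
  present <- tabulate(annotations$class, k)
  if (any(present == 0L))
    stopf("class '%s' has no labelled pixels",
          annotations$class_names[which(present == 0L)[1]])
  if (any(annotations$stack < 1L | annotations$stack > length(stacks)))
    stopf("annotation stack index out of range")
  rows <- lapply(seq_along(stacks), function(i) {
    sel <- annotations$stack == i
    if (!any(sel)) return(NULL)
    co <- as.matrix(annotations$coords[sel, , drop = FALSE])
    dm <- stacks[[i]]$dim
    if (ncol(co) != length(dm))
      stopf("annotation coordinates are %dD but stack %d is %dD",
            ncol(co), i, length(dm))
    if (any(co < 1L) || any(sweep(co, 2L, dm, `>`)))
      stopf("annotation coordinates out of image bounds")
    stacks[[i]]$values[coord_to_index(co, dm), , drop = FALSE]
  })
  x <- do.call(rbind, rows)
  # rows were gathered stack by stack; order() is stable, so labels align
  ord <- order(annotations$stack)
  y <- factor(annotations$class_names[annotations$class[ord]],
              levels = annotations$class_names)
  n_feat <- ncol(x)
  forest <- with_seed(seed, randomForest::randomForest(
    x = x, y = y, ntree = n_trees, mtry = ceiling(sqrt(n_feat))))
  structure(list(forest = forest, cfg = cfg,
                 class_names = annotations$class_names,
                 n_trees = as.integer(n_trees), seed = as.integer(seed),
                 feature_names = stacks[[1]]$feature_names),
            class = "pixel_classifier")
}

#' @export
print.pixel_classifier <- function(x, ...) {
  cat(sprintf("<pixel_classifier> %d classes (%s), %d trees, %d features\n",
              length(x$class_names), paste(x$class_names, collapse = ", "),
              x$n_trees, length(x$feature_names)))
  invisible(x)
}

#' Predict the per-class probability map of an image
#'
#' Computes the classifier's feature stack for `image` and evaluates the
#' forest at every pixel; channel `k` holds the vote fraction for class
#' `k`, so the channels sum to one at every pixel.
#'
#' @param image a [calibrated_image()] whose dimensionality matches the
#'   classifier's feature configuration.
#' @param clf a [train_pixel_classifier()] result.
#' @return An object of class `probability_map`: array with one trailing
#'   channel axis per class, plus calibration and class names.
#' @export
predict_probability_map <- function(image, clf) {
  stopifnot(inherits(image, "calibrated_image"),
            inherits(clf, "pixel_classifier"))
  if (ndim_of(image$data) != clf$cfg$ndim)
    stopf("image is %dD but classifier expects %dD",
          ndim_of(image$data), clf$cfg$ndim)
  fs <- compute_feature_stack(image, clf$cfg)
  pr <- stats::predict(clf$forest, newdata = fs$values, type = "prob")
  pr <- pr[, clf$class_names, drop = FALSE]
  probability_map(array(pr, c(fs$dim, ncol(pr))),
                  class_names = clf$class_names,
                  calibration = image$calibration, unit = image$unit)
}

#' Probability map container
#'
#' @param data array with spatial axes plus one trailing channel axis;
#'   channels must sum to 1 (within 1e-6) at every pixel.
#' @param class_names one name per channel.
#' @inheritParams calibrated_image
#' @return An object of class `probability_map`.
#' @export
probability_map <- function(data, class_names, calibration = 1,
                            unit = "pixel") {
  dm <- dim(data)
  k <- dm[length(dm)]
  if (k != length(class_names)) stopf("channel count must equal class count")
  if (any(data < -1e-9 | data > 1 + 1e-9)) stopf("probabilities outside [0,1]")
  sums <- apply(data, seq_len(length(dm) - 1L), sum)
  if (any(abs(sums - 1) > 1e-6))
    stopf("per-pixel channel probabilities must sum to 1")
  nd <- length(dm) - 1L
  calibration <- as.numeric(calibration)
  if (length(calibration) == 1L) calibration <- rep(calibration, nd)
  structure(list(data = data, class_names = as.character(class_names),
                 calibration = calibration, unit = unit),
            class = "probability_map")
}

#' @export
print.probability_map <- function(x, ...) {
  dm <- dim(x$data)
  cat(sprintf("<probability_map> %s, classes: %s\n",
              paste(dm[-length(dm)], collapse = "x"),
              paste(x$class_names, collapse = ", ")))
  invisible(x)
}

#' Save a probability map as multi-page 32-bit float TIFF
#'
#' Channels become pages (2D input) or channel-major blocks of planes
#' (3D input).
#'
#' @param pmap a [probability_map()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_probability_map <- function(pmap, path) {
  stopifnot(inherits(pmap, "probability_map"))
  dm <- dim(pmap$data)
  nd <- length(dm) - 1L
  pages <- list()
  for (ch in seq_len(dm[length(dm)])) {
    chan <- if (nd == 2L) pmap$data[, , ch] else pmap$data[, , , ch]
    pages <- c(pages, image_planes(chan))
  }
  write_float_tiff(pages, path)
}

#' Persist a pixel classifier to disk
#'
#' The archive stores the forest, feature configuration and class names
#' together so a reloaded classifier predicts identically; see
#' [load_pixel_classifier()].
#'
#' @param clf a `pixel_classifier`.
#' @param path output path (conventionally `.rds`).
#' @return `path`, invisibly.
#' @export
save_pixel_classifier <- function(clf, path) {
  stopifnot(inherits(clf, "pixel_classifier"))
  saveRDS(list(format = "filamorph_pixel_classifier", version = 1L,
               classifier = clf), path)
  invisible(path)
}

#' Load a pixel classifier archive
#'
#' @param path path written by [save_pixel_classifier()].
#' @param expected_cfg optional [feature_config()]; if supplied and it
#'   differs from the archived configuration, loading fails rather than
#'   silently recomputing features differently.
#' @return A `pixel_classifier`.
#' @export
load_pixel_classifier <- function(path, expected_cfg = NULL) {
  if (!file.exists(path)) stopf("classifier archive not found: %s", path)
  obj <- readRDS(path)
  if (!is.list(obj) || !identical(obj$format, "filamorph_pixel_classifier"))
    stopf("'%s' is not a pixel-classifier archive", path)
  clf <- obj$classifier
  if (!is.null(expected_cfg) && !identical(clf$cfg, expected_cfg))
    stopf("archived classifier was trained under a different feature %s",
          "configuration")
  clf
}
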
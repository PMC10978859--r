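# Independent oracles and shared fixtures. The oracles deliberately use
# different algorithms from the package (flood fill vs graph components,
# pairwise distance matrices vs separable transform + painting, dense
# convolution vs separable) so agreement is informative.

# Flood-fill connected-component oracle: explicit queue BFS.
oracle_flood_fill <- function(fg) {
  dm <- dim(fg)
  nd <- length(dm)
  offs <- as.matrix(do.call(expand.grid, rep(list(-1:1), nd)))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  lab <- array(0L, dm)
  cur <- 0L
  todo <- which(fg)
  for (s in todo) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    queue <- list(arrayInd(s, dm)[1, ])
    lab[s] <- cur
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (k in seq_len(nrow(offs))) {
        q <- p + offs[k, ]
        if (any(q < 1) || any(q > dm)) next
        qi <- sum((q - 1) * cumprod(c(1, dm[-nd]))) + 1
        if (fg[qi] && lab[qi] == 0L) {
          lab[qi] <- cur
          queue[[length(queue) + 1L]] <- q
        }
      }
    }
  }
  list(n = cur, labels = lab,
       sizes = if (cur) as.integer(table(lab[lab > 0L])) else integer(0))
}

# Brute-force largest-inscribed-ball thickness oracle, straight from the
# definition: dt(c) by minimising over all background pixels, then
# thickness(p) = max 2*dt(c) over centres whose ball contains p.
oracle_local_thickness <- function(fg, spacing = rep(1, length(dim(fg)))) {
  dm <- dim(fg)
  out <- array(NA_real_, dm)
  fgi <- which(fg)
  if (!length(fgi)) return(out)
  co <- arrayInd(seq_len(prod(dm)), dm)
  cof <- sweep(co[fgi, , drop = FALSE], 2, spacing, `*`)
  bgi <- which(!fg)
  if (!length(bgi)) { out[fg] <- Inf; return(out) }
  cob <- sweep(co[bgi, , drop = FALSE], 2, spacing, `*`)
  sq <- function(a, b) {
    # squared distances between rows of a and rows of b
    outer(rowSums(a^2), rep(1, nrow(b))) +
      outer(rep(1, nrow(a)), rowSums(b^2)) - 2 * a %*% t(b)
  }
  dt2 <- apply(sq(cof, cob), 1, min)
  d2 <- sq(cof, cof)
  contains <- d2 <= matrix(dt2, nrow(cof), nrow(cof), byrow = TRUE) + 1e-9
  th <- vapply(seq_len(nrow(cof)), function(i)
    2 * sqrt(max(dt2[contains[i, ]])), 1)
  out[fgi] <- th
  out
}

# Dense (non-separable) Gaussian convolution oracle with reflect padding.
oracle_gaussian_dense <- function(x, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k1 <- dnorm(-r:r, sd = sigma); k1 <- k1 / sum(k1)
  k2 <- outer(k1, k1)
  dm <- dim(x)
  refl <- function(i, n) {
    period <- 2L * n
    j <- (i - 1L) %% period
    ifelse(j >= n, period - 1L - j, j) + 1L
  }
  out <- array(0, dm)
  for (dr in -r:r) for (dc in -r:r) {
    xr <- x[refl(seq_len(dm[1]) + dr, dm[1]),
            refl(seq_len(dm[2]) + dc, dm[2]), drop = FALSE]
    out <- out + k2[dr + r + 1, dc + r + 1] * xr
  }
  out
}

# Digital disk mask of radius r centred in an n x n raster.
mk_disk <- function(r, n = 2 * r + 9, center = c((n + 1) / 2, (n + 1) / 2)) {
  co <- as.matrix(expand.grid(seq_len(n), seq_len(n)))
  array((co[, 1] - center[1])^2 + (co[, 2] - center[2])^2 <= r^2, c(n, n))
}

# Horizontal 2D tube mask: rows centred on `row0` (use a half-integer for
# generic grid placement), columns c0..c1.
mk_band <- function(dm, row0, r, c0, c1) {
  m <- array(FALSE, dm)
  rows <- which(abs(seq_len(dm[1]) - row0) <= r)
  m[rows, c0:c1] <- TRUE
  m
}

# Axis-aligned 3D tube mask with integer cross-section centre.
mk_tube3d <- function(dm, yc, zc, r, x0, x1) {
  co <- as.matrix(expand.grid(seq_len(dm[1]), seq_len(dm[2]), seq_len(dm[3])))
  sel <- (co[, 2] - yc)^2 + (co[, 3] - zc)^2 <= r^2 &
    co[, 1] >= x0 & co[, 1] <= x1
  m <- array(FALSE, dm)
  m[co[sel, , drop = FALSE]] <- TRUE
  m
}

# Shared 5-tube study phantom: five disjoint horizontal tubes of radius 3
# at half-integer row positions over a dark background, noise free.
five_tube_phantom <- function(seed = 7, noise_sigma = 0) {
  tubes <- lapply(c(20.5, 50.5, 80.5, 110.5, 140.5), function(r0)
    phantom_tube(rbind(c(r0, 10.5), c(r0, 150.5)), radius = 3,
                 intensity = 200))
  generate_phantom(phantom_config(shape = c(160, 160), tubes = tubes,
                                  background = 20,
                                  noise_sigma = noise_sigma, seed = seed))
}

# Train a tube/background classifier on a phantom with `n_labels` labelled
# pixels per class.
train_tube_classifier <- function(ph, n_labels = 200, seed = 17,
                                  sigmas = c(1, 2, 4), label_seed = 42) {
  fc <- feature_config(2L, sigmas = sigmas)
  fs <- compute_feature_stack(ph$image, fc)
  dm <- dim(ph$image$data)
  set.seed(label_seed)
  fgi <- sample(which(ph$truth$tubes_mask), n_labels)
  bgi <- sample(which(!ph$truth$tubes_mask), n_labels)
  co <- arrayInd(c(bgi, fgi), dm)
  ann <- annotation_set(data.frame(row = co[, 1], col = co[, 2]),
                        class = rep(1:2, each = n_labels),
                        class_names = c("background", "tube"))
  train_pixel_classifier(fs, ann, n_trees = 200, seed = seed)
}

# Build a ready-to-run pipeline folder (phantom image + classifier) and
# return the config list. Used by the pipeline and acceptance tests.
make_pipeline_fixture <- function(root, seed = 11) {
  img_dir <- file.path(root, "images")
  dir.create(img_dir, recursive = TRUE, showWarnings = FALSE)
  tubes <- lapply(c(30.5, 90.5), function(r0)
    phantom_tube(rbind(c(r0, 10.5), c(r0, 110.5)), 3, 120))
  blobs <- list(phantom_blob(c(60.5, 40.5), 10, 220),
                phantom_blob(c(60.5, 90.5), 10, 220),
                phantom_blob(c(60.5, 40.5), 4, 250),
                phantom_blob(c(60.5, 90.5), 4, 250))
  ph <- generate_phantom(phantom_config(shape = c(120, 120), tubes = tubes,
                                        blobs = blobs, background = 20,
                                        noise_sigma = 0, seed = 3))
  save_calibrated_image(ph$image, file.path(img_dir, "phantom.tif"))
  fc <- feature_config(2L, sigmas = c(1, 2, 4))
  fs <- compute_feature_stack(ph$image, fc)
  soma <- ph$truth$blob_masks[[1]] | ph$truth$blob_masks[[2]]
  nuc <- ph$truth$blob_masks[[3]] | ph$truth$blob_masks[[4]]
  lab <- array(1L, c(120, 120))
  lab[ph$truth$tubes_mask] <- 2L; lab[soma] <- 3L; lab[nuc] <- 4L
  set.seed(5)
  samp <- unlist(lapply(1:4, function(k) {
    w <- which(lab == k); sample(w, min(150, length(w)))
  }))
  co <- arrayInd(samp, c(120, 120))
  ann <- annotation_set(data.frame(row = co[, 1], col = co[, 2]),
                        class = lab[samp],
                        class_names = c("background", "tube", "soma",
                                        "nucleus"))
  clf <- train_pixel_classifier(fs, ann, seed = 17)
  clf_path <- file.path(root, "classifier.rds")
  save_pixel_classifier(clf, clf_path)
  thr_tube <- list(prob_min = 0.5, size_min = 20, size_units = "pixels")
  list(image_folder = img_dir,
       modes = c("neural_projections", "soma_and_nuclei",
                 "area_number_intensity", "length_and_branching", "width",
                 "colocalization"),
       channels = list(
         main = list(channel = 1, classifier = clf_path, class = "tube",
                     thresholds = thr_tube),
         soma = list(channel = 1, classifier = clf_path, class = "soma",
                     thresholds = list(prob_min = 0.5, size_min = 20,
                                       size_units = "pixels")),
         nuclei = list(channel = 1, classifier = clf_path,
                       class = "nucleus",
                       thresholds = list(prob_min = 0.5, size_min = 5,
                                         size_units = "pixels")),
         partner = list(channel = 1, classifier = clf_path, class = "soma",
                        thresholds = list(prob_min = 0.5, size_min = 20,
                                          size_units = "pixels"))),
       histogram = list(n_bins = 10, width_min = 0, width_max = 20),
       seed = seed, phantom = NULL)
}

# Memoised fixture cache shared across test files.
.fixture_env <- new.env(parent = emptyenv())
fixture <- function(name, builder) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}
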
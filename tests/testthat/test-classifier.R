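# A small two-class intensity phantom: foreground blocks at 200 +/- 5 over
# background 20 +/- 5, trivially separable by intensity features.
make_two_class <- function(seed = 1, n = 48) {
  set.seed(seed)
  fg <- array(FALSE, c(n, n))
  fg[round(n * 0.2):round(n * 0.4), round(n * 0.2):round(n * 0.8)] <- TRUE
  fg[round(n * 0.6):round(n * 0.85), round(n * 0.15):round(n * 0.45)] <- TRUE
  img <- array(rnorm(n * n, 20, 5), c(n, n))
  img[fg] <- rnorm(sum(fg), 200, 5)
  list(image = calibrated_image(img), fg = fg)
}

sample_annotations <- function(fg, n_per_class, seed) {
  set.seed(seed)
  dm <- dim(fg)
  fgi <- sample(which(fg), n_per_class)
  bgi <- sample(which(!fg), n_per_class)
  co <- arrayInd(c(bgi, fgi), dm)
  annotation_set(data.frame(row = co[, 1], col = co[, 2]),
                 class = rep(1:2, each = n_per_class),
                 class_names = c("background", "object"))
}

test_that("well-separated classes are learned with high held-out accuracy", {
  tc <- make_two_class()
  cfg <- feature_config(2L, sigmas = c(1, 2))
  fs <- compute_feature_stack(tc$image, cfg)
  ann <- sample_annotations(tc$fg, 100, seed = 2)
  clf <- train_pixel_classifier(fs, ann, n_trees = 100, seed = 17)
  pm <- predict_probability_map(tc$image, clf)
  pred_fg <- pm$data[, , 2] >= 0.5
  held_out <- setdiff(seq_along(tc$fg), arrayInd(1, dim(tc$fg)))
  acc <- mean(pred_fg == tc$fg)
  expect_gt(acc, 0.99)
  # probability normalisation at every pixel
  expect_lt(max(abs(pm$data[, , 1] + pm$data[, , 2] - 1)), 1e-6)
})

test_that("degenerate annotation sets are rejected", {
  tc <- make_two_class()
  fs <- compute_feature_stack(tc$image, feature_config(2L, sigmas = 1))
  co <- arrayInd(which(tc$fg)[1:10], dim(tc$fg))
  one_class <- annotation_set(data.frame(row = co[, 1], col = co[, 2]),
                              class = rep(2L, 10),
                              class_names = c("background", "object"))
  expect_error(train_pixel_classifier(fs, one_class), "no labelled")
  expect_error(annotation_set(data.frame(row = 1, col = 1), class = 1,
                              class_names = "one"), "two classes")
  oob <- annotation_set(data.frame(row = c(1, 500), col = c(1, 500)),
                        class = c(1L, 2L),
                        class_names = c("background", "object"))
  expect_error(train_pixel_classifier(fs, oob), "bounds")
})

test_that("training is deterministic and survives a save/load round trip", {
  tc <- make_two_class()
  cfg <- feature_config(2L, sigmas = c(1, 2))
  fs <- compute_feature_stack(tc$image, cfg)
  ann <- sample_annotations(tc$fg, 60, seed = 3)
  clf1 <- train_pixel_classifier(fs, ann, n_trees = 50, seed = 17)
  clf2 <- train_pixel_classifier(fs, ann, n_trees = 50, seed = 17)
  pm1 <- predict_probability_map(tc$image, clf1)
  pm2 <- predict_probability_map(tc$image, clf2)
  expect_identical(pm1$data, pm2$data)
  tmp <- withr::local_tempdir()
  path <- file.path(tmp, "clf.rds")
  save_pixel_classifier(clf1, path)
  clf3 <- load_pixel_classifier(path)
  expect_identical(predict_probability_map(tc$image, clf3)$data, pm1$data)
  # loading under a conflicting feature configuration is an error
  other <- feature_config(2L, sigmas = c(1, 2, 4))
  expect_error(load_pixel_classifier(path, expected_cfg = other),
               "different feature")
  expect_silent(load_pixel_classifier(path, expected_cfg = cfg))
})

test_that("a single-tree forest yields vote fractions in {0, 1}", {
  tc <- make_two_class()
  fs <- compute_feature_stack(tc$image, feature_config(2L, sigmas = 1))
  ann <- sample_annotations(tc$fg, 40, seed = 4)
  clf <- train_pixel_classifier(fs, ann, n_trees = 1, seed = 17)
  pm <- predict_probability_map(tc$image, clf)
  expect_true(all(pm$data %in% c(0, 1)))
})

test_that("exhaustive self-labelling is reproduced almost perfectly", {
  tc <- make_two_class(n = 32)
  cfg <- feature_config(2L, sigmas = 1)
  fs <- compute_feature_stack(tc$image, cfg)
  co <- arrayInd(seq_along(tc$fg), dim(tc$fg))
  ann <- annotation_set(data.frame(row = co[, 1], col = co[, 2]),
                        class = ifelse(tc$fg, 2L, 1L),
                        class_names = c("background", "object"))
  clf <- train_pixel_classifier(fs, ann, n_trees = 60, seed = 17)
  pm <- predict_probability_map(tc$image, clf)
  argmax_fg <- pm$data[, , 2] > pm$data[, , 1]
  expect_gt(mean(argmax_fg == tc$fg), 0.99)
})

test_that("class decisions are stable under feature-family reordering", {
  tc <- make_two_class()
  fam_a <- c("identity", "gaussian", "gradient_magnitude")
  fam_b <- c("gradient_magnitude", "gaussian", "identity")
  cls <- lapply(list(fam_a, fam_b), function(fams) {
    cfg <- feature_config(2L, sigmas = c(1, 2), families = fams)
    fs <- compute_feature_stack(tc$image, cfg)
    ann <- sample_annotations(tc$fg, 80, seed = 5)
    clf <- train_pixel_classifier(fs, ann, n_trees = 100, seed = 17)
    pm <- predict_probability_map(tc$image, clf)
    pm$data[, , 2] >= 0.5
  })
  expect_gt(mean(cls[[1]] == cls[[2]]), 0.99)
})

test_that("thresholding the foreground channel recovers a disjoint-support phantom", {
  tc <- make_two_class(seed = 9)
  fs <- compute_feature_stack(tc$image, feature_config(2L, sigmas = c(1, 2)))
  ann <- sample_annotations(tc$fg, 100, seed = 6)
  clf <- train_pixel_classifier(fs, ann, n_trees = 100, seed = 17)
  pm <- predict_probability_map(tc$image, clf)
  pred <- pm$data[, , 2] >= 0.5
  # ignore a 1-pixel boundary band around the true objects
  band <- dilate_mask(binary_mask(tc$fg), 1.5)$data &
    dilate_mask(binary_mask(!tc$fg), 1.5)$data
  interior <- !band
  expect_lt(mean(pred[interior] != tc$fg[interior]), 0.01)
})
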
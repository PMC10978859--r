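make_pmap <- function(chan_fg) {
  k <- array(0, c(dim(chan_fg), 2))
  k[, , 2] <- chan_fg
  k[, , 1] <- 1 - chan_fg
  probability_map(k, class_names = c("background", "object"))
}

test_that("probability thresholding follows the >= convention", {
  chan <- matrix(0.1, 8, 8)
  chan[c(3, 20, 40)] <- 0.9
  pmap <- make_pmap(chan)
  m <- extract_class_mask(pmap, "object", 0.5)
  expect_equal(sum(m$data), 3L)
  expect_equal(sum(extract_class_mask(pmap, 2L, 0)$data), 64L)
  tie <- matrix(0.1, 4, 4); tie[2, 2] <- 0.5
  expect_true(extract_class_mask(make_pmap(tie), 2L, 0.5)$data[2, 2])
  expect_error(extract_class_mask(pmap, 5L), "out of range")
})

test_that("size bounds keep exactly the objects inside the window", {
  m <- matrix(FALSE, 30, 30)
  m[2, 2:3] <- TRUE                      # 2 px
  m[10:11, 10:14] <- TRUE                # 10 px
  m[20:24, 15:24] <- TRUE                # 50 px
  mask <- binary_mask(m)
  out <- refine_mask(mask, cfg = threshold_config(size_min = 5,
                                                  size_units = "pixels"))
  expect_equal(count_components(out), 2L)
  expect_equal(sum(out$data), 60L)
  out2 <- refine_mask(mask, cfg = threshold_config(size_min = 5,
                                                   size_max = 20,
                                                   size_units = "pixels"))
  expect_equal(sum(out2$data), 10L)
  # physical units: pixel size 0.5 -> areas {0.5, 2.5, 12.5}
  maskc <- binary_mask(m, calibration = 0.5)
  outp <- refine_mask(maskc, cfg = threshold_config(size_min = 1,
                                                    size_max = 3))
  expect_equal(sum(outp$data), 10L)
})

test_that("a circularity bound separates a disk from a thin line", {
  co <- as.matrix(expand.grid(1:40, 1:60))
  m <- array((co[, 1] - 18)^2 + (co[, 2] - 18)^2 <= 64, c(40, 60))  # disk
  m[35, 20:49] <- TRUE                    # 30 px line
  rec <- measure_particles(binary_mask(m))
  expect_equal(nrow(rec), 2L)
  expect_true(any(rec$shape > 0.8) && any(rec$shape < 0.5))
  out <- refine_mask(binary_mask(m), cfg = threshold_config(circ_min = 0.5))
  expect_equal(count_components(out), 1L)
  rec_out <- measure_particles(out)
  expect_gt(rec_out$shape, 0.8)
})

test_that("edge exclusion removes border-touching objects", {
  m <- matrix(FALSE, 20, 20)
  m[1, 5:8] <- TRUE                        # touches row 1
  m[10:12, 10:12] <- TRUE                  # interior
  out <- refine_mask(binary_mask(m),
                     cfg = threshold_config(exclude_edges = TRUE))
  expect_equal(count_components(out), 1L)
  expect_false(any(out$data[1, ]))
})

test_that("per-object mean-intensity bound uses the redirected image", {
  m <- matrix(FALSE, 20, 20)
  m[2:4, 2:4] <- TRUE
  m[10:12, 10:12] <- TRUE
  img <- calibrated_image(matrix(10, 20, 20) +
                            ifelse(m & row(m) >= 10, 100, 0))
  out <- refine_mask(binary_mask(m), img,
                     threshold_config(intensity_min = 50))
  expect_equal(count_components(out), 1L)
  expect_true(all(which(out$data) %in% which(m & row(m) >= 10)))
  expect_error(refine_mask(binary_mask(m), cfg =
                             threshold_config(intensity_min = 50)),
               "input image")
})

test_that("refinement is idempotent, shrinking, and vacuous bounds are the identity", {
  set.seed(11)
  for (i in 1:5) {
    m <- matrix(runif(30 * 30) < 0.25, 30, 30)
    mask <- binary_mask(m)
    cfg <- threshold_config(size_min = 3, circ_min = 0.1,
                            size_units = "pixels")
    once <- refine_mask(mask, cfg = cfg)
    twice <- refine_mask(once, cfg = cfg)
    expect_identical(once$data, twice$data)
    expect_true(all(which(once$data) %in% which(m)))
    vac <- refine_mask(mask, cfg = threshold_config())
    expect_identical(vac$data, mask$data)
  }
})

test_that("tightening any bound never increases the object count", {
  set.seed(12)
  m <- matrix(runif(40 * 40) < 0.3, 40, 40)
  mask <- binary_mask(m)
  counts <- vapply(c(0, 2, 4, 8, 16), function(s)
    count_components(refine_mask(mask, cfg = threshold_config(
      size_min = s, size_units = "pixels"))), 1L)
  expect_true(all(diff(counts) <= 0))
  counts_c <- vapply(c(0, 0.2, 0.4, 0.6), function(cmin)
    count_components(refine_mask(mask, cfg = threshold_config(
      circ_min = cmin))), 1L)
  expect_true(all(diff(counts_c) <= 0))
})

test_that("threshold configs validate their bounds", {
  expect_error(threshold_config(prob_min = 1.5), "\\[0, 1\\]")
  expect_error(threshold_config(size_min = 10, size_max = 5), "size_min")
  expect_error(threshold_config(circ_min = 0.8, circ_max = 0.2),
               "circ_min")
})
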
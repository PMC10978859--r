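test_that("phantom generation is deterministic and respects its config", {
  cfg <- phantom_config(shape = c(80, 80),
                        tubes = list(phantom_tube(rbind(c(20.5, 6.5),
                                                        c(20.5, 73.5)),
                                                  3, 180)),
                        blobs = list(phantom_blob(c(55.5, 40.5), 8, 220)),
                        background = 15, noise_sigma = 4, seed = 9)
  p1 <- generate_phantom(cfg)
  p2 <- generate_phantom(cfg)
  expect_identical(p1$image$data, p2$image$data)
  expect_identical(p1$truth$tubes_mask, p2$truth$tubes_mask)
  # a different seed changes the noise but not the truth
  cfg2 <- cfg; cfg2$seed <- 10L
  p3 <- generate_phantom(cfg2)
  expect_false(identical(p1$image$data, p3$image$data))
  expect_identical(p1$truth$tubes_mask, p3$truth$tubes_mask)
})

test_that("noise-free phantoms only contain the configured levels plus edges", {
  cfg <- phantom_config(shape = c(60, 60),
                        tubes = list(phantom_tube(rbind(c(30.5, 5.5),
                                                        c(30.5, 54.5)),
                                                  2, 200)),
                        background = 10, noise_sigma = 0, seed = 1)
  ph <- generate_phantom(cfg)
  v <- ph$image$data
  # interior and background pixels sit exactly at the two levels; the
  # anti-aliased boundary band lies strictly between them
  expect_true(all(v >= 10 - 1e-9 & v <= 200 + 1e-9))
  expect_gt(sum(abs(v - 10) < 1e-9), 3000)
  expect_gt(sum(abs(v - 200) < 1e-9), 100)
})

test_that("five disjoint tubes yield the analytic foreground geometry", {
  ph <- fixture("five_tubes", five_tube_phantom)
  expect_equal(ph$truth$n_tubes, 5L)
  expect_equal(count_components(binary_mask(ph$truth$tubes_mask)), 5L)
  analytic <- 5 * 2 * 3 * 140
  rendered <- sum(ph$truth$tubes_mask)
  expect_lt(abs(rendered - analytic) / analytic, 0.10)
  expect_equal(ph$truth$tube_lengths, rep(140, 5))
  expect_equal(ph$truth$tube_diameters, rep(6, 5))
  # centerline pixels trace the polylines
  for (cl in ph$truth$centerlines)
    expect_true(all(ph$truth$tubes_mask[cl]))
})

test_that("structures outside the raster are rejected", {
  expect_error(phantom_config(shape = c(40, 40),
                              tubes = list(phantom_tube(rbind(c(5, 5),
                                                              c(5, 60)),
                                                        2, 100))),
               "outside")
  expect_error(phantom_config(shape = c(40, 40),
                              blobs = list(phantom_blob(c(2, 2), 5, 100))),
               "outside")
  expect_error(phantom_tube(rbind(c(1, 1)), 2, 10), "two control points")
  expect_error(phantom_blob(c(5, 5), -1, 10), "positive")
})

test_that("background gradients ramp linearly and clip to the value range", {
  cfg <- phantom_config(shape = c(30, 30), background = 10,
                        gradient = c(0, 100), seed = 1)
  ph <- generate_phantom(cfg)
  expect_equal(ph$image$data[15, 1], 10)
  expect_equal(ph$image$data[15, 30], 110)
  expect_equal(ph$image$data[15, 16] - ph$image$data[15, 15], 100 / 29)
})

test_that("validation rates reproduce the printed formula on constructions", {
  ph <- fixture("five_tubes", five_tube_phantom)
  truth <- ph$truth
  dm <- truth$shape
  # perfect recovery: the true centerlines themselves
  perfect <- array(FALSE, dm)
  perfect[unlist(truth$centerlines)] <- TRUE
  vr <- validation_rates(binary_mask(perfect), truth, kind = "length")
  expect_equal(vr$fp_rate, 0)
  expect_equal(vr$fn_rate, 0)
  # an off-centerline appendix adds ~10% false-positive length
  appendix <- perfect
  appendix[5, 10:79] <- TRUE     # 70 px far away from every tube
  vra <- validation_rates(binary_mask(appendix), truth, kind = "length")
  expect_gt(vra$fp_rate, 0.05)
  expect_lt(vra$fp_rate, 0.15)
  expect_equal(vra$fn_rate, 0)
  # dropping one of five tubes misses ~20% of the reference length
  partial <- array(FALSE, dm)
  partial[unlist(truth$centerlines[1:4])] <- TRUE
  vrp <- validation_rates(binary_mask(partial), truth, kind = "length")
  expect_equal(vrp$fn_rate, 0.2, tolerance = 0.02)
  expect_equal(vrp$fp_rate, 0)
})

test_that("count-based validation rates match object bookkeeping", {
  blobs <- lapply(seq_len(12), function(i) {
    r <- 10 + 20 * ((i - 1) %% 4); c <- 10 + 20 * ((i - 1) %/% 4)
    phantom_blob(c(r + 0.5, c + 0.5), 4, 200)
  })
  ph <- generate_phantom(phantom_config(shape = c(80, 80), blobs = blobs,
                                        background = 5, seed = 2))
  # object counting on the exact truth: 12 blobs, zero error rates
  mask <- binary_mask(ph$truth$blobs_mask)
  refined <- refine_mask(mask, cfg = threshold_config())
  expect_equal(count_components(refined), 12L)
  vr <- validation_rates(refined, ph$truth, kind = "count",
                         structures = "blobs")
  expect_equal(vr$fp_rate, 0)
  expect_equal(vr$fn_rate, 0)
  # one spurious object and one missed blob move both rates by 1/12
  spur <- ph$truth$blobs_mask
  spur[70:75, 70:75] <- TRUE
  spur[ph$truth$blob_masks[[1]]] <- FALSE
  vs <- validation_rates(binary_mask(spur), ph$truth, kind = "count",
                         structures = "blobs")
  expect_equal(vs$fp_rate, 1 / 12)
  expect_equal(vs$fn_rate, 1 / 12)
})

test_that("phantoms round trip through their TIFF + sidecar form", {
  tmp <- withr::local_tempdir()
  ph <- generate_phantom(phantom_config(
    shape = c(40, 40),
    tubes = list(phantom_tube(rbind(c(10.5, 5.5), c(10.5, 34.5)), 2, 150)),
    background = 12, seed = 4))
  img_path <- file.path(tmp, "ph.tif")
  save_phantom(ph, img_path)
  back <- load_calibrated_image(img_path)
  expect_lt(max(abs(back$data - ph$image$data)), 1e-4)
  side <- yaml::read_yaml(paste0(img_path, ".truth.yaml"))
  expect_equal(side$n_tubes, 1L)
  expect_equal(side$tube_lengths, 29)
  expect_setequal(side$tube_mask_pixels[[1]], which(ph$truth$tube_masks[[1]]))
})
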
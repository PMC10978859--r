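test_that("thinning reduces a bar to a single one-pixel path", {
  m <- array(FALSE, c(20, 40))
  m[9:11, 5:35] <- TRUE
  sk <- skeletonize_mask(binary_mask(m))
  expect_true(all(which(sk$data) %in% which(m)))
  expect_false(any(sk$data & filamorph:::full_neighbourhood(sk$data)))
  expect_equal(count_components(sk), 1L)
  rep <- analyze_skeleton(sk)
  expect_equal(rep$skeletons$n_branches, 1L)
  expect_equal(rep$skeletons$n_junctions, 0L)
  # endpoint extension keeps the centerline close to the full bar length
  expect_gte(rep$skeletons$branch_length_sum, 28)
})

test_that("thin inputs are fixed points and empty masks stay empty", {
  p <- array(FALSE, c(10, 30)); p[5, 3:25] <- TRUE
  sk <- skeletonize_mask(binary_mask(p))
  expect_identical(sk$data, p)
  sk2 <- skeletonize_mask(binary_mask(sk$data))
  expect_identical(sk2$data, sk$data)
  empty <- skeletonize_mask(binary_mask(array(FALSE, c(8, 8))))
  expect_equal(sum(empty$data), 0L)
  # 3D idempotence on a digital line
  q <- array(FALSE, c(4, 20, 4)); q[2, 3:17, 2] <- TRUE
  expect_identical(skeletonize_mask(binary_mask(q))$data, q)
})

test_that("component count is preserved by thinning", {
  set.seed(41)
  for (i in 1:5) {
    m <- matrix(FALSE, 40, 40)
    # several random rectangles
    for (j in 1:4) {
      r0 <- sample(1:30, 1); c0 <- sample(1:30, 1)
      m[r0:(r0 + sample(2:8, 1)), c0:(c0 + sample(2:8, 1))] <- TRUE
    }
    mask <- binary_mask(m)
    expect_equal(count_components(skeletonize_mask(mask)),
                 count_components(mask))
  }
})

test_that("closed-form path geometry: straight, diagonal, T, anisotropic", {
  # straight 11-pixel path, 1 um pixels
  p <- array(FALSE, c(5, 15)); p[3, 3:13] <- TRUE
  rep <- analyze_skeleton(skeletonize_mask(binary_mask(p, unit = "um")))
  expect_equal(rep$skeletons$n_endpoint_voxels, 2L)
  expect_equal(rep$skeletons$n_junction_voxels, 0L)
  expect_equal(rep$skeletons$n_slab_voxels, 9L)
  expect_equal(rep$skeletons$n_branches, 1L)
  expect_equal(rep$skeletons$branch_length_sum, 10)
  # 5-pixel diagonal: length 4 * sqrt(2)
  d <- array(FALSE, c(10, 10)); for (i in 1:5) d[i + 2, i + 2] <- TRUE
  repd <- analyze_skeleton(skeletonize_mask(binary_mask(d)))
  expect_equal(repd$skeletons$branch_length_sum, 4 * sqrt(2))
  # anisotropic steps: same diagonal with calibration (1, 2)
  repa <- analyze_skeleton(skeletonize_mask(binary_mask(d,
                                                        calibration = c(1, 2))))
  expect_equal(repa$skeletons$branch_length_sum, 4 * sqrt(1 + 4))
  # T of three 6-pixel arms meeting at one pixel
  t_ <- array(FALSE, c(15, 15))
  t_[8, 2:8] <- TRUE; t_[8, 8:14] <- TRUE; t_[2:8, 8] <- TRUE
  rept <- analyze_skeleton(skeletonize_mask(binary_mask(t_),
                                            extend_ends = FALSE))
  expect_equal(rept$skeletons$n_endpoint_voxels, 3L)
  expect_equal(rept$skeletons$n_junctions, 1L)
  expect_equal(rept$skeletons$n_branches, 3L)
  expect_equal(rept$skeletons$n_triple_points, 1L)
})

test_that("pixel taxonomy partitions every skeleton exactly", {
  set.seed(42)
  for (i in 1:6) {
    m <- matrix(runif(35 * 35) < 0.35, 35, 35)
    sk <- skeletonize_mask(binary_mask(m))
    rep <- analyze_skeleton(sk)
    if (!nrow(rep$skeletons)) next
    tot <- with(rep$skeletons, n_endpoint_voxels + n_junction_voxels +
                  n_slab_voxels)
    expect_equal(sum(tot), sum(sk$data))
    nb <- with(rep$skeletons, branch_length_mean * n_branches)
    expect_equal(nb, rep$skeletons$branch_length_sum, tolerance = 1e-9)
  }
})

test_that("an isolated pixel and a closed loop are accounted as specified", {
  iso <- array(FALSE, c(5, 5)); iso[3, 3] <- TRUE
  rep <- analyze_skeleton(skeletonize_mask(binary_mask(iso)))
  expect_equal(rep$n_skeletons, 1L)
  expect_equal(rep$skeletons$n_endpoint_voxels, 1L)
  expect_equal(rep$skeletons$n_branches, 0L)
  expect_equal(rep$skeletons$branch_length_sum, 0)
  # a 4-connected diamond ring: all slabs, one cyclic branch
  ring <- array(FALSE, c(9, 9))
  pts <- rbind(c(2, 5), c(3, 4), c(4, 3), c(5, 2), c(6, 3), c(7, 4),
               c(8, 5), c(7, 6), c(6, 7), c(5, 8), c(4, 7), c(3, 6))
  ring[pts] <- TRUE
  repr <- analyze_skeleton(skeletonize_mask(binary_mask(ring),
                                            extend_ends = FALSE))
  expect_equal(repr$n_skeletons, 1L)
  expect_equal(repr$skeletons$n_endpoint_voxels, 0L)
  expect_equal(repr$skeletons$n_branches, 1L)
  expect_equal(repr$skeletons$branch_length_sum, 12 * sqrt(2))
})

test_that("non-thin input to analyze_skeleton is a contract violation", {
  blob <- array(FALSE, c(9, 9)); blob[3:7, 3:7] <- TRUE
  expect_error(analyze_skeleton(binary_mask(blob)), "not thin")
})

test_that("tube phantoms recover their centerline length within 5 percent", {
  for (r in c(2, 3)) {
    len <- 20 * r + 20
    dm <- c(4 * r + 9, len + 12)
    m <- mk_band(dm, (dm[1] + 1) / 2, r, 6, len + 5)
    rep <- analyze_skeleton(skeletonize_mask(binary_mask(m)))
    true_len <- len - 1
    expect_equal(rep$skeletons$n_branches, 1L)
    expect_gt(rep$skeletons$branch_length_sum, 0.95 * true_len)
    expect_lt(rep$skeletons$branch_length_sum, 1.05 * true_len)
  }
  # 3D tube
  m3 <- mk_tube3d(c(70, 15, 15), 8, 8, 3, 4, 67)
  rep3 <- analyze_skeleton(skeletonize_mask(binary_mask(m3)))
  expect_equal(rep3$skeletons$n_branches, 1L)
  expect_gt(rep3$skeletons$branch_length_sum, 0.95 * 63)
  expect_lt(rep3$skeletons$branch_length_sum, 1.05 * 63)
})

test_that("attachment points count distinct skeleton entries into a body", {
  # soma disk with two emerging neurite skeletons (the projection class
  # excludes the soma, so the neurite paths start at its boundary)
  co <- as.matrix(expand.grid(1:40, 1:60))
  soma <- array((co[, 1] - 20)^2 + (co[, 2] - 15)^2 <= 36, c(40, 60))
  skel <- array(FALSE, c(40, 60))
  skel[20, 22:55] <- TRUE          # neurite leaving eastwards
  skel[27:38, 15] <- TRUE          # neurite leaving south
  sk <- binary_mask(skel)
  body <- binary_mask(soma)
  expect_equal(count_attachment_points(sk, body, halo = 2), 2L)
  # a single path crossing the soma boundary once
  one <- array(FALSE, c(40, 60)); one[20, 15:55] <- TRUE
  expect_equal(count_attachment_points(binary_mask(one), body, halo = 2), 1L)
  # empty body mask -> 0
  empty <- binary_mask(array(FALSE, c(40, 60)))
  expect_equal(count_attachment_points(sk, empty, halo = 2), 0L)
  expect_error(count_attachment_points(sk, binary_mask(matrix(FALSE, 3, 3))),
               "differ")
})
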
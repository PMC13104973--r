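test_that("preprocessing applies gamma on rescaled intensities", {
  # Values {0, 0.5, 1} with enough mass at the extremes that the 2nd/99.8th
  # percentiles coincide with 0 and 1, making the normalization the identity.
  a <- array(0, dim = c(10, 10, 10))
  a[, , 1:4] <- 0
  a[, , 5] <- 0.5
  a[, , 6:10] <- 1
  p <- seg3d_params(median_size = 1, downsample_factor = 1)
  out <- preprocess_volume(bamp_volume(a), p)
  expect_equal(unique(as.numeric(out$data[, , 5])), 0.5^0.8,
               tolerance = 1e-12)
  expect_error(preprocess_volume(bamp_volume(array(2, dim = c(6, 6, 6))), p),
               "constant")
})

test_that("the cubic median filter matches a brute-force neighbourhood oracle", {
  set.seed(3)
  a <- array(rnorm(8 * 7 * 6), dim = c(8, 7, 6))
  got <- bampq:::cpp_median_filter3(a, 1L)
  clamp <- function(i, n) pmin(pmax(i, 1), n)
  for (pick in list(c(1, 1, 1), c(4, 4, 3), c(8, 7, 6), c(2, 5, 4))) {
    nb <- as.matrix(expand.grid(pick[1] + (-1:1), pick[2] + (-1:1),
                                pick[3] + (-1:1)))
    nb[, 1] <- clamp(nb[, 1], 8); nb[, 2] <- clamp(nb[, 2], 7)
    nb[, 3] <- clamp(nb[, 3], 6)
    expect_equal(got[pick[1], pick[2], pick[3]],
                 median(a[nb]))
  }
  salt <- array(0, dim = c(9, 9, 9))
  salt[5, 5, 5] <- 1
  expect_true(all(bampq:::cpp_median_filter3(salt, 1L) == 0))
})

test_that("downsampling by 1/4 quarters each axis", {
  a <- array(runif(64^3), dim = c(64, 64, 64))
  out <- preprocess_volume(bamp_volume(a), seg3d_params(median_size = 1))
  expect_equal(dim(out$data), c(16, 16, 16))
})

test_that("orthoview Otsu segments each slice with the intensity floor", {
  a <- array(0.05, dim = c(24, 24, 24))
  cube <- array(FALSE, dim = dim(a))
  cube[8:16, 8:16, 8:16] <- TRUE
  a[cube] <- 0.9
  views <- orthoview_otsu(a)
  expect_identical(views$xy, cube)
  expect_identical(views$xz, cube)
  expect_identical(views$yz, cube)

  dim_vol <- array(0.05, dim = c(12, 12, 12))
  dim_vol[4:8, 4:8, 4:8] <- 0.15           # everything under the 0.2 floor
  v2 <- orthoview_otsu(dim_vol)
  expect_false(any(v2$xy) || any(v2$xz) || any(v2$yz))
})

test_that("consensus voting keeps the majority and the largest component", {
  m <- array(FALSE, dim = c(16, 16, 16))
  m[4:12, 4:12, 4:12] <- TRUE
  m[1:2, 1:2, 1:2] <- TRUE                 # small second component
  same <- consensus_combine(list(m, m, m), seg3d_params())
  expect_true(all(same$mask[4:12, 4:12, 4:12]))
  expect_false(any(same$mask[1:2, 1:2, 1:2]))

  solo <- array(FALSE, dim = c(16, 16, 16))
  solo[8, 8, 8] <- TRUE
  views <- list(m, m, solo | m)
  views[[1]][14, 14, 14] <- TRUE           # marked by exactly one view
  got <- consensus_combine(views, seg3d_params(consensus_votes = 2))
  expect_false(got$mask[14, 14, 14])

  expect_error(consensus_combine(list(solo & !solo, solo & !solo,
                                      solo & !solo), seg3d_params()),
               "empty consensus")
})

test_that("lowering the vote threshold never shrinks the consensus support", {
  set.seed(9)
  views <- lapply(1:3, function(i)
    array(runif(10^3) < 0.4, dim = c(10, 10, 10)))
  votes <- views[[1]] + views[[2]] + views[[3]]
  for (k in 2:3)
    expect_true(all((votes >= k) <= (votes >= k - 1)))
})

test_that("the pipeline recovers a planted ellipsoid on noiseless volumes", {
  g <- generate_spot_volume(spot_scene_spec(noise_sd = 0))
  seg <- segment_cell_3d(g$actin)
  expect_gte(sum(seg$mask$mask & g$truth$cell_mask) /
               sum(seg$mask$mask | g$truth$cell_mask), 0.85)
})

test_that("gamma-before-normalization order is pinned by a regression fixture", {
  # Outlier voxels separate the min-max range from the percentile range, so
  # swapping gamma and percentile normalization changes the output.
  set.seed(11)
  a <- array(runif(12^3, 0.2, 0.8), dim = c(12, 12, 12))
  a[1, 1, 1] <- 25
  p <- seg3d_params(median_size = 1, downsample_factor = 1)
  got <- preprocess_volume(bamp_volume(a), p)

  rng <- range(a)
  gamma_first <- percentile_normalize(
    bamp_volume(((a - rng[1]) / diff(rng))^p$gamma),
    spot_params(p_low = p$p_low, p_high = p$p_high))
  expect_equal(got$data, gamma_first$data, tolerance = 1e-12)

  norm_first <- percentile_normalize(bamp_volume(a),
                                     spot_params(p_low = p$p_low,
                                                 p_high = p$p_high))
  swapped <- norm_first$data^p$gamma
  expect_gt(max(abs(got$data - swapped)), 1e-3)
})
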
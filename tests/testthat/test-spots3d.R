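# Independent percentile oracle: sort-based linear interpolation between
# order statistics.
oracle_percentile <- function(x, p) {
  s <- sort(x)
  h <- (length(s) - 1) * p / 100 + 1
  lo <- floor(h)
  s[lo] + (h - lo) * (s[min(lo + 1, length(s))] - s[lo])
}

test_that("isotropization resamples to the smallest spacing", {
  iso <- bamp_volume(array(runif(8 * 8 * 8), dim = c(8, 8, 8)), c(1, 1, 1))
  out <- isotropize(iso)
  expect_identical(out$data, iso$data)

  a <- array(runif(10 * 6 * 6), dim = c(10, 6, 6))
  out2 <- isotropize(bamp_volume(a, c(2, 1, 1)))
  expect_equal(dim(out2$data), c(20, 6, 6))
  expect_equal(out2$voxel_spacing, c(1, 1, 1))

  ramp <- array(rep(seq(0, 9), 36), dim = c(10, 6, 6))
  out3 <- isotropize(bamp_volume(ramp, c(2, 1, 1)))
  expect_equal(out3$data[, 1, 1], seq(0, 9, length.out = 20),
               tolerance = 1e-6)
})

test_that("percentile normalization matches the sort-based oracle", {
  p <- spot_params()
  ramp <- bamp_volume(array(0:999, dim = c(10, 10, 10)))
  norm <- percentile_normalize(ramp, p)
  q_lo <- oracle_percentile(0:999, 2)
  q_hi <- oracle_percentile(0:999, 99.8)
  expected <- pmin(pmax((0:999 - q_lo) / (q_hi - q_lo), 0), 1)
  expect_equal(as.numeric(norm$data), expected, tolerance = 1e-9)
  expect_equal(min(norm$data), 0)
  expect_equal(max(norm$data), 1)

  set.seed(5)
  rand <- array(rnorm(4000), dim = c(20, 20, 10))
  norm2 <- percentile_normalize(rand, p)
  q <- c(oracle_percentile(rand, 2), oracle_percentile(rand, 99.8))
  expect_equal(as.numeric(norm2),
               pmin(pmax((as.numeric(rand) - q[1]) / (q[2] - q[1]), 0), 1),
               tolerance = 1e-9)

  expect_error(percentile_normalize(array(3, dim = c(5, 5, 5)), p),
               "degenerate percentiles")
})

test_that("difference-of-Gaussian detection localizes planted spots", {
  blank <- array(0, dim = c(32, 32, 32))
  expect_equal(nrow(detect_spots_dog(blank)), 0)

  one <- generate_spot_volume(spot_scene_spec(
    spots_inside = data.frame(z = 30.4, y = 33.2, x = 31.7, sigma = 4,
                              amplitude = 100),
    background_intensity = 0, cell_intensity = 0.001, noise_sd = 0))
  spots <- detect_spots_dog(percentile_normalize(one$spots))
  expect_equal(nrow(spots), 1)
  expect_lt(sqrt(sum((c(spots$z, spots$y, spots$x) -
                        c(30.4, 33.2, 31.7))^2)), 1)

  scn <- random_spot_scene(31, n_inside = 5, n_outside = 0, noise_sd = 0)
  g <- generate_spot_volume(scn)
  det <- detect_spots_dog(percentile_normalize(g$spots))
  expect_equal(nrow(det), 5)
  expect_true(all(match_distances(det, g$truth$spots_inside) <= 2))
})

test_that("the actin cell mask keeps one bright filled component", {
  # a cell large enough that the contractual 1-voxel final erosion costs
  # less than 10% of the volume
  g <- generate_spot_volume(spot_scene_spec(shape = c(80, 80, 80),
                                            cell_axes = c(30, 32, 32),
                                            noise_sd = 0))
  m <- cell_mask_from_actin(g$actin)
  expect_gte(sum(m$mask & g$truth$cell_mask) /
               sum(m$mask | g$truth$cell_mask), 0.9)

  two <- array(10, dim = c(40, 40, 40))
  two[10:19, 10:19, 10:19] <- 200          # 1000 voxels
  two[30:32, 30:32, 30:34] <- 200          # 45 voxels
  two[25:39, 5:10, 30:39] <- 100           # mid class for the 3-class split
  m2 <- cell_mask_from_actin(bamp_volume(two))
  expect_true(any(m2$mask[12:17, 12:17, 12:17]))
  expect_false(any(m2$mask[30:32, 30:32, 30:34]))

  cav <- array(10, dim = c(32, 32, 32))
  cav[8:24, 8:24, 8:24] <- 200
  cav[15:16, 15:16, 15] <- 10              # 4-voxel internal cavity
  cav[26:30, 26:30, 26:30] <- 100
  m3 <- cell_mask_from_actin(bamp_volume(cav))
  expect_true(all(m3$mask[15:16, 15:16, 15]))
})

test_that("the postprocessing order (close, fill, erode) is pinned", {
  # A box with an internal cavity connected to the outside by a thin channel.
  # The cavity is wider than the closing ball, so only hole filling can shut
  # it; closing first seals the channel so the fill step closes the cavity,
  # while filling before closing leaves it open for good.
  mask <- array(FALSE, dim = c(32, 32, 32))
  mask[4:28, 4:28, 4:28] <- TRUE
  mask[10:22, 10:22, 10:22] <- FALSE       # 13-voxel-wide cavity
  mask[16, 16, 23:28] <- FALSE             # 1-voxel channel to the outside
  off3 <- bampq:::ball_offsets(3)
  off1 <- bampq:::ball_offsets(1)
  quoted <- bampq:::cpp_morph3(
    bampq:::cpp_fill_holes3(
      bampq:::cpp_morph3(bampq:::cpp_morph3(mask, off3, TRUE), off3, FALSE)),
    off1, FALSE)
  permuted <- bampq:::cpp_morph3(
    bampq:::cpp_morph3(bampq:::cpp_morph3(bampq:::cpp_fill_holes3(mask),
                                          off3, TRUE), off3, FALSE),
    off1, FALSE)
  expect_false(identical(quoted, permuted))

  vol <- array(10, dim = c(32, 32, 32))
  vol[mask] <- 200
  vol[30:31, 2:6, 2:6] <- 100              # mid class
  got <- cell_mask_from_actin(bamp_volume(vol))
  expect_identical(got$mask, quoted)
})

test_that("spots are filtered by the rounded centre voxel", {
  spots <- data.frame(z = c(5.2, 10.0), y = c(5.0, 10.4), x = c(5.4, 10.0),
                      scale = 3, response = c(0.5, 0.4))
  class(spots) <- c("spot_list", class(spots))
  all_in <- array(TRUE, dim = c(16, 16, 16))
  expect_equal(nrow(filter_spots(spots, all_in)), 2)
  none <- array(FALSE, dim = c(16, 16, 16))
  expect_equal(nrow(filter_spots(spots, none)), 0)

  g <- generate_spot_volume(random_spot_scene(19))
  res <- spot_pipeline(g$spots, g$actin)
  expect_equal(nrow(res$spots), 5)
  d_out <- match_distances(res$spots, g$truth$spots_outside)
  expect_true(all(d_out > 3))
  d_out_all <- match_distances(res$spots_all, g$truth$spots_outside)
  expect_true(all(d_out_all <= 2))
})

test_that("compartment density is spots per unit area", {
  d <- compartment_density(10, 50, "lamella")
  expect_equal(d$density, 0.2)
  expect_equal(compartment_density(0, 50)$density, 0)
  expect_equal(compartment_density(20, 100)$density,
               compartment_density(10, 50)$density)
  expect_error(compartment_density(3, 0), "area")
})
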
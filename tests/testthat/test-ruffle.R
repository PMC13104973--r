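test_that("temporal baseline is the truncated-window median", {
  const <- bamp_movie(array(7, dim = c(9, 4, 4)))
  expect_true(all(temporal_baseline(const)$data == 7))

  spike <- array(1, dim = c(7, 1, 1))
  spike[4, 1, 1] <- 100
  base <- temporal_baseline(spike, ruffle_params(half_window_frames = 3))
  expect_equal(base[4, 1, 1], 1)

  set.seed(101)
  a <- array(rnorm(24 * 6 * 5), dim = c(24, 6, 5))
  got <- temporal_baseline(a, ruffle_params(half_window_frames = 5))
  brute <- array(0, dim = dim(a))
  for (t in 1:24)
    for (y in 1:6)
      for (x in 1:5) {
        win <- sort(a[max(1, t - 5):min(24, t + 5), y, x])
        n <- length(win)
        brute[t, y, x] <- if (n %% 2 == 1) win[(n + 1) / 2]
                          else mean(win[n / 2 + 0:1])
      }
  expect_identical(got, brute)
})

test_that("ratio normalization uses a percent scale with a background guard", {
  raw <- array(50, dim = c(3, 4, 4))
  p <- ruffle_params(ratio_floor = 0)
  expect_true(all(ratio_normalize(raw, raw, p)$data == 100))
  expect_true(all(ratio_normalize(2 * raw, raw, p)$data == 200))

  base <- raw
  base[2, 1, 1] <- 0
  r <- ratio_normalize(raw, base, ruffle_params(ratio_floor = 5))
  expect_equal(r$data[2, 1, 1], 0)
  expect_true(r$background_flag[2, 1, 1])
  expect_false(any(r$background_flag[c(1, 3), , ]))
  expect_error(ratio_normalize(raw, array(1, dim = c(3, 4, 5))), "shape")
})

test_that("ruffle segmentation finds high-ratio regions at multiple widths", {
  flat <- make_ratio_movie(array(100, dim = c(2, 64, 64)))
  expect_false(any(segment_ruffles(flat)$masks))

  frames <- array(100, dim = c(1, 100, 100))
  frames[1, 41:60, 41:60] <- 300
  m <- segment_ruffles(make_ratio_movie(frames))$masks[1, , ]
  gt <- block_mask(100, 100, 41:60, 41:60)
  expect_gte(sum(m & gt) / sum(m | gt), 0.8)

  two <- array(100, dim = c(1, 100, 100))
  two[1, 21:24, 21:24] <- 300   # 4 px wide
  two[1, 51:70, 51:70] <- 300   # 20 px wide
  masks <- segment_ruffles(make_ratio_movie(two))$masks[1, , ]
  lab <- EBImage::bwlabel(masks)
  hit_small <- unique(lab[21:24, 21:24])
  hit_large <- unique(lab[51:70, 51:70])
  expect_true(any(hit_small > 0))
  expect_true(any(hit_large > 0))
})

test_that("cell segmentation recovers the cell and flags blank frames", {
  g <- generate_ruffle_movie(scene_spec(n_frames = 6, noise_sd = 2, seed = 9))
  cells <- segment_cells(g$movie)
  ious <- vapply(1:6, function(t)
    jaccard(cells$masks[t, , ], g$truth$cell_masks[t, , ]), numeric(1))
  expect_true(all(ious >= 0.95))

  blank <- array(10, dim = c(3, 32, 32)) +
    array(rnorm(3 * 32 * 32, sd = 1), dim = c(3, 32, 32))
  expect_warning(empty <- segment_cells(blank), "no cell foreground")
  expect_false(any(empty$masks))

  two_cells <- array(10, dim = c(4, 64, 128))
  e1 <- bampq:::ellipse_mask(64, 128, c(32, 32), c(18, 20))
  e2 <- bampq:::ellipse_mask(64, 128, c(32, 96), c(18, 20))
  for (t in 1:4) two_cells[t, , ] <- 10 + 190 * (e1 | e2)
  cc <- segment_cells(two_cells)
  for (t in 1:4)
    expect_equal(max(EBImage::bwlabel(cc$masks[t, , ])), 2)
})

test_that("ruffling rate is the ruffle area as a percentage of cell area", {
  cells <- array(FALSE, dim = c(3, 20, 20))
  cells[, 1:10, 1:10] <- TRUE               # 100 px
  ruff <- array(FALSE, dim = c(3, 20, 20))
  ruff[, 1:2, 1:5] <- TRUE                  # 10 px
  res <- ruffling_rate(mask_stack(ruff, "ruffle"), mask_stack(cells, "cell"))
  expect_equal(res$per_frame_percent, rep(10, 3))
  expect_equal(res$mean_rate_percent, 10)

  none <- ruffling_rate(mask_stack(array(FALSE, dim = dim(ruff)), "ruffle"),
                        mask_stack(cells, "cell"))
  expect_equal(none$mean_rate_percent, 0)

  empty_cells <- mask_stack(array(FALSE, dim = dim(ruff)), "cell")
  expect_error(ruffling_rate(mask_stack(ruff, "ruffle"), empty_cells),
               "empty cell masks")

  partial <- cells
  partial[2, , ] <- FALSE
  res2 <- ruffling_rate(mask_stack(ruff, "ruffle"),
                        mask_stack(partial, "cell"))
  expect_equal(res2$excluded_frames, 2L)
  expect_true(is.na(res2$per_frame_percent[2]))
  expect_equal(res2$mean_rate_percent, 10)
})

test_that("a static scene scores below 1% and scores stay in [0, 100]", {
  quiet <- static_fiber_scene(noise_sd = 0)
  res <- ruffle_rate_pipeline(quiet$movie)
  expect_lt(res$mean_rate_percent, 1)
  ok <- res$per_frame_percent[!is.na(res$per_frame_percent)]
  expect_true(all(ok >= 0 & ok <= 100))
})

test_that("the percent-ratio (and rate) are invariant to intensity rescaling", {
  ev <- ruffle_events_for_fraction(0.06, 100)
  g <- generate_ruffle_movie(scene_spec(n_frames = 100, noise_sd = 2,
                                        seed = 13), ev)
  p <- ruffle_params()
  r1 <- ratio_normalize(g$movie, temporal_baseline(g$movie, p), p)
  scaled <- bamp_movie(g$movie$data * 7, g$movie$frame_interval)
  r2 <- ratio_normalize(scaled, temporal_baseline(scaled, p), p)
  expect_identical(r1$background_flag, r2$background_flag)
  ok <- !r1$background_flag
  expect_equal(r1$data[ok], r2$data[ok], tolerance = 1e-12)
})

test_that("measured rate increases with the planted ruffle fraction", {
  rates <- vapply(c(0.02, 0.08, 0.15), function(f) {
    g <- generate_ruffle_movie(scene_spec(n_frames = 100, noise_sd = 2,
                                          seed = 21),
                               ruffle_events_for_fraction(f, 100))
    ruffle_rate_pipeline(g$movie)$mean_rate_percent
  }, numeric(1))
  expect_true(all(diff(rates) > 0))
})
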
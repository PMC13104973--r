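test_that("membrane normalization divides frame by frame with an exclusion floor", {
  p <- enrichment_params(seg_threshold = 10, t0_frame = 1, t1_frame = 2,
                         membrane_floor = 1)
  mem <- array(50, dim = c(2, 8, 8))
  n1 <- normalize_by_membrane(mem, mem, p)
  expect_true(all(n1$data == 1))
  n3 <- normalize_by_membrane(3 * mem, mem, p)
  expect_true(all(n3$data == 3))

  mem0 <- mem
  mem0[1, 2, 2] <- 0
  nx <- normalize_by_membrane(mem, mem0, p)
  expect_true(nx$excluded_flag[1, 2, 2])
  expect_equal(nx$data[1, 2, 2], 0)
  expect_error(normalize_by_membrane(mem, array(1, dim = c(2, 8, 9)), p),
               "shape")
})

test_that("frame segmentation applies the tuned threshold", {
  p <- enrichment_params(seg_threshold = 10, t0_frame = 1, t1_frame = 2)
  expect_warning(m <- segment_cell_frame(matrix(5, 20, 20), p), "empty mask")
  expect_false(any(m))
  expect_true(all(segment_cell_frame(matrix(15, 20, 20), p)))

  masks <- protrusion_masks()
  g <- generate_protrusion_movie(protrusion_scene_spec(masks$base, masks$full,
                                                       noise_sd = 5,
                                                       seed = 2))
  p2 <- enrichment_params(seg_threshold = 50, t0_frame = 1, t1_frame = 20)
  got <- segment_cell_frame(g$membrane$data[20, , ], p2)
  expect_gte(jaccard(got, g$truth$mask_t1), 0.95)
})

test_that("partition follows the T0/T1 set differences exactly", {
  t0 <- block_mask(9, 9, 4:6, 4:6)
  t1 <- block_mask(9, 9, 3:7, 3:7)
  part <- partition_protrusions(t0, t1)
  expect_equal(sum(part$protrusive), 16)
  expect_equal(sum(part$non_protrusive), 9)

  same <- partition_protrusions(t1, t1)
  expect_false(any(same$protrusive))

  retract <- t0
  retract[4, 4:6] <- FALSE          # 3 px lost between T0 and T1
  part2 <- partition_protrusions(t1, retract)
  lost <- t1 & !retract
  expect_false(any(part2$protrusive & lost))
  expect_false(any(part2$non_protrusive & lost))
})

test_that("enrichment statistics compare the class means at T1", {
  p <- enrichment_params(seg_threshold = 10, t0_frame = 1, t1_frame = 2)
  t0 <- block_mask(10, 10, 1:5, 1:10)
  t1 <- block_mask(10, 10, 1:8, 1:10)
  part <- partition_protrusions(t0, t1)

  uni <- structure(list(data = array(1, dim = c(2, 10, 10)),
                        excluded_flag = array(FALSE, dim = c(2, 10, 10))),
                   class = "normalized_movie")
  res <- enrichment_stats(uni, part, p)
  expect_equal(c(res$mean_protrusive, res$mean_non_protrusive,
                 res$enrichment_ratio), c(1, 1, 1))

  vals <- array(1, dim = c(2, 10, 10))
  vals[2, , ][part$protrusive] <- 2
  res2 <- enrichment_stats(structure(list(
    data = vals, excluded_flag = array(FALSE, dim = c(2, 10, 10))),
    class = "normalized_movie"), part, p)
  expect_equal(res2$enrichment_ratio, 2)

  empty_part <- partition_protrusions(t1, t1)
  expect_warning(res3 <- enrichment_stats(uni, empty_part, p),
                 "protrusive mean undefined")
  expect_true(is.na(res3$enrichment_ratio))
})

test_that("planted enrichment is recovered and is monotone in the truth", {
  masks <- protrusion_masks()
  p <- enrichment_params(seg_threshold = 50, t0_frame = 1, t1_frame = 20)
  measured <- vapply(c(1.0, 1.5, 2.0, 3.0), function(r) {
    g <- generate_protrusion_movie(protrusion_scene_spec(
      masks$base, masks$full, reporter_ratio_protrusive = r,
      noise_sd = 5, seed = 17))
    enrichment_pipeline(g$reporter, g$membrane, p)$enrichment_ratio
  }, numeric(1))
  expect_equal(measured[2], 1.5, tolerance = 0.075 / 1.5)
  expect_lt(abs(measured[1] - 1), 0.05)
  expect_true(all(diff(measured) > 0))
})

test_that("a uniform channel gain leaves the enrichment ratio unchanged", {
  masks <- protrusion_masks()
  g <- generate_protrusion_movie(protrusion_scene_spec(
    masks$base, masks$full, reporter_ratio_protrusive = 2,
    noise_sd = 5, seed = 23))
  p <- enrichment_params(seg_threshold = 50, t0_frame = 1, t1_frame = 20)
  ref <- enrichment_pipeline(g$reporter, g$membrane, p)

  boosted <- bamp_movie(g$reporter$data * 4.2)
  res_r <- enrichment_pipeline(boosted, g$membrane, p)
  expect_equal(res_r$enrichment_ratio, ref$enrichment_ratio,
               tolerance = 1e-12)
  expect_equal(res_r$mean_protrusive, 4.2 * ref$mean_protrusive,
               tolerance = 1e-12)

  mem_boost <- bamp_movie(g$membrane$data * 3)
  p3 <- enrichment_params(seg_threshold = 150, t0_frame = 1, t1_frame = 20)
  res_m <- enrichment_pipeline(g$reporter, mem_boost, p3)
  expect_equal(res_m$enrichment_ratio, ref$enrichment_ratio,
               tolerance = 1e-12)
})

test_that("suggest_t1 points at the maximal-protrusion frame", {
  masks <- protrusion_masks()
  g <- generate_protrusion_movie(protrusion_scene_spec(masks$base, masks$full,
                                                       n_frames = 20,
                                                       noise_sd = 5,
                                                       seed = 29))
  p <- enrichment_params(seg_threshold = 50, t0_frame = 1, t1_frame = 2)
  expect_equal(suggest_t1(g$membrane, p), 20L)
})
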
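test_that("generators are pure functions of their specs", {
  scene <- scene_spec(n_frames = 20, noise_sd = 3, seed = 7)
  ev <- ruffle_spec(edge_angle = 0.5, area_fraction = 0.1, onset_frame = 3,
                    duration_frames = 10, amplitude = 150,
                    drift_px_per_frame = 1)
  a <- generate_ruffle_movie(scene, ev)
  b <- generate_ruffle_movie(scene, ev)
  expect_identical(a$movie$data, b$movie$data)
  expect_identical(a$truth$ruffle_masks, b$truth$ruffle_masks)

  spec <- random_spot_scene(11)
  expect_identical(generate_spot_volume(spec)$spots$data,
                   generate_spot_volume(spec)$spots$data)
})

test_that("ground truth is computed before noise is applied", {
  ev <- ruffle_spec(edge_angle = 1, area_fraction = 0.08, onset_frame = 2,
                    duration_frames = 8, amplitude = 150)
  quiet <- generate_ruffle_movie(scene_spec(n_frames = 12, noise_sd = 0,
                                            seed = 5), ev)
  noisy <- generate_ruffle_movie(scene_spec(n_frames = 12, noise_sd = 20,
                                            seed = 5), ev)
  expect_identical(quiet$truth, noisy$truth)
  expect_false(identical(quiet$movie$data, noisy$movie$data))
})

test_that("ruffle masks stay inside the cell and hit the planted fraction", {
  scene <- scene_spec(n_frames = 15, noise_sd = 0, seed = 1)
  empty <- generate_ruffle_movie(scene, ruffle_spec())
  expect_false(any(empty$truth$ruffle_masks))

  ev <- ruffle_spec(edge_angle = 0.7, area_fraction = 0.10, onset_frame = 1,
                    duration_frames = 15, amplitude = 150,
                    drift_px_per_frame = 1)
  g <- generate_ruffle_movie(scene, ev)
  expect_false(any(g$truth$ruffle_masks & !g$truth$cell_masks))
  expect_equal(g$truth$mean_fraction, 0.10, tolerance = 0.01 / 0.10)
})

test_that("overlapping ruffle events beyond the area bound are rejected", {
  scene <- scene_spec(n_frames = 10)
  ev <- ruffle_spec(edge_angle = c(0, 1), area_fraction = c(0.3, 0.3),
                    onset_frame = c(1, 1), duration_frames = c(10, 10),
                    amplitude = c(100, 100))
  expect_error(generate_ruffle_movie(scene, ev), "exceed half the cell area")
})

test_that("protrusion movies encode the planted region ratios exactly", {
  m <- protrusion_masks()
  eq <- generate_protrusion_movie(protrusion_scene_spec(
    m$base, m$full, reporter_ratio_protrusive = 1, reporter_ratio_body = 1,
    noise_sd = 0))
  last <- dim(eq$reporter$data)[1]
  on_cell <- m$full
  expect_equal(eq$reporter$data[last, , ][on_cell],
               eq$membrane$data[last, , ][on_cell])

  same <- generate_protrusion_movie(protrusion_scene_spec(m$base, m$base,
                                                          noise_sd = 0))
  expect_false(any(same$truth$protrusive))

  two <- generate_protrusion_movie(protrusion_scene_spec(
    m$base, m$full, reporter_ratio_protrusive = 2, reporter_ratio_body = 1,
    noise_sd = 0))
  pro <- two$truth$protrusive
  expect_equal(unique(two$reporter$data[last, , ][pro] /
                        two$membrane$data[last, , ][pro]), 2)
  expect_error(protrusion_scene_spec(m$full, m$base), "subset")
})

test_that("spot volumes plant Gaussians of the stated mass at the stated centres", {
  inside <- data.frame(z = c(25, 40, 30, 35, 28), y = c(25, 30, 45, 20, 38),
                       x = c(30, 42, 28, 35, 20), sigma = 4, amplitude = 100)
  outside <- data.frame(z = c(5, 60), y = c(5, 60), x = c(5, 60),
                        sigma = 4, amplitude = 100)
  spec <- spot_scene_spec(spots_inside = inside, spots_outside = outside,
                          noise_sd = 0)
  g <- generate_spot_volume(spec)
  expect_equal(nrow(g$truth$spots_inside), 5)
  expect_equal(nrow(g$truth$spots_outside), 2)

  one <- generate_spot_volume(spot_scene_spec(
    spots_inside = data.frame(z = 32.3, y = 30.6, x = 33.1, sigma = 4,
                              amplitude = 100),
    background_intensity = 0, cell_intensity = 0.001, noise_sd = 0))
  peak <- which(one$spots$data == max(one$spots$data), arr.ind = TRUE)[1, ]
  expect_lt(max(abs(peak - c(32.3, 30.6, 33.1))), 1)
  mass <- sum(one$spots$data)
  expect_equal(mass, 100 * (2 * pi)^1.5 * 4^3, tolerance = 0.02)

  too_close <- data.frame(z = c(30, 32), y = c(30, 30), x = c(30, 30),
                          sigma = 3, amplitude = 50)
  expect_error(spot_scene_spec(spots_inside = too_close, min_separation = 10),
               "separation")
})

test_that("nuclei fields carry an exact planted EdU-positive subset", {
  none <- generate_nuclei_images(nuclei_scene_spec(positive_fraction = 0,
                                                   noise_sd = 0, seed = 2))
  expect_true(all(none$edu == nuclei_scene_spec()$background))

  all_pos <- generate_nuclei_images(nuclei_scene_spec(positive_fraction = 1,
                                                      radius_sd = 0,
                                                      noise_sd = 0, seed = 2))
  thr <- all_pos$truth
  expect_equal(sum(thr$edu_mask), sum(thr$dapi_mask))

  g <- generate_nuclei_images(nuclei_scene_spec(n_nuclei = 20,
                                                positive_fraction = 0.4,
                                                seed = 4))
  expect_equal(g$truth$positive_count, 8)
  expect_equal(sum(g$truth$nuclei$positive), 8)

  cramped <- nuclei_scene_spec(height = 30, width = 30, n_nuclei = 40,
                               radius_mean = 6, seed = 1)
  expect_error(generate_nuclei_images(cramped), "cannot place")
})
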
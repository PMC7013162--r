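test_that("phantom spec validation rejects impossible geometry", {
  expect_error(validate_phantom_spec(
    phantom_spec(perisperm_semiaxes = c(2, 2, 2))), "inside")
  expect_error(validate_phantom_spec(
    phantom_spec(noise_sd = 40)), "noise")
  expect_silent(validate_phantom_spec(phantom_spec()))
})

test_that("phantom rendering is deterministic under a seed", {
  spec <- phantom_spec()
  a <- make_seed_phantom(spec, rng_seed = 3L)
  b <- make_seed_phantom(spec, rng_seed = 3L)
  expect_identical(a$tomogram$intensities, b$tomogram$intensities)
  expect_identical(a$labeling$labels, b$labeling$labels)
  c <- make_seed_phantom(spec, rng_seed = 4L)
  expect_false(identical(a$tomogram$intensities, c$tomogram$intensities))
})

test_that("phantom labels contain every compartment and a closed cavity", {
  lab <- make_seed_phantom(phantom_spec(noise_sd = 0))$labeling
  cls <- seed_classes()
  for (cp in c("embryo", "perisperm", "coat", "cavity")) {
    expect_gt(sum(lab$labels == cls[[cp]]), 0)
  }
  # the cavity must be a hole of the solid foreground
  holes <- fill_holes(lab$labels > 0 & lab$labels != cls[["cavity"]])$holes
  expect_true(all(holes[lab$labels == cls[["cavity"]]]))
})

test_that("scan generation matches its truth table and stays gapped", {
  scan <- make_scan(small_scan_spec())
  expect_s3_class(scan$tomogram, "tomogram")
  expect_equal(length(unique(scan$truth$seed)), 4L)
  # per-seed voxel tallies in the truth agree with the rendered labels
  expect_equal(sum(scan$truth$voxels),
               sum(scan$labeling$labels > 0L))
  # seeds must not touch: 26-connectivity components = seed count
  lab <- label_components(scan$labeling$labels > 0L, connectivity = 26L)
  expect_equal(attr(lab, "n_components"), 4L)
})

test_that("germination event tables quantize to the frame grid", {
  spec <- germination_sim_spec(n_seeds = 3, true_times = c(23, 24, 350.5),
                               nongerminating_fraction = 0,
                               frame_interval = 2, duration = 360)
  rec <- make_germination_series(spec)$records
  expect_equal(rec$time_h, c(24, 24, 352))
  expect_false(any(rec$censored))
  # events past the assay end are censored, never dropped
  spec2 <- germination_sim_spec(n_seeds = 2, true_times = c(100, 400),
                                nongerminating_fraction = 0,
                                frame_interval = 2, duration = 360)
  rec2 <- make_germination_series(spec2)$records
  expect_equal(rec2$censored, c(FALSE, TRUE))
  expect_equal(rec2$censored_at[2], 360)
})

test_that("lazy frame series regenerate frames deterministically", {
  spec <- germination_sim_spec(n_seeds = 4, true_times = c(10, 20, 30, 40),
                               nongerminating_fraction = 0,
                               frame_interval = 2, duration = 60,
                               mode = "image_series", rng_seed = 5)
  ser <- make_germination_series(spec)$series
  expect_identical(ser$get_frame(7L), ser$get_frame(7L))
  expect_false(identical(ser$get_frame(7L), ser$get_frame(8L)))
  expect_true(all(ser$get_frame(1L) >= 0 & ser$get_frame(1L) <= 1))
})

test_that("elongation tracks follow the growth model exactly", {
  spec <- elongation_sim_spec(n_seeds = 2, germination_times = c(48, 96),
                              radicle_rate = 0.3, shoot_rate = 0.1,
                              frame_interval = 4, duration = 240)
  sim <- make_elongation_series(spec)
  tr <- sim$tracks[[1]]
  expect_equal(tr$series$radicle_mm,
               0.3 * pmax(0, tr$series$time_h - 48))
  expect_equal(tr$series$shoot_mm,
               0.1 * pmax(0, tr$series$time_h - 48))
})
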
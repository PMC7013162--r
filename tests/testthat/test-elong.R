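test_that("green channel extraction needs a color frame", {
  fr <- array(runif(60), dim = c(4, 5, 3))
  expect_identical(green_channel(fr), fr[, , 2])
  expect_error(green_channel(matrix(0, 4, 5)), "3 channels")
})

test_that("RadLg at a fixed offset is exact on noise-free tracks", {
  tr <- seedling_track(seed_id = 1L, hgerm = 50,
                       time_h = seq(0, 400, by = 4),
                       radicle_mm = 0.25 * pmax(0, seq(0, 400, by = 4) - 50),
                       shoot_mm = 0.1 * pmax(0, seq(0, 400, by = 4) - 50),
                       scale = 9)
  expect_equal(radlg_at_offset(tr, offset = 168), 42.0)
  short <- seedling_track(seed_id = 1L, hgerm = 50, time_h = c(0, 100),
                          radicle_mm = c(0, 10), shoot_mm = c(0, 4),
                          scale = 9)
  expect_error(radlg_at_offset(short, offset = 168), "track too short")
})

test_that("growth-rate fits recover the generator rates", {
  sim <- make_elongation_series(elongation_sim_spec(
    n_seeds = 3, germination_times = c(40, 80, 120),
    radicle_rate = 0.25, shoot_rate = 0.12, duration = 400))
  for (tr in sim$tracks) {
    expect_equal(fit_growth_rate(tr, "radicle"), 0.25, tolerance = 1e-8)
    expect_equal(fit_growth_rate(tr, "shoot"), 0.12, tolerance = 1e-8)
  }
})

test_that("the imaging chain detects Hgerm and tracks organ lengths", {
  spec <- elongation_sim_spec(n_seeds = 3,
                              germination_times = c(24, 60, 96),
                              radicle_rate = 0.25, shoot_rate = 0.12,
                              frame_interval = 4, duration = 200,
                              mode = "image_series", rng_seed = 7)
  sim <- make_elongation_series(spec)
  hg <- detect_hgerm(sim$series)
  expect_true(all(hg$measurable))
  # within one frame interval of the truth
  expect_true(all(abs(hg$hgerm - sim$truth$hgerm) <= spec$frame_interval))
  tracks <- measure_lengths(sim$series, hg)
  for (tr in tracks) {
    s <- tr$seed_id
    truth_rad <- 0.25 * pmax(0, sim$series$times - sim$truth$hgerm[s])
    # lengths follow the truth closely once the radicle is visible
    late <- truth_rad > 2
    expect_lt(max(abs(tr$series$radicle_mm[late] - truth_rad[late])), 1)
    # measured series are non-decreasing by construction
    expect_true(all(diff(tr$series$radicle_mm) >= 0))
    # recovered growth rate within 5%
    expect_lt(abs(fit_growth_rate(tr, "radicle") - 0.25) / 0.25, 0.05)
  }
})
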
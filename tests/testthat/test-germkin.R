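test_that("MGT is the count-weighted mean of germination times", {
  rec <- tibble::tibble(time_h = c(24, 48, 96), n = c(2, 1, 1))
  expect_equal(mgt(rec), (2 * 24 + 48 + 96) / 4)
  # per-seed records (implicit n = 1)
  rec1 <- tibble::tibble(seed_id = 1:3, time_h = c(10, 20, 60),
                         censored = c(FALSE, FALSE, TRUE))
  expect_equal(mgt(rec1), 15) # censored seed excluded
  expect_error(mgt(tibble::tibble(time_h = numeric(0))), "zero germinated")
})

test_that("T50/T70 interpolate linearly and handle exact attainment", {
  rec <- tibble::tibble(time_h = c(rep(100, 4), rep(120, 2)), n = 1)
  curve <- build_curve(rec, n_total = 10, grid = c(100, 120, 140))
  # 40% at 100 h, 60% at 120 h -> T50 by linear interpolation = 110 h
  expect_equal(time_to_percent(curve, 0.5), 110)
  # step method returns the first observation at or above the target
  expect_equal(time_to_percent(curve, 0.5, method = "step"), 120)
  # exact attainment returns the observation time itself
  expect_equal(time_to_percent(curve, 0.4), 100)
  # never reached -> NA
  expect_true(is.na(time_to_percent(curve, 0.8)))
})

test_that("germination rates are percentages of sown seeds at a cutoff", {
  rec <- tibble::tibble(time_h = c(24, 48, 72), n = c(5, 5, 5))
  expect_equal(rate_at(rec, n_total = 20, cutoff = 50), 50)
  expect_equal(rate_at(rec, n_total = 20, cutoff = 100), 75)
})

test_that("assay summaries follow the per-temperature protocols", {
  p5 <- germ_protocol(5)
  expect_equal(p5$final_days, 28)
  expect_equal(p5$early_days, 17)
  expect_equal(p5$frame_interval, 4)
  expect_error(germ_protocol(15), "temperature")
  rec <- tibble::tibble(time_h = seq(24, 24 * 20, by = 24), n = 2)
  s5 <- assay_summary(rec, n_total = 50, temperature = 5)
  expect_s3_class(s5, "kinetics_stats")
  expect_false(is.na(s5$early_rate_pct))
  s10 <- assay_summary(rec, n_total = 50, temperature = 10)
  expect_true(is.na(s10$early_rate_pct))
  # events after the assay end do not count toward the final rate
  expect_equal(s10$final_rate_pct, 100 * 2 * 15 / 50)
})

test_that("event detection recovers germination within one frame", {
  truths <- c(24, 48, 96, 30, 110, 140)
  spec <- germination_sim_spec(n_seeds = 6, true_times = truths,
                               nongerminating_fraction = 0,
                               frame_interval = 2, duration = 160,
                               mode = "image_series", rng_seed = 4)
  sim <- make_germination_series(spec)
  det <- detect_events(sim$series)
  quant <- ceiling(truths / 2) * 2
  expect_true(all(abs(det$time_h - quant) <= 2))
  expect_false(any(det$censored))
  # a seed that never germinates is censored at the last frame
  spec2 <- germination_sim_spec(n_seeds = 2, true_times = c(24, 1000),
                                nongerminating_fraction = 0,
                                frame_interval = 2, duration = 60,
                                mode = "image_series", rng_seed = 4)
  det2 <- detect_events(make_germination_series(spec2)$series)
  expect_true(det2$censored[2])
  expect_equal(det2$censored_at[2], 60)
})

test_that("whole-frame camera motion aborts detection", {
  spec <- germination_sim_spec(n_seeds = 4, true_times = rep(1000, 4),
                               nongerminating_fraction = 0,
                               frame_interval = 2, duration = 20,
                               mode = "image_series", rng_seed = 4)
  ser <- make_germination_series(spec)$series
  base_get <- ser$get_frame
  shifted <- ser
  shifted$get_frame <- function(i) {
    fr <- base_get(i)
    if (i >= 5L) {
      out <- fr * 0 + 0.1
      out[, 11:ncol(fr)] <- fr[, 1:(ncol(fr) - 10)]
      out
    } else {
      fr
    }
  }
  expect_error(detect_events(shifted), "global motion")
})
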
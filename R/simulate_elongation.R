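#' Specification of a synthetic seedling elongation assay
#'
#' Emulates a growth-box time-lapse under green (inactinic) light imaged
#' in backlight: dark seeds in a row, each growing a radicle downward and
#' a shoot upward at constant rates from its own germination time,
#' inclined ~10 degrees from vertical, at 9 px/mm. Defaults describe the
#' 10 degC assay (10 seeds per box, images every 4 h for 21 days).
#'
#' @param n_seeds Seeds per box (default 10).
#' @param germination_times Hours, one per seed, or `NULL` to draw
#'   lognormal times (median ~120 h).
#' @param meanlog,sdlog Lognormal parameters for drawn germination times.
#' @param radicle_rate,shoot_rate Growth rates in mm/h, length 1 or
#'   `n_seeds`, or `NULL` to draw around 0.25 (radicle) / 0.12 (shoot)
#'   mm/h.
#' @param rate_sd SD of drawn rates (mm/h).
#' @param inclination Growth direction tilt from vertical, degrees.
#' @param scale Image scale in px/mm.
#' @param frame_interval Hours between frames.
#' @param duration Assay length in hours (default 21 days).
#' @param seed_radius_mm Seed radius.
#' @param noise_sd Pixel noise SD (0-1 intensities).
#' @param mode `"tracks"` (analytic truth tracks only) or
#'   `"image_series"` (color frames + truth).
#' @param rng_seed Integer seed.
#' @return Object of class `elongation_sim_spec`.
#' @export
elongation_sim_spec <- function(n_seeds = 10L, germination_times = NULL,
                                meanlog = log(120), sdlog = 0.25,
                                radicle_rate = NULL, shoot_rate = NULL,
                                rate_sd = 0.04, inclination = 10,
                                scale = 9, frame_interval = 4,
                                duration = 504, seed_radius_mm = 1.5,
                                noise_sd = 0.02,
                                mode = c("tracks", "image_series"),
                                rng_seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(n_seeds >= 1L, scale > 0, frame_interval > 0, duration > 0,
            is.null(radicle_rate) || all(radicle_rate >= 0),
            is.null(shoot_rate) || all(shoot_rate >= 0))
  structure(
    list(n_seeds = as.integer(n_seeds),
         germination_times = germination_times,
         meanlog = meanlog, sdlog = sdlog,
         radicle_rate = radicle_rate, shoot_rate = shoot_rate,
         rate_sd = rate_sd, inclination = inclination, scale = scale,
         frame_interval = frame_interval, duration = duration,
         seed_radius_mm = seed_radius_mm, noise_sd = noise_sd,
         mode = mode, rng_seed = as.integer(rng_seed)),
    class = "elongation_sim_spec"
  )
}

draw_elongation_truth <- function(spec) {
  withr::with_seed(spec$rng_seed, {
    tg <- spec$germination_times
    if (is.null(tg)) tg <- rlnorm(spec$n_seeds, spec$meanlog, spec$sdlog)
    rr <- spec$radicle_rate
    if (is.null(rr)) rr <- pmax(0.05, rnorm(spec$n_seeds, 0.25, spec$rate_sd))
    if (length(rr) == 1L) rr <- rep(rr, spec$n_seeds)
    sr <- spec$shoot_rate
    if (is.null(sr)) sr <- pmax(0.02, rnorm(spec$n_seeds, 0.12, spec$rate_sd / 2))
    if (length(sr) == 1L) sr <- rep(sr, spec$n_seeds)
    tibble::tibble(seed_id = seq_len(spec$n_seeds), hgerm = tg,
                   radicle_rate = rr, shoot_rate = sr)
  })
}

# Analytic truth track for one seed on the frame grid.
truth_track <- function(times, hgerm, r_rate, s_rate, seed_id, scale) {
  grow <- pmax(0, times - hgerm)
  seedling_track(seed_id = seed_id, hgerm = hgerm,
                 time_h = times,
                 radicle_mm = r_rate * grow,
                 shoot_mm = s_rate * grow,
                 scale = scale)
}

#' Simulate a seedling elongation assay
#'
#' In `tracks` mode returns noise-free [seedling_track()] objects built
#' directly from the growth model (piecewise-linear organ lengths from
#' each seed's own germination time). In `image_series` mode additionally
#' renders a lazy series of color frames for the imaging chain
#' ([detect_hgerm()], [measure_lengths()]).
#'
#' @param spec An [elongation_sim_spec()].
#' @return List with `truth` (per-seed germination time and rates),
#'   `tracks` (list of `seedling_track`), and in image mode `series`.
#' @export
make_elongation_series <- function(spec) {
  stopifnot(inherits(spec, "elongation_sim_spec"))
  truth <- draw_elongation_truth(spec)
  times <- seq(0, spec$duration, by = spec$frame_interval)
  tracks <- lapply(seq_len(spec$n_seeds), function(s)
    truth_track(times, truth$hgerm[s], truth$radicle_rate[s],
                truth$shoot_rate[s], s, spec$scale))
  out <- list(truth = truth, tracks = tracks)
  if (spec$mode == "image_series") {
    out$series <- elongation_frame_series(spec, truth)
  }
  out
}

# Lazy color frame series. Backlit geometry: bright background, dark
# seeds/organs on the green channel; red and blue planes carry no signal.
elongation_frame_series <- function(spec, truth) {
  r_px <- round(spec$seed_radius_mm * spec$scale)
  incl <- spec$inclination * pi / 180
  max_down <- max(truth$radicle_rate) * spec$duration * spec$scale
  max_up <- max(truth$shoot_rate) * spec$duration * spec$scale
  # Inclined organs drift sideways (radicle one way, shoot the other);
  # the box spaces seeds so each seedling stays in its own lane.
  drift_r <- ceiling(max_down * sin(incl))
  drift_s <- ceiling(max_up * sin(incl))
  cell <- 2L * r_px + 40L + drift_r + drift_s
  width <- spec$n_seeds * cell
  y_seed <- ceiling(max_up * cos(incl)) + r_px + 20L
  height <- y_seed + r_px + ceiling(max_down * cos(incl)) + 20L
  x_off <- drift_s + r_px + 20L # seed offset inside its lane
  centers <- cbind(x = (seq_len(spec$n_seeds) - 1L) * cell + x_off,
                   y = rep(y_seed, spec$n_seeds))
  times <- seq(0, spec$duration, by = spec$frame_interval)
  get_frame <- function(i) {
    t <- times[i]
    g <- matrix(0.85, nrow = height, ncol = width)
    for (s in seq_len(spec$n_seeds)) {
      cx <- centers[s, "x"]; cy <- centers[s, "y"]
      g <- draw_disk(g, cx, cy, r_px, 0.15)
      grow <- t - truth$hgerm[s]
      if (grow > 0) {
        rad_px <- truth$radicle_rate[s] * grow * spec$scale
        if (rad_px >= 1) {
          g <- draw_segment(g, cx, cy + r_px,
                            cx + rad_px * sin(incl), cy + r_px + rad_px * cos(incl),
                            0.15)
        }
        sh_px <- truth$shoot_rate[s] * grow * spec$scale
        if (sh_px >= 1) {
          g <- draw_segment(g, cx, cy - r_px,
                            cx - sh_px * sin(incl), cy - r_px - sh_px * cos(incl),
                            0.15)
        }
      }
    }
    if (spec$noise_sd > 0) {
      g <- withr::with_seed(spec$rng_seed + 2000L + i, {
        pmin(pmax(g + matrix(rnorm(length(g), sd = spec$noise_sd),
                             nrow = height), 0), 1)
      })
    }
    fr <- array(0.5, dim = c(height, width, 3L))
    fr[, , 2L] <- g
    fr
  }
  structure(
    list(times = times, get_frame = get_frame, centers = centers,
         seed_radius_px = r_px, cell_px = cell, px_per_mm = spec$scale,
         size = c(height, width), color = TRUE),
    class = "frame_series"
  )
}
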
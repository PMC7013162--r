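#' Specification of a synthetic germination assay
#'
#' Emulates a Jacobsen-tank germination time course: seeds on a grid,
#' photographed at a fixed interval, each germinated seed showing a small
#' displacement and a radicle outgrowth from its germination time on. Per
#' temperature, imaging runs every 2 h (10 and 20 degC) or every 4 h
#' (5 degC); defaults describe the 10 degC assay.
#'
#' @param n_seeds Seeds sown (one replicate of 25 by default).
#' @param true_times Germination times in hours, one per seed, or `NULL`
#'   to draw them from a lognormal distribution.
#' @param meanlog,sdlog Lognormal parameters used when `true_times` is
#'   `NULL`. Defaults give a median germination time of ~120 h, typical of
#'   sugar beet at 10 degC.
#' @param nongerminating_fraction Fraction of sown seeds that never
#'   germinate (dead/dormant), 0-1.
#' @param frame_interval Hours between images.
#' @param duration Assay length in hours.
#' @param mode `"event_table"` (records only) or `"image_series"`.
#' @param px_per_mm Image scale for image mode.
#' @param seed_radius_mm Seed radius drawn in image mode.
#' @param move_px Seed displacement in pixels at the germination frame.
#' @param radicle_px_per_h Radicle growth rate in pixels per hour.
#' @param radicle_max_px Drawn radicle length cap: the simulator emulates
#'   the protrusion phase that event detection relies on, not week-long
#'   radicle growth (which would grow seeds into their neighbors'
#'   regions — the elongation assay, with its own generator, covers
#'   that).
#' @param noise_sd Pixel noise SD (intensities in 0-1).
#' @param rng_seed Integer seed; all randomness flows through it.
#' @return Object of class `germination_sim_spec`.
#' @export
germination_sim_spec <- function(n_seeds = 25L, true_times = NULL,
                                 meanlog = log(120), sdlog = 0.25,
                                 nongerminating_fraction = 0.05,
                                 frame_interval = 2, duration = 360,
                                 mode = c("event_table", "image_series"),
                                 px_per_mm = 5, seed_radius_mm = 1.6,
                                 move_px = 2, radicle_px_per_h = 1,
                                 radicle_max_px = 12L,
                                 noise_sd = 0.02, rng_seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(n_seeds >= 1L, frame_interval > 0, duration > 0,
            nongerminating_fraction >= 0, nongerminating_fraction <= 1,
            is.null(true_times) || (length(true_times) == n_seeds &&
                                      all(true_times >= 0)))
  structure(
    list(n_seeds = as.integer(n_seeds), true_times = true_times,
         meanlog = meanlog, sdlog = sdlog,
         nongerminating_fraction = nongerminating_fraction,
         frame_interval = frame_interval, duration = duration, mode = mode,
         px_per_mm = px_per_mm, seed_radius_mm = seed_radius_mm,
         move_px = move_px, radicle_px_per_h = radicle_px_per_h,
         radicle_max_px = as.integer(radicle_max_px),
         noise_sd = noise_sd, rng_seed = as.integer(rng_seed)),
    class = "germination_sim_spec"
  )
}

# Draw per-seed truth: germination time (NA for non-germinating seeds).
draw_germination_truth <- function(spec) {
  withr::with_seed(spec$rng_seed, {
    times <- spec$true_times
    if (is.null(times)) times <- rlnorm(spec$n_seeds, spec$meanlog, spec$sdlog)
    n_ng <- round(spec$nongerminating_fraction * spec$n_seeds)
    ng <- if (n_ng > 0) sample(spec$n_seeds, n_ng) else integer(0)
    times[ng] <- NA_real_
    times
  })
}

#' Simulate a germination assay
#'
#' In `event_table` mode returns per-seed germination records as the
#' imaging system would produce them: event times quantized up to the next
#' frame, seeds that never trigger (or trigger past the assay end)
#' censored at the last frame. In `image_series` mode returns a lazy frame
#' series on which [detect_events()] can be run. True (continuous) times
#' are returned alongside in both modes.
#'
#' @param spec A [germination_sim_spec()].
#' @return List with `records` (event_table mode) or `series`
#'   (image_series mode), plus `truth` (tibble `seed_id`, `true_time`,
#'   `germinated`).
#' @export
make_germination_series <- function(spec) {
  stopifnot(inherits(spec, "germination_sim_spec"))
  times <- draw_germination_truth(spec)
  truth <- tibble::tibble(seed_id = seq_len(spec$n_seeds),
                          true_time = times,
                          germinated = !is.na(times) & times <= spec$duration)
  if (spec$mode == "event_table") {
    frame_time <- ceiling(times / spec$frame_interval) * spec$frame_interval
    censored <- is.na(times) | frame_time > spec$duration
    records <- tibble::tibble(
      seed_id = seq_len(spec$n_seeds),
      time_h = ifelse(censored, NA_real_, frame_time),
      censored = censored,
      censored_at = ifelse(censored, spec$duration, NA_real_),
      basis = ifelse(censored, NA_character_, "simulated")
    )
    return(list(records = records, truth = truth))
  }
  list(series = germination_frame_series(spec, times), truth = truth)
}

# Lazy frame series for image mode. Frames are regenerated on demand and
# deterministically (noise seeded per frame), so long series do not need
# to be held in memory.
germination_frame_series <- function(spec, times) {
  r_px <- round(spec$seed_radius_mm * spec$px_per_mm)
  cell <- 2 * r_px + 30L
  cols <- ceiling(sqrt(spec$n_seeds))
  rows <- ceiling(spec$n_seeds / cols)
  width <- cols * cell
  height <- rows * cell
  centers <- cbind(
    x = ((seq_len(spec$n_seeds) - 1L) %% cols + 0.5) * cell,
    y = ((seq_len(spec$n_seeds) - 1L) %/% cols + 0.5) * cell
  )
  frame_times <- seq(0, spec$duration, by = spec$frame_interval)
  get_frame <- function(i) {
    t <- frame_times[i]
    img <- matrix(0.1, nrow = height, ncol = width)
    for (s in seq_len(spec$n_seeds)) {
      cx <- centers[s, "x"]; cy <- centers[s, "y"]
      germ <- !is.na(times[s]) && t >= times[s]
      if (germ) cx <- cx + spec$move_px
      img <- draw_disk(img, cx, cy, r_px, 0.8)
      if (germ) {
        len <- min(round(spec$radicle_px_per_h * (t - times[s])),
                   spec$radicle_max_px)
        if (len > 0) {
          img <- draw_segment(img, cx, cy + r_px, cx, cy + r_px + len, 0.8)
        }
      }
    }
    if (spec$noise_sd > 0) {
      img <- withr::with_seed(spec$rng_seed + 1000L + i, {
        pmin(pmax(img + matrix(rnorm(length(img), sd = spec$noise_sd),
                               nrow = height), 0), 1)
      })
    }
    img
  }
  structure(
    list(times = frame_times, get_frame = get_frame,
         centers = centers, seed_radius_px = r_px, cell_px = cell,
         px_per_mm = spec$px_per_mm, size = c(height, width)),
    class = "frame_series"
  )
}

#' @export
print.frame_series <- function(x, ...) {
  cat(sprintf("<frame_series> %d frames of %d x %d px, t = %g..%g h\n",
              length(x$times), x$size[1], x$size[2],
              min(x$times), max(x$times)))
  invisible(x)
}

# Rasterize a filled disk onto an image matrix (row = y, col = x).
draw_disk <- function(img, cx, cy, r, value) {
  xs <- max(1, floor(cx - r)):min(ncol(img), ceiling(cx + r))
  ys <- max(1, floor(cy - r)):min(nrow(img), ceiling(cy + r))
  for (y in ys) {
    dx2 <- r^2 - (y - cy)^2
    if (dx2 < 0) next
    dx <- sqrt(dx2)
    x0 <- max(1, ceiling(cx - dx)); x1 <- min(ncol(img), floor(cx + dx))
    if (x0 <= x1) img[y, x0:x1] <- value
  }
  img
}

# Rasterize a 1-px line (Bresenham on rounded endpoints).
draw_segment <- function(img, x0, y0, x1, y1, value) {
  n <- max(abs(round(x1) - round(x0)), abs(round(y1) - round(y0))) + 1L
  xs <- round(seq(x0, x1, length.out = n))
  ys <- round(seq(y0, y1, length.out = n))
  ok <- xs >= 1 & xs <= ncol(img) & ys >= 1 & ys <= nrow(img)
  img[cbind(ys[ok], xs[ok])] <- value
  img
}
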
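#' Detection thresholds for germination events
#'
#' @param movement_px Minimum centroid displacement (pixels) between
#'   consecutive frames that counts as the seed movement accompanying
#'   radicle emergence.
#' @param protrusion_px Minimum extent (pixels, measured as outgrowth
#'   pixel count of the thin radicle, a skeleton-length proxy) of a new
#'   outgrowth from the seed contour.
#' @param intensity_threshold Binarization threshold for frames in 0-1.
#' @param global_motion_px If the median per-seed displacement of a frame
#'   exceeds this, the whole frame moved (camera shift) and detection
#'   aborts.
#' @param baseline_dilate Dilation steps applied to the sown-seed mask
#'   before outgrowth detection.
#' @return List of class `germ_detect_config`.
#' @export
germ_detect_config <- function(movement_px = 2, protrusion_px = 5,
                               intensity_threshold = 0.5,
                               global_motion_px = 5,
                               baseline_dilate = 2L) {
  structure(list(movement_px = movement_px, protrusion_px = protrusion_px,
                 intensity_threshold = intensity_threshold,
                 global_motion_px = global_motion_px,
                 baseline_dilate = as.integer(baseline_dilate)),
            class = "germ_detect_config")
}

# Largest foreground component of a binary ROI; returns a logical matrix.
largest_component <- function(bin) {
  lab <- label_components(bin, connectivity = 26L) # 8-connectivity in 2D
  n <- attr(lab, "n_components")
  if (n == 0L) return(bin & FALSE)
  sizes <- tabulate(lab[lab > 0L], nbins = n)
  lab == which.max(sizes)
}

roi_bounds <- function(center, half, size) {
  y0 <- max(1L, round(center[2] - half)); y1 <- min(size[1], round(center[2] + half))
  x0 <- max(1L, round(center[1] - half)); x1 <- min(size[2], round(center[1] + half))
  list(x = x0:x1, y = y0:y1)
}

#' Detect germination events in a time-lapse series
#'
#' Per seed region, germination is called at the first frame where either
#' the seed's centroid moved at least `movement_px` relative to the
#' previous frame, or a new outgrowth from the seed contour reaches
#' `protrusion_px`; the earlier criterion wins. Seeds that never trigger
#' are censored at the last frame. If the median displacement of all
#' seeds in a frame exceeds `global_motion_px`, whole-frame motion is
#' assumed and an error is raised (fixed-camera contract).
#'
#' @param series A `frame_series` (see [make_germination_series()]), or a
#'   list with `times` and `get_frame`; seed centers are taken from the
#'   series metadata or detected on frame 1.
#' @param config A [germ_detect_config()].
#' @return Tibble of germination records: `seed_id`, `time_h` (NA if
#'   censored), `censored`, `censored_at`, `basis` (movement, protrusion
#'   or both).
#' @export
detect_events <- function(series, config = germ_detect_config()) {
  stopifnot(length(series$times) >= 2L)
  n_frames <- length(series$times)
  f1 <- series$get_frame(1L)
  size <- dim(f1)
  centers <- series$centers
  if (is.null(centers)) {
    lab <- label_components(f1 > config$intensity_threshold)
    n <- attr(lab, "n_components")
    centers <- t(vapply(seq_len(n), function(l) {
      yx <- which(lab == l, arr.ind = TRUE)
      c(x = mean(yx[, 2]), y = mean(yx[, 1]))
    }, numeric(2)))
  }
  n_seeds <- nrow(centers)
  half <- if (!is.null(series$cell_px)) series$cell_px / 2
          else min(dist(centers)) / 2
  rois <- lapply(seq_len(n_seeds), function(s)
    roi_bounds(centers[s, ], half, size))
  baseline <- vector("list", n_seeds)
  prev_centroid <- matrix(NA_real_, n_seeds, 2)
  for (s in seq_len(n_seeds)) {
    bin <- f1[rois[[s]]$y, rois[[s]]$x] > config$intensity_threshold
    comp <- largest_component(bin)
    baseline[[s]] <- dilate_mask(comp, config$baseline_dilate)
    yx <- which(comp, arr.ind = TRUE)
    prev_centroid[s, ] <- c(mean(yx[, 1]), mean(yx[, 2]))
  }
  time_h <- rep(NA_real_, n_seeds)
  basis <- rep(NA_character_, n_seeds)
  open <- rep(TRUE, n_seeds)
  for (k in 2:n_frames) {
    if (!any(open)) break
    fr <- series$get_frame(k)
    disp <- rep(NA_real_, n_seeds)
    trig_move <- rep(FALSE, n_seeds)
    trig_prot <- rep(FALSE, n_seeds)
    for (s in seq_len(n_seeds)) {
      bin <- fr[rois[[s]]$y, rois[[s]]$x] > config$intensity_threshold
      comp <- largest_component(bin)
      if (!any(comp)) next
      yx <- which(comp, arr.ind = TRUE)
      cen <- c(mean(yx[, 1]), mean(yx[, 2]))
      disp[s] <- sqrt(sum((cen - prev_centroid[s, ])^2))
      prev_centroid[s, ] <- cen
      if (!open[s]) next
      trig_move[s] <- disp[s] >= config$movement_px
      outgrowth <- sum(comp & !baseline[[s]])
      trig_prot[s] <- outgrowth >= config$protrusion_px
    }
    if (median(disp, na.rm = TRUE) > config$global_motion_px) {
      stop("global motion detected at frame ", k,
           ": median seed displacement ",
           signif(median(disp, na.rm = TRUE), 3), " px")
    }
    hit <- open & (trig_move | trig_prot)
    if (any(hit)) {
      time_h[hit] <- series$times[k]
      basis[hit] <- ifelse(trig_move[hit] & trig_prot[hit], "both",
                           ifelse(trig_move[hit], "movement", "protrusion"))
      open[hit] <- FALSE
    }
  }
  tibble::tibble(
    seed_id = seq_len(n_seeds),
    time_h = time_h,
    censored = is.na(time_h),
    censored_at = ifelse(is.na(time_h), series$times[n_frames], NA_real_),
    basis = basis
  )
}

germinated_times <- function(records) {
  if ("censored" %in% names(records)) {
    records <- records[!records$censored & !is.na(records$time_h), , drop = FALSE]
  } else {
    records <- records[!is.na(records$time_h), , drop = FALSE]
  }
  n <- if ("n" %in% names(records)) records[["n"]] else rep(1L, nrow(records))
  list(t = records$time_h, n = n)
}

#' Cumulative germination curve
#'
#' Step function of the cumulative germinated fraction of the sown
#' population, evaluated on a time grid.
#'
#' @param records Germination records ([detect_events()] output or a
#'   table with `time_h` and optionally `censored` and count `n`).
#' @param n_total Number of seeds sown (>= number of records).
#' @param grid Observation times in hours (strictly increasing).
#' @return Object of class `germination_curve`: tibble `time_h`,
#'   `fraction`, with `n_total` as an attribute.
#' @export
build_curve <- function(records, n_total, grid) {
  ev <- germinated_times(records)
  stopifnot(n_total >= sum(ev$n), all(diff(grid) > 0))
  frac <- vapply(grid, function(g) sum(ev$n[ev$t <= g]) / n_total, numeric(1))
  out <- tibble::tibble(time_h = grid, fraction = frac)
  attr(out, "n_total") <- n_total
  class(out) <- c("germination_curve", class(out))
  out
}

#' Mean germination time
#'
#' Count-weighted mean `sum(n_i t_i) / sum(n_i)` over germination events;
#' with one record per seed this is the arithmetic mean of the individual
#' germination times. Censored seeds are excluded.
#'
#' @param records Germination records (optionally with a count column
#'   `n`).
#' @return MGT in hours.
#' @export
mgt <- function(records) {
  ev <- germinated_times(records)
  if (length(ev$t) == 0L) stop("MGT undefined: zero germinated seeds")
  sum(ev$n * ev$t) / sum(ev$n)
}

#' Time to reach a germination percentage
#'
#' Reads T50/T70-style percentiles off a cumulative germination curve.
#' Fractions are relative to the sown population. The default linearly
#' interpolates between the two observations bracketing `p`; if `p` is
#' attained exactly at an observation, that observation's time is
#' returned. `method = "step"` returns the first observation at or above
#' `p`.
#'
#' @param curve A [build_curve()] result.
#' @param p Target fraction, 0 < p < 1.
#' @param method `"linear"` or `"step"`.
#' @return Time in hours, or `NA` if the curve never reaches `p`
#'   ("not reached").
#' @export
time_to_percent <- function(curve, p, method = c("linear", "step")) {
  method <- match.arg(method)
  stopifnot(p > 0, p < 1)
  tt <- c(0, curve$time_h)
  ff <- c(0, curve$fraction)
  if (max(ff) < p) return(NA_real_)
  i <- which(ff >= p)[1]
  if (ff[i] == p || method == "step" || i == 1L) return(tt[i])
  tt[i - 1] + (p - ff[i - 1]) / (ff[i] - ff[i - 1]) * (tt[i] - tt[i - 1])
}

#' Germination rate at a cutoff time
#'
#' @param records Germination records.
#' @param n_total Seeds sown.
#' @param cutoff Hours from sowing (> 0).
#' @return Percentage of sown seeds germinated by `cutoff`.
#' @export
rate_at <- function(records, n_total, cutoff) {
  stopifnot(cutoff > 0)
  ev <- germinated_times(records)
  100 * sum(ev$n[ev$t <= cutoff]) / n_total
}

#' Assay protocol per temperature
#'
#' Imaging interval, final count and (for 5 degC) early count of the
#' germination assays: final rates after 28, 15 and 6 days at 5, 10 and
#' 20 degC; an early count after 17 days at 5 degC as an extra vigor
#' measure; images every 4 h at 5 degC and every 2 h otherwise.
#'
#' @param temperature 5, 10 or 20 (degC).
#' @return List with `temperature`, `frame_interval` (h), `final_days`,
#'   `early_days` (NULL if no early count).
#' @export
germ_protocol <- function(temperature) {
  if (!temperature %in% c(5, 10, 20)) stop("temperature must be 5, 10 or 20")
  switch(as.character(temperature),
    "5"  = list(temperature = 5,  frame_interval = 4, final_days = 28,
                early_days = 17),
    "10" = list(temperature = 10, frame_interval = 2, final_days = 15,
                early_days = NULL),
    "20" = list(temperature = 20, frame_interval = 2, final_days = 6,
                early_days = NULL)
  )
}

#' Germination kinetics summary for one assay
#'
#' Computes the kinetics variables of one temperature's assay from the
#' pooled records of its replicates: MGT, T50, T70, the final germination
#' rate at the protocol's assay end, and (5 degC only) the early rate.
#' Events after the assay end are treated as censored.
#'
#' @param records Pooled germination records.
#' @param n_total Total seeds sown across replicates.
#' @param temperature 5, 10 or 20 degC.
#' @param protocol Assay protocol; defaults to [germ_protocol()] of the
#'   temperature.
#' @return One-row tibble of class `kinetics_stats`: `temperature`,
#'   `mgt_h`, `t50_h`, `t70_h`, `early_rate_pct` (NA when the protocol
#'   has no early count), `final_rate_pct`, `n_total`, `duration_days`.
#' @export
assay_summary <- function(records, n_total, temperature,
                          protocol = germ_protocol(temperature)) {
  final_h <- protocol$final_days * 24
  ev <- germinated_times(records)
  keep <- ev$t <= final_h
  rec <- tibble::tibble(time_h = ev$t[keep], n = ev$n[keep])
  grid <- seq(protocol$frame_interval, final_h, by = protocol$frame_interval)
  curve <- build_curve(rec, n_total, grid)
  out <- tibble::tibble(
    temperature = protocol$temperature,
    mgt_h = if (nrow(rec) > 0) mgt(rec) else NA_real_,
    t50_h = time_to_percent(curve, 0.5),
    t70_h = time_to_percent(curve, 0.7),
    early_rate_pct = if (!is.null(protocol$early_days))
      rate_at(rec, n_total, protocol$early_days * 24) else NA_real_,
    final_rate_pct = rate_at(rec, n_total, final_h),
    n_total = n_total,
    duration_days = protocol$final_days
  )
  class(out) <- c("kinetics_stats", class(out))
  out
}
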
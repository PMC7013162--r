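#' Seedling track container
#'
#' Organ-length time series of one seedling, aligned to its own
#' germination hour.
#'
#' @param seed_id Seed identifier.
#' @param hgerm Germination hour (Hgerm), from sowing.
#' @param time_h Frame times in hours.
#' @param radicle_mm,shoot_mm Organ lengths in mm at each frame.
#' @param scale Image scale in px/mm.
#' @param truncated TRUE when the seedling left the field of view and the
#'   track stops early.
#' @return Object of class `seedling_track`.
#' @export
seedling_track <- function(seed_id, hgerm, time_h, radicle_mm, shoot_mm,
                           scale, truncated = FALSE) {
  stopifnot(length(time_h) == length(radicle_mm),
            length(time_h) == length(shoot_mm))
  structure(
    list(seed_id = seed_id, hgerm = hgerm,
         series = tibble::tibble(time_h = time_h, radicle_mm = radicle_mm,
                                 shoot_mm = shoot_mm),
         scale = scale, truncated = truncated),
    class = "seedling_track"
  )
}

#' @export
print.seedling_track <- function(x, ...) {
  cat(sprintf("<seedling_track> seed %s, Hgerm = %s h, %d frames%s\n",
              x$seed_id, signif(x$hgerm, 4), nrow(x$series),
              if (x$truncated) " (truncated)" else ""))
  invisible(x)
}

#' Extract the green channel of a color frame
#'
#' The elongation assay is lit by green LEDs only, so all signal lives in
#' the green plane; it is returned unchanged.
#'
#' @param frame Numeric array with at least 3 channels in the third
#'   dimension.
#' @return Grayscale matrix (the green plane).
#' @export
green_channel <- function(frame) {
  if (!(is.array(frame) && length(dim(frame)) == 3L && dim(frame)[3] >= 3L)) {
    stop("frame must have at least 3 channels")
  }
  frame[, , 2L]
}

#' Detection settings for the elongation assay
#'
#' @param visibility_px Minimum outgrowth extent in pixels for a radicle
#'   to count as visible (default 5 px, about 0.56 mm at 9 px/mm).
#' @param intensity_threshold Green-channel binarization threshold;
#'   objects are darker than background (backlight).
#' @param baseline_dilate Dilation steps of the sown-seed mask used to
#'   separate organ pixels from the seed body.
#' @param polyline_step Resampling step (px) for skeleton path lengths.
#' @param jitter_mm Isotonic clipping tolerance for length series.
#' @return List of class `elong_config`.
#' @export
elong_config <- function(visibility_px = 5, intensity_threshold = 0.5,
                         baseline_dilate = 2L, polyline_step = 8L,
                         jitter_mm = 0.5) {
  structure(list(visibility_px = visibility_px,
                 intensity_threshold = intensity_threshold,
                 baseline_dilate = as.integer(baseline_dilate),
                 polyline_step = as.integer(polyline_step),
                 jitter_mm = jitter_mm),
            class = "elong_config")
}

# Binarize one elongation frame (objects dark on bright backlight).
elong_binary <- function(series, i, config) {
  fr <- series$get_frame(i)
  g <- if (length(dim(fr)) == 3L) green_channel(fr) else fr
  g < config$intensity_threshold
}

# Per-seed baseline: seed-body mask on frame 1, its dilation, and centroid.
# Each seed's region is a full-height lane bounded midway to its neighbors,
# because organs grow the whole image height (radicle down, shoot up).
elong_baseline <- function(series, config) {
  bin1 <- elong_binary(series, 1L, config)
  size <- dim(bin1)
  centers <- series$centers
  n_seeds <- nrow(centers)
  ord <- order(centers[, "x"])
  xs <- centers[ord, "x"]
  cuts <- floor(c(0, (head(xs, -1) + xs[-1]) / 2, size[2]))
  rois <- vector("list", n_seeds)
  for (i in seq_len(n_seeds)) {
    rois[[ord[i]]] <- list(x = (cuts[i] + 1L):cuts[i + 1L], y = seq_len(size[1]))
  }
  # Overlap guard: seed bodies must stay inside their own regions.
  overlapping <- logical(n_seeds)
  body <- vector("list", n_seeds)
  for (s in seq_len(n_seeds)) {
    comp <- largest_component(bin1[rois[[s]]$y, rois[[s]]$x])
    body[[s]] <- comp
    # a seed body reaching its ROI edge means neighboring regions overlap
    overlapping[s] <- any(comp[, c(1, ncol(comp))]) || any(comp[1, ]) ||
      any(comp[nrow(comp), ])
  }
  list(rois = rois, body = body, overlapping = overlapping)
}

#' Detect each seed's germination hour from an elongation series
#'
#' Hgerm of a seed is the first frame hour at which a contour outgrowth
#' (radicle) of at least `visibility_px` pixels is visible. Seeds whose
#' regions overlap on the first frame are flagged unmeasurable; seeds
#' that never show an outgrowth are censored.
#'
#' @param series Elongation `frame_series`.
#' @param config An [elong_config()].
#' @return Tibble: `seed_id`, `hgerm` (NA if censored/unmeasurable),
#'   `censored`, `measurable`.
#' @export
detect_hgerm <- function(series, config = elong_config()) {
  stopifnot(length(series$times) >= 2L)
  base <- elong_baseline(series, config)
  n_seeds <- length(base$body)
  baseline <- lapply(base$body, dilate_mask, steps = config$baseline_dilate)
  hgerm <- rep(NA_real_, n_seeds)
  open <- !base$overlapping
  for (k in 2:length(series$times)) {
    if (!any(open)) break
    bin <- elong_binary(series, k, config)
    for (s in which(open)) {
      roi <- base$rois[[s]]
      comp <- largest_component(bin[roi$y, roi$x])
      if (sum(comp & !baseline[[s]]) >= config$visibility_px) {
        hgerm[s] <- series$times[k]
        open[s] <- FALSE
      }
    }
  }
  tibble::tibble(
    seed_id = seq_len(n_seeds),
    hgerm = hgerm,
    censored = is.na(hgerm) & !base$overlapping,
    measurable = !base$overlapping
  )
}

# Geodesic path length (mm) of one organ component: BFS from the pixels
# adjacent to the seed body, walk back from the deepest pixel, resample
# the path every `step` px and sum Euclidean segment lengths (robust to
# the staircase overestimate of naive chain codes).
organ_path_length_mm <- function(organ, body, scale, step = 8L) {
  if (!any(organ)) return(0)
  nr <- nrow(organ)
  start <- which(organ & dilate_mask(body)) # organ pixels touching the body
  if (length(start) == 0L) {
    # disconnected: fall back to the organ pixel closest to the body
    byx <- which(body, arr.ind = TRUE)
    oyx <- which(organ, arr.ind = TRUE)
    bc <- colMeans(byx)
    dd <- (oyx[, 1] - bc[1])^2 + (oyx[, 2] - bc[2])^2
    start <- (oyx[which.min(dd), 2] - 1L) * nr + oyx[which.min(dd), 1L]
  }
  idx <- which(organ)
  depth <- rep(NA_integer_, length(idx))
  parent <- rep(NA_integer_, length(idx))
  lookup <- integer(length(organ)); lookup[idx] <- seq_along(idx)
  queue <- lookup[start]
  depth[queue] <- 0L
  head_i <- 1L
  offs <- c(-1L - nr, -nr, 1L - nr, -1L, 1L, nr - 1L, nr, nr + 1L)
  while (head_i <= length(queue)) {
    cur <- queue[head_i]; head_i <- head_i + 1L
    p <- idx[cur]
    py <- (p - 1L) %% nr + 1L
    for (o in offs) {
      q <- p + o
      if (q < 1L || q > length(organ)) next
      qy <- (q - 1L) %% nr + 1L
      if (abs(qy - py) > 1L) next # column wrap guard
      j <- lookup[q]
      if (j > 0L && is.na(depth[j])) {
        depth[j] <- depth[cur] + 1L
        parent[j] <- cur
        queue <- c(queue, j)
      }
    }
  }
  reached <- which(!is.na(depth))
  tip <- reached[which.max(depth[reached])]
  # walk back to a start pixel, collecting the path
  path <- tip
  while (!is.na(parent[path[length(path)]])) {
    path <- c(path, parent[path[length(path)]])
  }
  p_idx <- idx[path]
  ys <- (p_idx - 1L) %% nr + 1L
  xs <- (p_idx - 1L) %/% nr + 1L
  keep <- unique(c(seq(1L, length(path), by = step), length(path)))
  sum(sqrt(diff(xs[keep])^2 + diff(ys[keep])^2)) / scale
}

#' Measure organ elongation tracks
#'
#' Per frame, the seedling mask of each seed is split at the (dilated)
#' seed body; connected organ parts are classified by net vertical
#' direction — downward parts are radicle, upward parts shoot (the
#' seedlings follow their gravitropism in the near-vertical boxes) — and
#' their geodesic path lengths accumulate into per-seed tracks aligned to
#' each seed's own Hgerm. Length series are isotonically clipped
#' (non-decreasing) before use.
#'
#' @param series Elongation `frame_series`.
#' @param hgerm Tibble from [detect_hgerm()] (or any table with
#'   `seed_id`, `hgerm`).
#' @param config An [elong_config()].
#' @return List of [seedling_track()] objects (unmeasurable seeds
#'   omitted).
#' @export
measure_lengths <- function(series, hgerm, config = elong_config()) {
  base <- elong_baseline(series, config)
  n_seeds <- length(base$body)
  baseline <- lapply(base$body, dilate_mask, steps = config$baseline_dilate)
  n_frames <- length(series$times)
  rad <- matrix(0, n_frames, n_seeds)
  sho <- matrix(0, n_frames, n_seeds)
  truncated <- logical(n_seeds)
  measurable <- !base$overlapping
  for (k in seq_len(n_frames)) {
    bin <- elong_binary(series, k, config)
    for (s in which(measurable)) {
      roi <- base$rois[[s]]
      sub <- bin[roi$y, roi$x]
      comp <- largest_component(sub)
      organ <- comp & !baseline[[s]]
      if (!any(organ)) next
      # seed centroid row separates radicle (below) from shoot (above)
      byx <- which(base$body[[s]], arr.ind = TRUE)
      cy <- mean(byx[, 1])
      lab <- label_components(organ)
      for (l in seq_len(attr(lab, "n_components"))) {
        part <- lab == l
        pyx <- which(part, arr.ind = TRUE)
        len <- organ_path_length_mm(part, base$body[[s]], series$px_per_mm,
                                    config$polyline_step)
        if (mean(pyx[, 1]) > cy) rad[k, s] <- rad[k, s] + len
        else sho[k, s] <- sho[k, s] + len
      }
      # field-of-view check: organ touching the ROI edge truncates the track
      if (any(organ[c(1, nrow(organ)), ]) || any(organ[, c(1, ncol(organ))])) {
        truncated[s] <- TRUE
      }
    }
  }
  lapply(which(measurable), function(s) {
    hg <- hgerm$hgerm[match(s, hgerm$seed_id)]
    seedling_track(seed_id = s, hgerm = hg,
                   time_h = series$times,
                   radicle_mm = cummax(rad[, s]),
                   shoot_mm = cummax(sho[, s]),
                   scale = series$px_per_mm,
                   truncated = truncated[s])
  })
}

#' Radicle length at a fixed offset after germination
#'
#' RadLg: the radicle length exactly `offset` hours after the seed's own
#' germination time, linearly interpolated between the bracketing frames.
#' The assay's nominal offset is seven days (168 h).
#'
#' @param track A [seedling_track()].
#' @param offset Hours after Hgerm (default 168).
#' @return Radicle length in mm.
#' @export
radlg_at_offset <- function(track, offset = 168) {
  stopifnot(inherits(track, "seedling_track"))
  if (is.na(track$hgerm)) stop("track has no germination time")
  target <- track$hgerm + offset
  ts <- track$series$time_h
  if (target > max(ts)) stop("track too short: ends at ", max(ts),
                             " h, need ", target, " h")
  approx(ts, track$series$radicle_mm, xout = target)$y
}

#' Fit the elongation rate of one organ
#'
#' Linear growth-rate estimate (mm/h) over the post-germination part of a
#' track.
#'
#' @param track A [seedling_track()].
#' @param organ `"radicle"` or `"shoot"`.
#' @return Slope in mm/h.
#' @export
fit_growth_rate <- function(track, organ = c("radicle", "shoot")) {
  organ <- match.arg(organ)
  col <- if (organ == "radicle") "radicle_mm" else "shoot_mm"
  df <- track$series[track$series$time_h >= track$hgerm, , drop = FALSE]
  df <- df[df[[col]] > 0, , drop = FALSE]
  if (nrow(df) < 2L) stop("not enough growing frames to fit a rate")
  unname(coef(lm(df[[col]] ~ df$time_h))[2])
}
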
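#' Specification of a multi-seed synthetic scan
#'
#' A tomography scan holds a fixed number of seeds (25 per scan in the
#' assay this package models) laid out on a grid in one plane, each seed a
#' jittered copy of a base [phantom_spec()] (random size factor and
#' rotation about the vertical axis).
#'
#' @param n_seeds Number of seeds in the scan (default 25).
#' @param phantom Base `phantom_spec` for every seed.
#' @param voxel_spacing Scan voxel spacing in mm (default 0.1; coarser than
#'   the single-seed default so that a 25-seed scan stays around 200^3
#'   voxels).
#' @param jitter_sd SD of the per-seed log size factor (0 = identical
#'   seeds).
#' @param rotate Randomly rotate each seed about z.
#' @param gap_mm Minimum surface-to-surface gap between seeds in mm;
#'   raised to 2 voxels if smaller.
#' @param layout Optional matrix of seed centers in mm (n x 3); default is
#'   an automatic square grid.
#' @param volume_shape Optional volume shape in voxels; default sized to
#'   the layout.
#' @param rng_seed Integer seed driving jitter and noise.
#' @return Object of class `scan_spec`.
#' @export
scan_spec <- function(n_seeds = 25L, phantom = phantom_spec(),
                      voxel_spacing = 0.1, jitter_sd = 0.04, rotate = TRUE,
                      gap_mm = 0.5, layout = NULL, volume_shape = NULL,
                      rng_seed = 1L) {
  stopifnot(n_seeds >= 1L, voxel_spacing > 0, jitter_sd >= 0)
  gap_mm <- max(gap_mm, 2 * voxel_spacing)
  structure(
    list(n_seeds = as.integer(n_seeds), phantom = phantom,
         voxel_spacing = voxel_spacing, jitter_sd = jitter_sd,
         rotate = rotate, gap_mm = gap_mm, layout = layout,
         volume_shape = volume_shape, rng_seed = as.integer(rng_seed)),
    class = "scan_spec"
  )
}

# Largest linear half-extent (mm) a jittered seed can reach; jitter is
# clipped at 3 SD so the layout bound is hard.
seed_half_extent <- function(spec) {
  max(spec$phantom$coat_semiaxes) * exp(3 * spec$jitter_sd)
}

# Default grid layout: seeds in one z plane, rows along y, columns along x,
# ordered so seed index increases with (y, x) — the same order in which
# individualize_seeds() reports instances.
default_layout <- function(spec) {
  half <- seed_half_extent(spec)
  cell <- 2 * half + spec$gap_mm
  cols <- ceiling(sqrt(spec$n_seeds))
  rows <- ceiling(spec$n_seeds / cols)
  pos <- expand.grid(col = seq_len(cols), row = seq_len(rows))
  pos <- pos[seq_len(spec$n_seeds), , drop = FALSE]
  zc <- half + spec$gap_mm / 2
  cbind(x = (pos$col - 0.5) * cell + spec$gap_mm / 2,
        y = (pos$row - 0.5) * cell + spec$gap_mm / 2,
        z = zc)
}

#' Generate a synthetic multi-seed scan
#'
#' Builds the full intensity volume, the exact compartment label map, and
#' a ground-truth table of per-seed, per-compartment voxel counts obtained
#' by direct tallying on the label map. Identical specs (including
#' `rng_seed`) produce bit-identical output.
#'
#' @param spec A [scan_spec()].
#' @return List with `tomogram`, `labeling`, and `truth` (a tibble with
#'   one row per seed x compartment: voxel count, volume in mm^3, plus the
#'   seed's center, size factor and rotation). The per-seed jittered
#'   phantom parameters are attached as `attr(truth, "seeds")`.
#' @export
make_scan <- function(spec) {
  stopifnot(inherits(spec, "scan_spec"))
  sp <- spec$voxel_spacing
  layout <- spec$layout
  if (is.null(layout)) layout <- default_layout(spec)
  layout <- as.matrix(layout)
  if (nrow(layout) != spec$n_seeds) stop("layout must have one row per seed")
  half <- seed_half_extent(spec)
  if (is.null(spec$volume_shape)) {
    ext <- apply(layout, 2, max) + half + spec$gap_mm / 2
    shape <- as.integer(ceiling(ext / sp))
  } else {
    shape <- as.integer(spec$volume_shape)
  }
  # Hard bounds check: every (maximal) seed bounding box must fit.
  lo <- sweep(layout, 2, half + sp)
  hi <- sweep(layout, 2, -half - sp)
  if (any(lo < 0) || any(t(t(hi) > shape * sp))) {
    stop("seed layout exceeds the volume bounds")
  }
  # Pairwise non-touching check (conservative bounding-sphere distance).
  if (spec$n_seeds > 1) {
    d <- as.matrix(dist(layout))
    diag(d) <- Inf
    if (min(d) < 2 * half + spec$gap_mm - 1e-9) {
      stop("seed layout violates the minimum gap between seeds")
    }
  }
  withr::with_seed(spec$rng_seed, {
    scales <- exp(pmin(pmax(rnorm(spec$n_seeds, 0, spec$jitter_sd),
                            -3 * spec$jitter_sd), 3 * spec$jitter_sd))
    angles <- if (spec$rotate) runif(spec$n_seeds, 0, 2 * pi)
              else rep(0, spec$n_seeds)
    lab <- array(0L, dim = shape)
    for (k in seq_len(spec$n_seeds)) {
      box_half <- scales[k] * max(spec$phantom$coat_semiaxes) + 2 * sp
      i0 <- pmax(1L, floor((layout[k, ] - box_half) / sp) + 1L)
      i1 <- pmin(shape, ceiling((layout[k, ] + box_half) / sp))
      nx <- i1[1] - i0[1] + 1L; ny <- i1[2] - i0[2] + 1L; nz <- i1[3] - i0[3] + 1L
      x <- (voxel_centers(shape[1], sp))[i0[1]:i1[1]] - layout[k, 1]
      y <- (voxel_centers(shape[2], sp))[i0[2]:i1[2]] - layout[k, 2]
      z <- (voxel_centers(shape[3], sp))[i0[3]:i1[3]] - layout[k, 3]
      X <- array(x, dim = c(nx, ny, nz))
      Y <- array(rep(y, each = nx), dim = c(nx, ny, nz))
      Z <- array(rep(z, each = nx * ny), dim = c(nx, ny, nz))
      sub <- phantom_labels_at(spec$phantom, X, Y, Z,
                               scale = scales[k], angle = angles[k])
      old <- lab[i0[1]:i1[1], i0[2]:i1[2], i0[3]:i1[3]]
      old[sub > 0L] <- sub[sub > 0L]
      lab[i0[1]:i1[1], i0[2]:i1[2], i0[3]:i1[3]] <- old
    }
    vol <- render_intensity(lab, spec$phantom, rng_seed = NULL)
  })
  truth <- scan_truth_table(lab, layout, scales, angles, spec)
  list(tomogram = tomogram(vol, sp, scan_id = sprintf("synthetic-%d", spec$rng_seed)),
       labeling = component_labeling(lab, sp),
       truth = truth)
}

# Direct voxel tallying of per-seed compartment volumes on the label map.
scan_truth_table <- function(lab, layout, scales, angles, spec) {
  sp <- spec$voxel_spacing
  shape <- dim(lab)
  compartments <- c("embryo", "perisperm", "coat", "cavity")
  rows <- vector("list", nrow(layout))
  for (k in seq_len(nrow(layout))) {
    box_half <- scales[k] * max(spec$phantom$coat_semiaxes) + 2 * sp
    i0 <- pmax(1L, floor((layout[k, ] - box_half) / sp) + 1L)
    i1 <- pmin(shape, ceiling((layout[k, ] + box_half) / sp))
    sub <- lab[i0[1]:i1[1], i0[2]:i1[2], i0[3]:i1[3]]
    counts <- vapply(1:4, function(cl) sum(sub == cl), numeric(1))
    rows[[k]] <- tibble::tibble(
      seed = k, compartment = compartments,
      voxels = counts, volume_mm3 = counts * sp^3,
      x = layout[k, 1], y = layout[k, 2], z = layout[k, 3],
      size_factor = scales[k], rotation = angles[k]
    )
  }
  truth <- do.call(rbind, rows)
  attr(truth, "seeds") <- data.frame(seed = seq_len(nrow(layout)),
                                     size_factor = scales, rotation = angles)
  truth
}

# Thomsen's approximation for the surface area of an ellipsoid
# (relative error < 1.1%).
ellipsoid_area <- function(a, b, c, p = 1.6075) {
  4 * pi * (((a * b)^p + (a * c)^p + (b * c)^p) / 3)^(1 / p)
}

#' Closed-form feature truth for a phantom spec
#'
#' Analytic per-compartment volume and surface area for a (possibly
#' rescaled) [phantom_spec()]: ellipsoid formulas for perisperm and
#' envelope, partial-torus formulas for the embryo ring, sphere for the
#' cavity. The coat volume is the envelope minus the enclosed
#' compartments; its surface is reported as the exterior envelope surface.
#'
#' @param spec A `phantom_spec`.
#' @param scale Linear size factor applied to the whole seed.
#' @return Tibble with compartment, volume_mm3, surface_mm2.
#' @export
phantom_truth_features <- function(spec, scale = 1) {
  a <- spec$coat_semiaxes * scale
  p <- spec$perisperm_semiaxes * scale
  v_env <- 4 / 3 * pi * prod(a)
  a_env <- ellipsoid_area(a[1], a[2], a[3])
  v_per <- 4 / 3 * pi * prod(p)
  a_per <- ellipsoid_area(p[1], p[2], p[3])
  if (!is.null(spec$embryo_arc)) {
    e <- spec$embryo_arc
    R <- e$ring_radius * scale; r <- e$tube_radius * scale; f <- e$arc_fraction
    v_emb <- f * 2 * pi^2 * R * r^2
    a_emb <- f * 4 * pi^2 * R * r + if (f < 1) 2 * pi * r^2 else 0
  } else {
    v_emb <- 0; a_emb <- 0
  }
  rc <- spec$cavity_radius * scale
  v_cav <- 4 / 3 * pi * rc^3
  a_cav <- 4 * pi * rc^2
  if (spec$coat_thickness > 0) {
    v_coat <- v_env - v_per - v_emb - v_cav
    a_coat <- a_env
  } else {
    v_coat <- 0; a_coat <- 0
    v_per <- v_env - v_emb - v_cav
  }
  tibble::tibble(
    compartment = c("embryo", "perisperm", "coat", "cavity", "whole_seed"),
    volume_mm3 = c(v_emb, v_per, v_coat, v_cav, v_env),
    surface_mm2 = c(a_emb, a_per, a_coat, a_cav, a_env)
  )
}
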
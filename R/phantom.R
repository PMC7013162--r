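#' Component labeling container
#'
#' Per-voxel compartment labels for one seed or one whole scan, using the
#' codes of [seed_classes()]: 0 background, 1 embryo, 2 perisperm, 3 coat,
#' 4 internal cavity.
#'
#' @param labels Integer 3D array of label codes.
#' @param spacing Voxel spacing in mm (length 1 or 3).
#' @return Object of class `component_labeling`.
#' @export
component_labeling <- function(labels, spacing) {
  stopifnot(is.array(labels), length(dim(labels)) == 3L)
  if (!all(unique(as.integer(labels)) %in% 0:4)) {
    stop("labels must be in 0..4")
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  stopifnot(length(spacing) == 3L, all(spacing > 0))
  structure(list(labels = labels, spacing = spacing),
            class = "component_labeling")
}

#' @export
print.component_labeling <- function(x, ...) {
  d <- dim(x$labels)
  tab <- table(factor(x$labels, levels = 0:4,
                      labels = names(.SEED_CLASSES)))
  cat(sprintf("<component_labeling> %d x %d x %d voxels\n", d[1], d[2], d[3]))
  print(tab)
  invisible(x)
}

#' Geometric specification of one synthetic seed phantom
#'
#' Defines an idealized sugar beet seed: an ellipsoidal pericarp (coat)
#' enclosing a central perisperm ellipsoid, a partial-torus embryo ring
#' hugging the perisperm in the equatorial plane, and an optional spherical
#' internal cavity (empty space) above the perisperm. All voxels of the
#' seed interior not claimed by perisperm, embryo or cavity belong to the
#' coat. Default dimensions give a ~3.6 x 3.4 x 2.8 mm seed, typical of
#' the multigerm beet seed balls imaged by microtomography.
#'
#' @param coat_semiaxes Outer ellipsoid semi-axes in mm (x, y, z).
#' @param coat_thickness Minimum coat wall thickness in mm; 0 means the
#'   whole ellipsoid is perisperm (no coat compartment), used by spherical
#'   calibration phantoms.
#' @param perisperm_semiaxes Perisperm ellipsoid semi-axes in mm.
#' @param embryo_arc List with `ring_radius`, `tube_radius` (mm) and
#'   `arc_fraction` (0-1) describing the embryo ring; `NULL` for no embryo.
#' @param cavity_radius Radius in mm of the internal empty space; 0 = absent.
#' @param class_intensities Named mean gray levels for background, embryo,
#'   perisperm, coat, cavity.
#' @param noise_sd Additive Gaussian noise SD in gray levels.
#' @param voxel_spacing Isotropic voxel spacing in mm.
#' @param max_gray Upper clip bound of the intensity range.
#' @return A validated object of class `phantom_spec`.
#' @export
phantom_spec <- function(coat_semiaxes = c(1.8, 1.7, 1.4),
                         coat_thickness = 0.2,
                         perisperm_semiaxes = c(0.8, 0.7, 0.55),
                         embryo_arc = list(ring_radius = 1.1,
                                           tube_radius = 0.2,
                                           arc_fraction = 0.85),
                         cavity_radius = 0.2,
                         class_intensities = c(background = 20, embryo = 120,
                                               perisperm = 160, coat = 210,
                                               cavity = 50),
                         noise_sd = 5,
                         voxel_spacing = 0.05,
                         max_gray = 255) {
  spec <- structure(
    list(coat_semiaxes = as.numeric(coat_semiaxes),
         coat_thickness = as.numeric(coat_thickness),
         perisperm_semiaxes = as.numeric(perisperm_semiaxes),
         embryo_arc = embryo_arc,
         cavity_radius = as.numeric(cavity_radius),
         class_intensities = class_intensities,
         noise_sd = as.numeric(noise_sd),
         voxel_spacing = as.numeric(voxel_spacing),
         max_gray = as.numeric(max_gray)),
    class = "phantom_spec"
  )
  validate_phantom_spec(spec)
  spec
}

#' Spherical calibration phantom
#'
#' A single-compartment digital sphere (all perisperm), used to check
#' morphometric estimators against closed forms.
#'
#' @param radius Sphere radius in mm.
#' @param voxel_spacing Voxel spacing in mm.
#' @param intensity Foreground mean gray level.
#' @param noise_sd Gaussian noise SD in gray levels.
#' @return A `phantom_spec`.
#' @export
phantom_spec_sphere <- function(radius, voxel_spacing = 0.02,
                                intensity = 160, noise_sd = 0) {
  phantom_spec(
    coat_semiaxes = rep(radius, 3), coat_thickness = 0,
    perisperm_semiaxes = rep(radius, 3),
    embryo_arc = NULL, cavity_radius = 0,
    class_intensities = c(background = 20, embryo = 120,
                          perisperm = intensity, coat = 210, cavity = 50),
    noise_sd = noise_sd, voxel_spacing = voxel_spacing
  )
}

# Internal position of the cavity center along +z, chosen to clear the
# perisperm and the embryo ring by a fixed 0.1 mm margin.
cavity_center_z <- function(spec) {
  spec$perisperm_semiaxes[3] + spec$cavity_radius + 0.1
}

validate_phantom_spec <- function(spec) {
  s <- spec
  if (any(s$coat_semiaxes <= 0) || any(s$perisperm_semiaxes <= 0)) {
    stop("semi-axes must be positive")
  }
  if (s$coat_thickness < 0) stop("coat_thickness must be >= 0")
  if (s$voxel_spacing <= 0) stop("voxel_spacing must be positive")
  if (s$noise_sd < 0) stop("noise_sd must be >= 0")
  interior <- s$coat_semiaxes - s$coat_thickness
  if (any(interior <= 0)) stop("coat_thickness exceeds the coat semi-axes")
  if (s$coat_thickness > 0 && any(s$perisperm_semiaxes >= interior)) {
    stop("perisperm must fit strictly inside the coat interior")
  }
  if (s$coat_thickness == 0 && any(s$perisperm_semiaxes > s$coat_semiaxes)) {
    stop("perisperm larger than the seed envelope")
  }
  if (!is.null(s$embryo_arc)) {
    e <- s$embryo_arc
    if (e$ring_radius <= 0 || e$tube_radius <= 0 ||
        e$arc_fraction <= 0 || e$arc_fraction > 1) {
      stop("invalid embryo_arc")
    }
    outer_r <- e$ring_radius + e$tube_radius
    fit <- (outer_r / min(interior[1:2]))^2 + (e$tube_radius / interior[3])^2
    if (fit >= 1) stop("embryo ring does not fit inside the coat interior")
    if (e$ring_radius - e$tube_radius <= max(s$perisperm_semiaxes[1:2])) {
      stop("embryo ring overlaps the perisperm")
    }
  }
  if (s$cavity_radius < 0) stop("cavity_radius must be >= 0")
  if (s$cavity_radius > 0) {
    zc <- cavity_center_z(s)
    if (zc + s$cavity_radius >= interior[3]) {
      stop("cavity does not fit inside the coat interior")
    }
    if (!is.null(s$embryo_arc) &&
        zc - s$cavity_radius <= s$embryo_arc$tube_radius) {
      stop("cavity overlaps the embryo ring")
    }
  }
  present <- c("background",
               if (!is.null(s$embryo_arc)) "embryo",
               "perisperm",
               if (s$coat_thickness > 0) "coat",
               if (s$cavity_radius > 0) "cavity")
  ci <- s$class_intensities[present]
  if (anyNA(ci)) stop("class_intensities must name all present classes")
  if (length(ci) > 1 && s$noise_sd > 0) {
    gaps <- abs(outer(ci, ci, "-"))
    min_gap <- min(gaps[upper.tri(gaps)])
    if (min_gap < 3 * s$noise_sd) {
      stop("class intensity means must be separated by >= 3 x noise_sd")
    }
  }
  invisible(spec)
}

# Evaluate phantom geometry on voxel-center coordinates relative to the
# seed center (mm), after optional scaling and z-rotation. Returns an
# integer label array.
phantom_labels_at <- function(spec, X, Y, Z, scale = 1, angle = 0) {
  if (scale != 1) {
    X <- X / scale; Y <- Y / scale; Z <- Z / scale
  }
  if (angle != 0) {
    ca <- cos(-angle); sa <- sin(-angle)
    Xr <- ca * X - sa * Y
    Y  <- sa * X + ca * Y
    X  <- Xr
  }
  lab <- array(0L, dim = dim(X))
  a <- spec$coat_semiaxes
  inside <- (X / a[1])^2 + (Y / a[2])^2 + (Z / a[3])^2 <= 1
  lab[inside] <- if (spec$coat_thickness > 0) .SEED_CLASSES[["coat"]]
                 else .SEED_CLASSES[["perisperm"]]
  p <- spec$perisperm_semiaxes
  per <- (X / p[1])^2 + (Y / p[2])^2 + (Z / p[3])^2 <= 1
  lab[per] <- .SEED_CLASSES[["perisperm"]]
  if (!is.null(spec$embryo_arc)) {
    e <- spec$embryo_arc
    rad <- sqrt(X^2 + Y^2)
    emb <- (rad - e$ring_radius)^2 + Z^2 <= e$tube_radius^2
    if (e$arc_fraction < 1) {
      theta <- atan2(Y, X)
      emb <- emb & abs(theta) <= pi * e$arc_fraction
    }
    lab[emb] <- .SEED_CLASSES[["embryo"]]
  }
  if (spec$cavity_radius > 0) {
    zc <- cavity_center_z(spec)
    cav <- X^2 + Y^2 + (Z - zc)^2 <= spec$cavity_radius^2
    lab[cav] <- .SEED_CLASSES[["cavity"]]
  }
  lab
}

# Voxel-center world coordinates along one axis (0-based voxels, centers at
# (i + 0.5) * spacing).
voxel_centers <- function(n, spacing) (seq_len(n) - 0.5) * spacing

#' Generate one synthetic seed phantom
#'
#' Voxelizes a [phantom_spec()] into an intensity tomogram (class mean plus
#' clipped Gaussian noise) and the exact voxel label map.
#'
#' @param spec A `phantom_spec`.
#' @param origin Seed center in mm within the volume; default centers the
#'   seed in a volume sized to fit it with a 4-voxel pad.
#' @param shape Volume shape in voxels; default sized to hold the seed
#'   geometry of `spec` with a margin.
#' @param rng_seed Integer seed for the noise; `NULL` uses the current RNG
#'   state.
#' @return List with `tomogram` (a [tomogram()]) and `labeling`
#'   (a [component_labeling()]).
#' @export
make_seed_phantom <- function(spec, origin = NULL, shape = NULL,
                              rng_seed = NULL) {
  validate_phantom_spec(spec)
  sp <- spec$voxel_spacing
  if (is.null(shape)) {
    ext <- spec$coat_semiaxes
    shape <- ceiling(2 * ext / sp) + 8L
  }
  shape <- as.integer(shape)
  if (is.null(origin)) origin <- shape * sp / 2
  x <- voxel_centers(shape[1], sp) - origin[1]
  y <- voxel_centers(shape[2], sp) - origin[2]
  z <- voxel_centers(shape[3], sp) - origin[3]
  X <- array(x, dim = shape)
  Y <- array(rep(y, each = shape[1]), dim = shape)
  Z <- array(rep(z, each = shape[1] * shape[2]), dim = shape)
  lab <- phantom_labels_at(spec, X, Y, Z)
  vol <- render_intensity(lab, spec, rng_seed)
  list(tomogram = tomogram(vol, sp),
       labeling = component_labeling(lab, sp))
}

# Map labels to mean intensities and add clipped Gaussian noise.
render_intensity <- function(lab, spec, rng_seed = NULL) {
  ci <- spec$class_intensities
  lut <- c(ci[["background"]], ci[["embryo"]], ci[["perisperm"]],
           ci[["coat"]], ci[["cavity"]])
  vol <- array(lut[as.integer(lab) + 1L], dim = dim(lab))
  if (spec$noise_sd > 0) {
    add_noise <- function() {
      vol <- vol + rnorm(length(vol), sd = spec$noise_sd)
      array(pmin(pmax(vol, 0), spec$max_gray), dim = dim(lab))
    }
    vol <- if (is.null(rng_seed)) add_noise()
           else withr::with_seed(rng_seed, add_noise())
  }
  vol
}
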
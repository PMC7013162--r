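#' Tomogram container
#'
#' Wraps a 3D grayscale intensity array together with its voxel spacing in
#' mm and identifying metadata. A 2D image may be supplied; it is promoted
#' to a single-slice volume.
#'
#' @param intensities Numeric 3D array (or 2D matrix) of gray values.
#' @param spacing Voxel spacing in mm, length 1 (isotropic) or 3.
#' @param scan_id,genotype_id Optional identifiers carried through outputs.
#' @return Object of class `tomogram` with elements `intensities`,
#'   `spacing`, `scan_id`, `genotype_id`.
#' @export
tomogram <- function(intensities, spacing, scan_id = NA_character_,
                     genotype_id = NA_character_) {
  if (is.matrix(intensities)) {
    intensities <- array(intensities, dim = c(dim(intensities), 1L))
  }
  stopifnot(is.array(intensities), length(dim(intensities)) == 3L,
            length(intensities) > 0L)
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("`spacing` must be positive, length 1 or 3, in mm")
  }
  structure(
    list(intensities = intensities, spacing = spacing,
         scan_id = scan_id, genotype_id = genotype_id),
    class = "tomogram"
  )
}

#' @export
print.tomogram <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("<tomogram> %d x %d x %d voxels, spacing %s mm\n",
              d[1], d[2], d[3], paste(signif(x$spacing, 4), collapse = " x ")))
  if (!is.na(x$scan_id)) cat("  scan_id:", x$scan_id, "\n")
  if (!is.na(x$genotype_id)) cat("  genotype:", x$genotype_id, "\n")
  invisible(x)
}

as_volume <- function(x) {
  if (inherits(x, "tomogram")) x$intensities
  else if (is.matrix(x)) array(x, dim = c(dim(x), 1L))
  else if (is.array(x) && length(dim(x)) == 3L) x
  else stop("expected a tomogram or a 3D array")
}

#' Label connected components of a binary volume
#'
#' @param mask Logical 3D array (or 2D matrix).
#' @param connectivity 6 or 26 (in 2D: 4 or 8 via the singleton z axis).
#' @return Integer array of component labels (0 = background) with
#'   attribute `n_components`.
#' @export
label_components <- function(mask, connectivity = 26L) {
  two_d <- is.matrix(mask)
  if (two_d) mask <- array(mask, dim = c(dim(mask), 1L))
  stopifnot(is.array(mask), length(dim(mask)) == 3L,
            connectivity %in% c(6L, 26L))
  lab <- cpp_label_components(as.logical(mask), dim(mask), as.integer(connectivity))
  n <- attr(lab, "n_components")
  out <- array(lab, dim = dim(mask))
  if (two_d) out <- out[, , 1L]
  attr(out, "n_components") <- n
  out
}

#' Binary erosion / dilation with a 1-voxel digital ball
#'
#' Repeated one-step morphology with the 6-neighborhood structuring element
#' (4-neighborhood for 2D input).
#'
#' @param mask Logical array or matrix.
#' @param steps Number of elementary steps.
#' @return Logical array of the same shape.
#' @export
erode_mask <- function(mask, steps = 1L) .morph(mask, steps, dilate = FALSE)

#' @rdname erode_mask
#' @export
dilate_mask <- function(mask, steps = 1L) .morph(mask, steps, dilate = TRUE)

.morph <- function(mask, steps, dilate) {
  two_d <- is.matrix(mask)
  if (two_d) mask <- array(mask, dim = c(dim(mask), 1L))
  d <- dim(mask)
  m <- as.logical(mask)
  for (i in seq_len(steps)) m <- cpp_morph_step(m, d, dilate)
  out <- array(m, dim = d)
  if (two_d) out <- out[, , 1L]
  out
}

#' Fill internal holes of a binary volume
#'
#' Background components (6-connectivity) that do not touch the volume
#' border are interpreted as enclosed holes and added to the foreground.
#'
#' @param mask Logical 3D array or 2D matrix.
#' @return List with `filled` (logical array) and `holes` (logical array of
#'   the hole voxels only).
#' @export
fill_holes <- function(mask) {
  two_d <- is.matrix(mask)
  if (two_d) mask <- array(mask, dim = c(dim(mask), 1L))
  d <- dim(mask)
  comp <- label_components(!mask, connectivity = 6L)
  border_labels <- unique(c(
    comp[1, , ], comp[d[1], , ],
    comp[, 1, ], comp[, d[2], ],
    comp[, , 1], comp[, , d[3]]
  ))
  holes <- comp > 0L & !(comp %in% border_labels)
  filled <- mask | holes
  if (two_d) {
    filled <- filled[, , 1L]
    holes <- holes[, , 1L]
  }
  list(filled = filled, holes = holes)
}

#' Dice similarity between two binary masks
#'
#' @param a,b Logical arrays of identical shape.
#' @return Dice coefficient 2|A∩B| / (|A|+|B|); 1 when both masks are empty.
#' @export
dice_coefficient <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0) return(1)
  2 * sum(a & b) / (na + nb)
}
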
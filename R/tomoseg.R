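#' Denoise a tomogram
#'
#' Edge-bounded smoothing prior to thresholding and watershed: a cube
#' median filter (default) or a renormalized separable Gaussian. Both keep
#' the output range within the input range.
#'
#' @param volume A [tomogram()].
#' @param method `"median"` or `"gaussian"`.
#' @param strength Filter radius in voxels (median) or sigma in voxels
#'   (Gaussian). 0 returns the input unchanged.
#' @return A denoised `tomogram` with identical shape and spacing.
#' @export
denoise <- function(volume, method = c("median", "gaussian"), strength = 1) {
  method <- match.arg(method)
  stopifnot(inherits(volume, "tomogram"), strength >= 0)
  if (strength == 0) return(volume)
  v <- volume$intensities
  out <- switch(method,
    median = cpp_median3d(as.numeric(v), dim(v), as.integer(strength)),
    gaussian = cpp_gaussian3d(as.numeric(v), dim(v), strength)
  )
  volume$intensities <- array(out, dim = dim(v))
  volume
}

#' Otsu threshold of an intensity sample
#'
#' Bimodal histogram split maximizing the between-class variance.
#'
#' @param values Numeric vector (or array) of intensities.
#' @param nbins Number of histogram bins.
#' @return The threshold, on the intensity scale.
#' @export
otsu_threshold <- function(values, nbins = 256L) {
  values <- as.numeric(values)
  rng <- range(values)
  if (diff(rng) == 0) stop("no bimodal structure: constant intensities")
  h <- hist(values, breaks = seq(rng[1], rng[2], length.out = nbins + 1L),
            plot = FALSE)
  w <- h$counts / sum(h$counts)
  mids <- h$mids
  omega <- cumsum(w)
  mu <- cumsum(w * mids)
  mu_t <- mu[length(mu)]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  if (max(sigma_b) <= 0) stop("no bimodal structure in the histogram")
  k <- which.max(sigma_b)
  h$breaks[k + 1L]
}

#' Multi-level Otsu thresholds
#'
#' Exhaustive k-class generalization of Otsu's criterion over a binned
#' histogram; used to derive intensity bands for watershed markers.
#'
#' @param values Numeric intensities.
#' @param k Number of classes (2 or 3).
#' @param nbins Histogram bins.
#' @return Increasing vector of k-1 thresholds.
#' @export
multiotsu_thresholds <- function(values, k = 3L, nbins = 128L) {
  stopifnot(k %in% c(2L, 3L))
  values <- as.numeric(values)
  rng <- range(values)
  if (diff(rng) == 0) stop("no multimodal structure: constant intensities")
  if (k == 2L) return(otsu_threshold(values, nbins))
  h <- hist(values, breaks = seq(rng[1], rng[2], length.out = nbins + 1L),
            plot = FALSE)
  w <- h$counts / sum(h$counts)
  mids <- h$mids
  cw <- c(0, cumsum(w))
  cm <- c(0, cumsum(w * mids))
  class_term <- function(i, j) { # bins (i+1)..j form one class
    ww <- cw[j + 1L] - cw[i + 1L]
    if (ww <= 0) return(0)
    (cm[j + 1L] - cm[i + 1L])^2 / ww
  }
  n <- length(w)
  best <- -Inf; best_ij <- c(1L, 2L)
  for (i in 1:(n - 2L)) {
    t1 <- class_term(0L, i)
    for (j in (i + 1L):(n - 1L)) {
      s <- t1 + class_term(i, j) + class_term(j, n)
      if (s > best) { best <- s; best_ij <- c(i, j) }
    }
  }
  c(h$breaks[best_ij[1] + 1L], h$breaks[best_ij[2] + 1L])
}

#' Threshold a tomogram into a binary seed mask
#'
#' Builds the mask M with M = 1 where the intensity strictly exceeds the
#' threshold tau and 0 elsewhere. With `tau = "auto"` the threshold is
#' fixed by a bimodal (Otsu) histogram split and recorded in the result.
#'
#' @param volume A [tomogram()].
#' @param tau Gray-level threshold, or `"auto"`.
#' @return Object of class `binary_mask3d`: list with `mask` (logical
#'   array) and `threshold_used`.
#' @export
threshold_mask <- function(volume, tau = "auto") {
  stopifnot(inherits(volume, "tomogram"))
  v <- volume$intensities
  if (identical(tau, "auto")) {
    tau <- otsu_threshold(v)
  } else {
    tau <- as.numeric(tau)
    stopifnot(length(tau) == 1L, is.finite(tau))
  }
  structure(list(mask = v > tau, threshold_used = tau),
            class = "binary_mask3d")
}

#' @export
print.binary_mask3d <- function(x, ...) {
  cat(sprintf("<binary_mask3d> %s voxels, %d foreground, tau = %.4g\n",
              paste(dim(x$mask), collapse = " x "), sum(x$mask),
              x$threshold_used))
  invisible(x)
}

#' Individualize seeds from a scan mask
#'
#' Splits the binary seed mask into per-seed instances by 26-connectivity
#' connected components. Components smaller than `size_floor_frac` times
#' the median component volume are discarded as specks. Instances are
#' cropped with a 1-voxel pad and ordered by centroid (z, y, x). A count
#' differing from `expected_n` raises a warning, not an error.
#'
#' @param volume A [tomogram()].
#' @param mask A [threshold_mask()] result (or logical array).
#' @param expected_n Expected number of seeds per scan (default 25).
#' @param size_floor_frac Fraction of the median component volume below
#'   which a component is discarded.
#' @return List of `seed_instance` objects: `intensities`, `mask`
#'   (logical), `offset` (0-based voxel offset in the parent scan),
#'   `seed_index`, `spacing`.
#' @export
individualize_seeds <- function(volume, mask, expected_n = 25L,
                                size_floor_frac = 0.1) {
  stopifnot(inherits(volume, "tomogram"))
  m <- if (inherits(mask, "binary_mask3d")) mask$mask else mask
  stopifnot(identical(dim(m), dim(volume$intensities)))
  if (!any(m)) stop("no seeds found: empty mask")
  lab <- label_components(m, connectivity = 26L)
  n <- attr(lab, "n_components")
  sizes <- tabulate(lab[lab > 0L], nbins = n)
  keep <- which(sizes >= size_floor_frac * median(sizes))
  if (length(keep) != expected_n) {
    warning(sprintf("expected %d seeds but found %d components",
                    expected_n, length(keep)))
  }
  d <- dim(m)
  # Centroids and bounding boxes in one pass over foreground voxels.
  idx <- which(lab > 0L & array(lab %in% keep, dim = d))
  lv <- lab[idx]
  coord <- arrayInd(idx, d)
  inst <- lapply(keep, function(l) {
    sel <- lv == l
    xyz <- coord[sel, , drop = FALSE]
    cen <- colMeans(xyz)
    lo <- pmax(1L, apply(xyz, 2, min) - 1L)
    hi <- pmin(d, apply(xyz, 2, max) + 1L)
    sub_m <- lab[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] == l
    sub_i <- volume$intensities[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]
    list(intensities = sub_i, mask = sub_m, offset = lo - 1L,
         centroid = cen, spacing = volume$spacing)
  })
  ord <- order(vapply(inst, function(s) s$centroid[3], numeric(1)),
               vapply(inst, function(s) s$centroid[2], numeric(1)),
               vapply(inst, function(s) s$centroid[1], numeric(1)))
  inst <- inst[ord]
  for (i in seq_along(inst)) {
    inst[[i]]$seed_index <- i
    class(inst[[i]]) <- "seed_instance"
  }
  inst
}

#' @export
print.seed_instance <- function(x, ...) {
  cat(sprintf("<seed_instance> #%d, %s voxels, %d foreground\n",
              x$seed_index, paste(dim(x$mask), collapse = " x "),
              sum(x$mask)))
  invisible(x)
}
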
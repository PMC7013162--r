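#' QC thresholds for seed filtering
#'
#' @param shape_band Acceptable band for the VA3d shape factor of any
#'   non-empty compartment (a sphere scores 1; heavily distorted or
#'   fragmented compartments score much higher).
#' @param fence_k Robust fence width: a compartment volume further than
#'   `fence_k` scaled MADs from the scan median is flagged.
#' @param fence_compartments Compartments subjected to the volume fences.
#' @return List of class `qc_config`.
#' @export
qc_config <- function(shape_band = c(0.9, 8),
                      fence_k = 3,
                      fence_compartments = c("embryo", "perisperm", "coat")) {
  structure(list(shape_band = shape_band, fence_k = fence_k,
                 fence_compartments = fence_compartments),
            class = "qc_config")
}

#' Filter morphologically distorted seeds
#'
#' Flags dead, malformed or empty seeds so their measurements do not enter
#' the genotype summary. A seed is rejected as `"empty"` when its embryo
#' volume is zero, and as `"malformed"` when any compartment's shape or
#' filling factor leaves the configured band or any compartment volume
#' falls outside robust fences (median +/- `fence_k` x scaled MAD across
#' the seeds of the scan).
#'
#' @param features Per-seed feature tibble from [compute_features()]
#'   stacked over the seeds of one scan.
#' @param thresholds A [qc_config()].
#' @return Tibble with `seed_index`, `status` (`accepted`/`rejected`),
#'   `reason` (`empty`, `malformed`, `none`) and `detail`.
#' @export
qc_filter <- function(features, thresholds = qc_config()) {
  stopifnot(all(c("seed_index", "compartment", "volume_mm3") %in%
                  names(features)))
  seeds <- sort(unique(features$seed_index))
  # Robust per-compartment volume fences over the scan.
  fences <- lapply(thresholds$fence_compartments, function(cp) {
    v <- features$volume_mm3[features$compartment == cp]
    c(center = median(v), half = thresholds$fence_k * mad(v))
  })
  names(fences) <- thresholds$fence_compartments
  out <- lapply(seeds, function(s) {
    df <- features[features$seed_index == s, , drop = FALSE]
    emb <- df$volume_mm3[df$compartment == "embryo"]
    if (length(emb) == 1L && emb <= 0) {
      return(tibble::tibble(seed_index = s, status = "rejected",
                            reason = "empty", detail = "embryo volume 0"))
    }
    bad <- character(0)
    sh <- df$shape_va3d[!is.na(df$shape_va3d)]
    if (any(sh < thresholds$shape_band[1] | sh > thresholds$shape_band[2])) {
      bad <- c(bad, "shape factor outside band")
    }
    ff <- df$filling_factor[!is.na(df$filling_factor)]
    if (any(ff < 0 | ff > 1)) bad <- c(bad, "filling factor outside [0,1]")
    for (cp in names(fences)) {
      v <- df$volume_mm3[df$compartment == cp]
      f <- fences[[cp]]
      if (length(v) == 1L && abs(v - f["center"]) > f["half"]) {
        bad <- c(bad, sprintf("%s volume outside robust fences", cp))
      }
    }
    if (length(bad) > 0) {
      tibble::tibble(seed_index = s, status = "rejected",
                     reason = "malformed", detail = paste(bad, collapse = "; "))
    } else {
      tibble::tibble(seed_index = s, status = "accepted",
                     reason = "none", detail = "")
    }
  })
  do.call(rbind, out)
}
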
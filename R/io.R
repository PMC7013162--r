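#' Write a volume as a multi-page TIFF with a metadata sidecar
#'
#' Pages are z slices, 16-bit grayscale, intensities scaled by
#' `max_gray`. A YAML sidecar (`<file>.yml`) stores the voxel spacing
#' and gray scale so [read_volume_tiff()] restores the tomogram exactly
#' up to the 16-bit quantization.
#'
#' @param tomogram A [tomogram()].
#' @param path Output `.tif` path.
#' @param max_gray Gray value mapped to the 16-bit maximum (default the
#'   volume's own maximum).
#' @return `path`, invisibly.
#' @export
write_volume_tiff <- function(tomogram, path, max_gray = NULL) {
  vol <- tomogram$intensities
  stopifnot(length(dim(vol)) == 3L)
  mg <- if (!is.null(max_gray)) max_gray else max(vol)
  pages <- lapply(seq_len(dim(vol)[3]), function(z)
    pmin(pmax(vol[, , z] / mg, 0), 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  yaml::write_yaml(
    list(voxel_spacing_mm = as.numeric(tomogram$spacing),
         max_gray = as.numeric(mg)),
    paste0(path, ".yml")
  )
  invisible(path)
}

#' Read a volume TIFF written by [write_volume_tiff()]
#'
#' @param path `.tif` path; the `.yml` sidecar next to it supplies voxel
#'   spacing and gray scale (defaults 0.1 mm and 255 if absent).
#' @return A [tomogram()].
#' @export
read_volume_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  meta <- if (file.exists(paste0(path, ".yml"))) {
    yaml::read_yaml(paste0(path, ".yml"))
  } else {
    list(voxel_spacing_mm = c(0.1, 0.1, 0.1), max_gray = 255)
  }
  d <- c(dim(pages[[1]])[1:2], length(pages))
  vol <- array(0, dim = d)
  for (z in seq_len(d[3])) {
    vol[, , z] <- pages[[z]][, , drop = TRUE] * meta$max_gray
  }
  tomogram(vol, spacing = meta$voxel_spacing_mm)
}

#' Write/read germination event tables
#'
#' Plain CSV with columns `seed_id`, `time_h`, `censored` (and any
#' extras the records carry).
#'
#' @param records Event records tibble.
#' @param path CSV path.
#' @return `path` invisibly (write); records tibble (read).
#' @export
write_event_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_event_csv
#' @export
read_event_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("seed_id", "time_h") %in% names(df))) {
    stop("event CSV must have seed_id and time_h columns")
  }
  tibble::as_tibble(df)
}

#' Write a phenotype table as CSV
#'
#' UTF-8, comma-separated, header exactly the `Name[CO_333:code]`
#' schema columns (byte-identical across runs).
#'
#' @param table An [assemble_table()] result.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_phenotype_csv <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a phenotype table CSV
#'
#' @param path CSV written by [write_phenotype_csv()].
#' @return Tibble with the schema columns restored.
#' @export
read_phenotype_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8")
  tibble::as_tibble(df)
}
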
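#' Phenotype table schema
#'
#' The 28 ontology-coded variables of the assay: 13 from the tomograph
#' (ingested seed mass plus volume, surface area, 3D shape and spherical
#' diameter of perisperm, embryo and seed coat), 13 germination kinetics
#' variables across 5, 10 and 20 degC, and 2 elongation variables.
#' Column names are ASCII (`Name[CO_333:code]`); temperature and cutoff
#' are folded into the name (e.g. `GermFnlRt_28d_5C`).
#'
#' @return Tibble with `column` (the CSV header), `name`, `code`
#'   (`CO_333:` + 7 digits), `group` (`tomograph`, `germination`,
#'   `elongation`) and `unit`.
#' @export
phenotype_schema <- function() {
  def <- rbind(
    c("SeedMass",           "1000327", "tomograph",   "mg"),
    c("PerispVol",          "1000324", "tomograph",   "mm3"),
    c("PerispSurfArea",     "1000323", "tomograph",   "mm2"),
    c("PerispShapeVA3d",    "1000389", "tomograph",   "1"),
    c("PerispSpDiameter",   "1000390", "tomograph",   "mm"),
    c("EmbVol",             "1000320", "tomograph",   "mm3"),
    c("EmbSurfArea",        "1000319", "tomograph",   "mm2"),
    c("EmbShapeVA3d",       "1000391", "tomograph",   "1"),
    c("EmbSpDiameter",      "1000392", "tomograph",   "mm"),
    c("SeedCoatVol",        "1000325", "tomograph",   "mm3"),
    c("CoatSurfArea",       "1000317", "tomograph",   "mm2"),
    c("SeedCoatShapeVA3d",  "1000393", "tomograph",   "1"),
    c("SeedCoatSpDiameter", "1000394", "tomograph",   "mm"),
    c("MGT_5C",             "1000311", "germination", "h"),
    c("T50_5C",             "1000330", "germination", "h"),
    c("T70_5C",             "1000330", "germination", "h"),
    c("EGermRt_17d_5C",     "1000388", "germination", "%"),
    c("GermFnlRt_28d_5C",   "1000321", "germination", "%"),
    c("MGT_10C",            "1000311", "germination", "h"),
    c("T50_10C",            "1000330", "germination", "h"),
    c("T70_10C",            "1000330", "germination", "h"),
    c("GermFnlRt_15d_10C",  "1000321", "germination", "%"),
    c("MGT_20C",            "1000311", "germination", "h"),
    c("T50_20C",            "1000330", "germination", "h"),
    c("T70_20C",            "1000330", "germination", "h"),
    c("GermFnlRt_6d_20C",   "1000321", "germination", "%"),
    c("HGerm_10C",          "1000386", "elongation",  "h"),
    c("RadLg_10C",          "1000387", "elongation",  "mm")
  )
  tibble::tibble(
    column = sprintf("%s[CO_333:%s]", def[, 1], def[, 2]),
    name = def[, 1],
    code = paste0("CO_333:", def[, 2]),
    group = def[, 3],
    unit = def[, 4]
  )
}

# Tomograph variable <-> (compartment, feature) mapping of the schema.
.TOMO_MAP <- list(
  PerispVol          = c("perisperm", "volume_mm3"),
  PerispSurfArea     = c("perisperm", "surface_mm2"),
  PerispShapeVA3d    = c("perisperm", "shape_va3d"),
  PerispSpDiameter   = c("perisperm", "spherical_diameter_mm"),
  EmbVol             = c("embryo", "volume_mm3"),
  EmbSurfArea        = c("embryo", "surface_mm2"),
  EmbShapeVA3d       = c("embryo", "shape_va3d"),
  EmbSpDiameter      = c("embryo", "spherical_diameter_mm"),
  SeedCoatVol        = c("coat", "volume_mm3"),
  CoatSurfArea       = c("coat", "surface_mm2"),
  SeedCoatShapeVA3d  = c("coat", "shape_va3d"),
  SeedCoatSpDiameter = c("coat", "spherical_diameter_mm")
)

# Germination variable <-> (temperature, kinetics column) mapping.
.GERM_MAP <- list(
  MGT_5C = c(5, "mgt_h"), T50_5C = c(5, "t50_h"), T70_5C = c(5, "t70_h"),
  EGermRt_17d_5C = c(5, "early_rate_pct"),
  GermFnlRt_28d_5C = c(5, "final_rate_pct"),
  MGT_10C = c(10, "mgt_h"), T50_10C = c(10, "t50_h"),
  T70_10C = c(10, "t70_h"), GermFnlRt_15d_10C = c(10, "final_rate_pct"),
  MGT_20C = c(20, "mgt_h"), T50_20C = c(20, "t50_h"),
  T70_20C = c(20, "t70_h"), GermFnlRt_6d_20C = c(20, "final_rate_pct")
)

check_unique_ids <- function(ids, what) {
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L) {
    stop("duplicate genotype ids in ", what, ": ",
         paste(dup, collapse = ", "))
  }
}

#' Assemble the genotype phenotype table
#'
#' Joins the per-assay results into one row per genotype with exactly the
#' 28 variable columns of [phenotype_schema()]. Genotypes missing an
#' assay keep their row; the affected cells are `NA` and the reason is
#' recorded in the `missing` attribute (a sidecar table distinguishing
#' not-assayed cells from any reason string carried by the inputs).
#'
#' @param tomo Morphometry summaries ([summarize_features()] rows stacked
#'   over genotypes): `genotype_id`, `compartment`, `feature`, `mean`,
#'   `n_seeds`.
#' @param germ Kinetics summaries ([assay_summary()] rows stacked over
#'   genotypes and temperatures) with a `genotype_id` column.
#' @param elong Per-genotype elongation results: `genotype_id`,
#'   `hgerm_h`, `radlg_mm`.
#' @param seed_mass Balance data: `genotype_id`, `seed_mass_mg` (seed
#'   mass is weighed, not computed from images).
#' @param genotypes Row roster; default is the union of the ids seen in
#'   the inputs, in order of first appearance.
#' @return Tibble of class `phenotype_table`: `genotype_id`, the 28
#'   schema columns, and provenance columns `n_seeds_scanned`,
#'   `n_seeds_germ`. Attribute `missing` holds the sidecar reason table
#'   (`genotype_id`, `column`, `reason`).
#' @export
assemble_table <- function(tomo = NULL, germ = NULL, elong = NULL,
                           seed_mass = NULL, genotypes = NULL) {
  sch <- phenotype_schema()
  seen <- character(0)
  for (x in list(seed_mass, tomo, germ, elong)) {
    if (!is.null(x)) seen <- c(seen, as.character(x$genotype_id))
  }
  if (is.null(genotypes)) genotypes <- unique(seen)
  genotypes <- as.character(genotypes)
  check_unique_ids(genotypes, "roster")
  if (length(genotypes) == 0L) stop("no genotypes to assemble")

  vals <- matrix(NA_real_, nrow = length(genotypes), ncol = nrow(sch),
                 dimnames = list(genotypes, sch$name))
  n_scan <- rep(NA_integer_, length(genotypes))
  n_germ <- rep(NA_integer_, length(genotypes))

  if (!is.null(seed_mass)) {
    check_unique_ids(seed_mass$genotype_id, "seed_mass")
    i <- match(as.character(seed_mass$genotype_id), genotypes)
    vals[i[!is.na(i)], "SeedMass"] <- seed_mass$seed_mass_mg[!is.na(i)]
  }
  if (!is.null(tomo)) {
    for (nm in names(.TOMO_MAP)) {
      mp <- .TOMO_MAP[[nm]]
      sub <- tomo[tomo$compartment == mp[1] & tomo$feature == mp[2], ,
                  drop = FALSE]
      check_unique_ids(sub$genotype_id, paste0("tomo/", nm))
      i <- match(as.character(sub$genotype_id), genotypes)
      vals[i[!is.na(i)], nm] <- sub$mean[!is.na(i)]
      i2 <- i[!is.na(i)]
      n_scan[i2] <- as.integer(sub$n_seeds[!is.na(i)])
    }
  }
  if (!is.null(germ)) {
    for (nm in names(.GERM_MAP)) {
      mp <- .GERM_MAP[[nm]]
      sub <- germ[germ$temperature == as.numeric(mp[1]), , drop = FALSE]
      check_unique_ids(sub$genotype_id, paste0("germ/", nm))
      i <- match(as.character(sub$genotype_id), genotypes)
      vals[i[!is.na(i)], nm] <- sub[[mp[2]]][!is.na(i)]
      n_germ[i[!is.na(i)]] <- as.integer(sub$n_total[!is.na(i)])
    }
  }
  if (!is.null(elong)) {
    check_unique_ids(elong$genotype_id, "elong")
    i <- match(as.character(elong$genotype_id), genotypes)
    vals[i[!is.na(i)], "HGerm_10C"] <- elong$hgerm_h[!is.na(i)]
    vals[i[!is.na(i)], "RadLg_10C"] <- elong$radlg_mm[!is.na(i)]
  }

  out <- tibble::as_tibble(as.data.frame(vals))
  names(out) <- sch$column
  out <- tibble::tibble(genotype_id = genotypes, out,
                        n_seeds_scanned = n_scan, n_seeds_germ = n_germ)
  miss <- which(is.na(vals), arr.ind = TRUE)
  missing_tbl <- tibble::tibble(
    genotype_id = genotypes[miss[, 1]],
    column = sch$column[miss[, 2]],
    reason = "not_assayed"
  )
  attr(out, "missing") <- missing_tbl
  class(out) <- c("phenotype_table", class(out))
  out
}

#' Configuration of a full synthetic experiment
#'
#' @param n_progeny,n_controls Roster sizes (defaults 198 progeny + 4
#'   commercial controls); genotype ids are generated as `P001...` and
#'   `C1...`. Supply `genotypes` to override.
#' @param genotypes Explicit id vector (unique, non-empty), or `NULL`.
#' @param seeds_per_scan Seeds per tomography scan.
#' @param germ_seeds_per_temp Seeds sown per germination assay.
#' @param temperatures Germination assay temperatures (each must have a
#'   [germ_protocol()]).
#' @param elong_seeds Seeds per elongation box.
#' @param elong_offset_h Offset after Hgerm at which RadLg is read.
#' @param rng_seed Master seed; per-genotype/per-assay seeds derive from
#'   it.
#' @return Object of class `experiment_config`.
#' @export
experiment_config <- function(n_progeny = 198L, n_controls = 4L,
                              genotypes = NULL, seeds_per_scan = 25L,
                              germ_seeds_per_temp = 50L,
                              temperatures = c(5, 10, 20),
                              elong_seeds = 10L, elong_offset_h = 168,
                              rng_seed = 1L) {
  if (is.null(genotypes)) {
    genotypes <- c(sprintf("P%03d", seq_len(n_progeny)),
                   sprintf("C%d", seq_len(n_controls)))
  }
  genotypes <- as.character(genotypes)
  if (length(genotypes) == 0L) stop("genotype roster is empty")
  check_unique_ids(genotypes, "config roster")
  stopifnot(seeds_per_scan >= 1L, germ_seeds_per_temp >= 1L,
            elong_seeds >= 1L, elong_offset_h > 0)
  for (tp in temperatures) germ_protocol(tp) # validates
  structure(
    list(genotypes = genotypes, seeds_per_scan = as.integer(seeds_per_scan),
         germ_seeds_per_temp = as.integer(germ_seeds_per_temp),
         temperatures = temperatures, elong_seeds = as.integer(elong_seeds),
         elong_offset_h = elong_offset_h, rng_seed = as.integer(rng_seed)),
    class = "experiment_config"
  )
}

# Deterministic per-genotype, per-stage RNG seed below 2^31.
stage_seed <- function(config, g, stage) {
  (config$rng_seed * 7L + g * 131L + stage * 7919L) %% 2147483647L
}

# Per-genotype germination median: genotypes differ in vigor; the 120 h
# population median at 10 degC is scaled per genotype and temperature
# (germination slows sharply with cold).
germ_meanlog <- function(temperature, vigor) {
  base <- switch(as.character(temperature),
                 "5" = log(320), "10" = log(120), "20" = log(60))
  base - log(vigor)
}

# Morphometry of one genotype without voxelization: per-seed analytic
# compartment features from the phantom geometry at the seed's size
# factor, pushed through the same QC and summary stages as imaged scans.
summary_morphometry <- function(config, g) {
  sid <- stage_seed(config, g, 1L)
  spec <- phantom_spec()
  n <- config$seeds_per_scan
  withr::with_seed(sid, {
    scales <- exp(rnorm(n, 0, 0.04))
  })
  # volumes scale as s^3 and areas as s^2, so one truth evaluation covers
  # every seed size
  tr <- phantom_truth_features(spec)
  env <- tr$volume_mm3[tr$compartment == "whole_seed"]
  keep <- tr$compartment %in% c("embryo", "perisperm", "coat", "whole_seed")
  tr <- tr[keep, , drop = FALSE]
  k <- nrow(tr)
  s3 <- rep(scales^3, each = k)
  v <- rep(tr$volume_mm3, n) * s3
  a <- rep(tr$surface_mm2, n) * rep(scales^2, each = k)
  feats <- tibble::tibble(
    seed_index = rep(seq_len(n), each = k),
    compartment = rep(tr$compartment, n),
    volume_mm3 = v, surface_mm2 = a,
    shape_va3d = a^3 / (36 * pi * v^2),
    spherical_diameter_mm = (6 * v / pi)^(1 / 3),
    filling_factor = rep(tr$volume_mm3 / env, n)
  )
  qc <- qc_filter(feats)
  summarize_features(feats, qc, genotype_id = config$genotypes[g])
}

# Morphometry of one genotype through the full imaging chain:
# scan rendering, thresholding, individualization, compartment
# segmentation and per-seed feature extraction.
imaging_morphometry <- function(config, g, log_add) {
  sid <- stage_seed(config, g, 1L)
  scan <- make_scan(scan_spec(n_seeds = config$seeds_per_scan,
                              rng_seed = sid))
  den <- denoise(scan$tomogram, method = "median")
  mask <- threshold_mask(den)
  log_add(sprintf("genotype %s: tau = %.3f",
                  config$genotypes[g], mask$threshold_used))
  seeds <- individualize_seeds(scan$tomogram, mask,
                               expected_n = config$seeds_per_scan)
  feats <- do.call(rbind, lapply(seq_along(seeds), function(s) {
    seg <- segment_components(seeds[[s]])
    compute_features(seg, seed_index = s)
  }))
  qc <- qc_filter(feats)
  summarize_features(feats, qc, genotype_id = config$genotypes[g])
}

# Germination kinetics of one genotype at one temperature (records
# simulated on the protocol's frame grid; detection adds nothing in
# event-table mode).
summary_germination <- function(config, g, temperature, vigor) {
  proto <- germ_protocol(temperature)
  sid <- stage_seed(config, g, 10L + as.integer(temperature))
  spec <- germination_sim_spec(
    n_seeds = config$germ_seeds_per_temp,
    meanlog = germ_meanlog(temperature, vigor),
    frame_interval = proto$frame_interval,
    duration = proto$final_days * 24,
    rng_seed = sid
  )
  sim <- make_germination_series(spec)
  out <- assay_summary(sim$records, n_total = spec$n_seeds, temperature)
  out$genotype_id <- config$genotypes[g]
  out
}

# Elongation of one genotype from noise-free analytic tracks.
summary_elongation <- function(config, g, vigor) {
  sid <- stage_seed(config, g, 2L)
  spec <- elongation_sim_spec(n_seeds = config$elong_seeds,
                              meanlog = germ_meanlog(10, vigor),
                              rng_seed = sid)
  sim <- make_elongation_series(spec)
  # extend the box run until every seed reaches the RadLg offset
  # (the truth draw depends only on the seed, not the duration)
  need <- max(sim$truth$hgerm) + config$elong_offset_h
  if (need > spec$duration) {
    spec$duration <- ceiling(need / spec$frame_interval) * spec$frame_interval
    sim <- make_elongation_series(spec)
  }
  radlg <- vapply(sim$tracks, radlg_at_offset, numeric(1),
                  offset = config$elong_offset_h)
  tibble::tibble(genotype_id = config$genotypes[g],
                 hgerm_h = mean(sim$truth$hgerm),
                 radlg_mm = mean(radlg))
}

#' Run the full experiment pipeline
#'
#' Drives every assay for every genotype of the config and assembles the
#' phenotype table. `detail = "summary"` computes morphometry from the
#' generators' analytic per-seed geometry (no voxel rendering) and
#' kinetics/elongation from simulated event tables and tracks, so the
#' full 202-genotype schema run takes seconds; `detail = "imaging"` runs
#' the complete voxel and frame chains (use small rosters). A failure in
#' any stage stops the run with the stage name; results of completed
#' genotypes are retained in the error's `partial` field and, when
#' `out_dir` is set, on disk.
#'
#' @param config An [experiment_config()].
#' @param mode `"synthetic"` (generate the data) — reading measured
#'   archives is out of scope here.
#' @param detail `"summary"` or `"imaging"`.
#' @param out_dir Optional directory: writes `phenotypes.csv`,
#'   `missing.csv` and `run_log.txt`.
#' @return List: `table` (a [assemble_table()] result) and `log`
#'   (character vector; records the thresholds actually used).
#' @export
run_pipeline <- function(config, mode = c("synthetic", "from_files"),
                         detail = c("summary", "imaging"),
                         out_dir = NULL) {
  mode <- match.arg(mode)
  detail <- match.arg(detail)
  stopifnot(inherits(config, "experiment_config"))
  if (mode == "from_files") {
    stop("stage input: mode 'from_files' requires measured archives; ",
         "only 'synthetic' is available")
  }
  log_lines <- character(0)
  log_add <- function(msg) log_lines <<- c(log_lines, msg)
  tomo <- NULL; germ <- NULL; elong <- NULL; mass <- NULL
  ng <- length(config$genotypes)
  vigor <- withr::with_seed(config$rng_seed,
                            exp(rnorm(ng, 0, 0.15))) # genotype vigor spread
  run_stage <- function(stage_name, fun) {
    tryCatch(fun(), error = function(e) {
      partial <- list(tomo = tomo, germ = germ, elong = elong)
      err <- simpleError(paste0("stage ", stage_name, " failed: ",
                                conditionMessage(e)))
      err$partial <- partial
      if (!is.null(out_dir)) {
        writeLines(c(log_lines, conditionMessage(err)),
                   file.path(out_dir, "run_log.txt"))
      }
      stop(err)
    })
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  }
  mass <- run_stage("seed_mass", function() {
    withr::with_seed(config$rng_seed + 1L, tibble::tibble(
      genotype_id = config$genotypes,
      seed_mass_mg = round(rnorm(ng, 14, 2), 2)
    ))
  })
  tomo <- run_stage("tomoseg/morpho3d", function() {
    do.call(rbind, lapply(seq_len(ng), function(g) {
      if (detail == "summary") summary_morphometry(config, g)
      else imaging_morphometry(config, g, log_add)
    }))
  })
  germ <- run_stage("germkin", function() {
    do.call(rbind, lapply(seq_len(ng), function(g) {
      do.call(rbind, lapply(config$temperatures, function(tp)
        summary_germination(config, g, tp, vigor[g])))
    }))
  })
  elong <- run_stage("elong", function() {
    do.call(rbind, lapply(seq_len(ng), function(g)
      summary_elongation(config, g, vigor[g])))
  })
  tab <- run_stage("assemble", function() {
    assemble_table(tomo = tomo, germ = germ, elong = elong,
                   seed_mass = mass, genotypes = config$genotypes)
  })
  log_add(sprintf("assembled %d genotypes x %d phenotype columns",
                  nrow(tab), nrow(phenotype_schema())))
  if (!is.null(out_dir)) {
    write_phenotype_csv(tab, file.path(out_dir, "phenotypes.csv"))
    utils::write.csv(attr(tab, "missing"),
                     file.path(out_dir, "missing.csv"), row.names = FALSE)
    writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  }
  list(table = tab, log = log_lines)
}
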
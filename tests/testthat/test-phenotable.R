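test_that("the schema has exactly 28 coded variables in three groups", {
  sch <- phenotype_schema()
  expect_equal(nrow(sch), 28L)
  expect_equal(sum(sch$group == "tomograph"), 13L)
  expect_equal(sum(sch$group == "germination"), 13L)
  expect_equal(sum(sch$group == "elongation"), 2L)
  expect_true(all(grepl("^CO_333:[0-9]{7}$", sch$code)))
  expect_true(all(grepl("^[A-Za-z0-9_]+\\[CO_333:[0-9]{7}\\]$", sch$column)))
  expect_false(any(duplicated(sch$column)))
})

test_that("assemble_table marks missing assays instead of dropping rows", {
  mass <- tibble::tibble(genotype_id = c("A", "B"),
                         seed_mass_mg = c(14, 15))
  germ <- tibble::tibble(genotype_id = "A", temperature = 10,
                         mgt_h = 100, t50_h = 98, t70_h = 110,
                         early_rate_pct = NA_real_, final_rate_pct = 92,
                         n_total = 50, duration_days = 15)
  tab <- assemble_table(germ = germ, seed_mass = mass)
  expect_equal(nrow(tab), 2L)
  expect_equal(tab[["MGT_10C[CO_333:1000311]"]], c(100, NA))
  miss <- attr(tab, "missing")
  expect_true(all(c("genotype_id", "column", "reason") %in% names(miss)))
  # B misses the 10 degC block; A misses e.g. the 5 degC block
  expect_true(any(miss$genotype_id == "B" &
                    miss$column == "MGT_10C[CO_333:1000311]"))
  expect_true(any(miss$genotype_id == "A" &
                    miss$column == "MGT_5C[CO_333:1000311]"))
})

test_that("duplicate genotype ids are rejected", {
  mass <- tibble::tibble(genotype_id = c("A", "A"), seed_mass_mg = c(1, 2))
  expect_error(assemble_table(seed_mass = mass), "duplicate")
  expect_error(assemble_table(genotypes = c("A", "A")), "duplicate")
})

test_that("the pipeline is deterministic and writes a stable header", {
  cfg <- tiny_config()
  out1 <- tempfile()
  out2 <- tempfile()
  r1 <- run_pipeline(cfg, detail = "summary", out_dir = out1)
  r2 <- run_pipeline(cfg, detail = "summary", out_dir = out2)
  expect_identical(as.data.frame(r1$table), as.data.frame(r2$table))
  h1 <- readLines(file.path(out1, "phenotypes.csv"), n = 1)
  h2 <- readLines(file.path(out2, "phenotypes.csv"), n = 1)
  expect_identical(h1, h2)
  sch <- phenotype_schema()
  expect_true(all(vapply(sch$column, function(cn)
    grepl(cn, h1, fixed = TRUE), logical(1))))
  # round trip through CSV preserves the schema columns
  back <- read_phenotype_csv(file.path(out1, "phenotypes.csv"))
  expect_true(all(sch$column %in% names(back)))
})

test_that("imaging and summary details agree on the phenotype scale", {
  cfg <- tiny_config(genotypes = "G1")
  s <- run_pipeline(cfg, detail = "summary")$table
  i <- run_pipeline(cfg, detail = "imaging")$table
  sch <- phenotype_schema()
  vol_cols <- sch$column[grepl("Vol\\[", sch$column)]
  for (cn in vol_cols) {
    expect_lt(abs(i[[cn]] - s[[cn]]) / s[[cn]], 0.25)
  }
})

test_that("pipeline failures name the stage and keep partial results", {
  cfg <- tiny_config()
  cfg$temperatures <- c(10, 37) # no such protocol
  err <- tryCatch(run_pipeline(cfg, detail = "summary"),
                  error = function(e) e)
  expect_match(conditionMessage(err), "stage germkin failed")
  expect_false(is.null(err$partial$tomo)) # earlier stage retained
  expect_error(run_pipeline(tiny_config(), mode = "from_files"),
               "from_files")
})

test_that("volume TIFF round trips keep intensities within quantization", {
  scan <- make_scan(small_scan_spec())
  path <- tempfile(fileext = ".tif")
  write_volume_tiff(scan$tomogram, path)
  back <- read_volume_tiff(path)
  expect_equal(dim(back$intensities), dim(scan$tomogram$intensities))
  expect_equal(back$spacing, scan$tomogram$spacing)
  q <- max(scan$tomogram$intensities) / 65535
  expect_lt(max(abs(back$intensities - scan$tomogram$intensities)), q)
})

test_that("the CLI front end drives simulation and assembly", {
  out <- tempfile()
  expect_invisible(seedphenom_cli(c("simulate", "germination",
                                    "--out", out, "--seed", "3",
                                    "--n-seeds", "10")))
  rec <- read_event_csv(file.path(out, "events.csv"))
  expect_equal(nrow(rec), 10L)
  out2 <- tempfile()
  seedphenom_cli(c("germ", "run", "--events",
                   file.path(out, "events.csv"),
                   "--temperature", "10", "--n-total", "10",
                   "--out", out2))
  kin <- utils::read.csv(file.path(out2, "kinetics.csv"))
  expect_equal(kin$temperature, 10)
  expect_error(seedphenom_cli(c("frobnicate")), "unknown command")
})
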
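# seedphenom

High-throughput seed and seedling phenotyping of sugar beet from 3D
X-ray microtomograms and time-lapse imagery, with synthetic generators
providing exact ground truth for every stage.

A sugar beet "seed" is botanically a fruit: a corky **pericarp (seed
coat)** enclosing the true seed, whose ring-shaped **embryo** encircles
a central nutrient store, the **perisperm**; an internal empty
**cavity** completes the anatomy. The package covers three assays over
this material and their fusion into one genotype-level table:

* **Tomography** — segment dry-seed microtomograms into the four
  compartments (threshold mask, 26-connectivity seed individualization,
  marker-controlled watershed) and measure per-compartment volume,
  surface area, 3D shape factor `A³/(36πV²)`, equivalent spherical
  diameter `(6V/π)^(1/3)` and filling factor.
* **Germination** — detect per-seed germination events in time-lapse
  frames (seed movement and radicle protrusion), then compute mean
  germination time, T50/T70 by linear interpolation over the sown
  population, and early/final germination rates under per-temperature
  protocols (5, 10, 20 °C).
* **Elongation** — track radicle and shoot lengths of seedlings growing
  under green (inactinic) light by skeleton path length with a
  gravitropic down/up organ split, and read the radicle length a fixed
  168 h after each seed's own germination hour.

Results assemble into a phenotype table with exactly **28
crop-ontology-coded variables** (13 tomograph, 13 germination, 2
elongation) over a roster of 202 genotypes (198 progeny + 4 commercial
controls). Because real scanner/camera archives are not shipped, every
assay has a **synthetic generator** (`make_scan()`,
`make_germination_series()`, `make_elongation_series()`) whose ground
truth is exact, making the full chain verifiable to stated tolerances.
See the methods vignette (`vignettes/methods.Rmd`) for models,
parameters and numerical choices.

## Worked example

Generate a 25-seed scan, individualize the seeds, segment one into
compartments and measure it:

```r
library(seedphenom)

scan <- make_scan(scan_spec(n_seeds = 25, rng_seed = 1))
scan$tomogram
#> <tomogram> 231 x 231 x 46 voxels, spacing 0.1 x 0.1 x 0.1 mm
#>   scan_id: synthetic-1

mask <- threshold_mask(denoise(scan$tomogram, method = "median"))
mask
#> <binary_mask3d> 231 x 231 x 46 voxels, 458873 foreground, tau = 65.11

seeds <- individualize_seeds(scan$tomogram, mask, expected_n = 25)
length(seeds)
#> [1] 25

f <- compute_features(segment_components(seeds[[1]]), seed_index = 1)
f[, c("compartment", "volume_mm3", "surface_mm2", "shape_va3d")]
#>   compartment volume_mm3 surface_mm2 shape_va3d
#> 1      embryo      0.876        7.13      4.173
#> 2   perisperm      1.549        6.34      0.937
#> 3        coat     19.019       51.24      3.288
#> 4  whole_seed     21.462       37.61      1.021
```

Germination kinetics of one simulated assay at 10 °C:

```r
rec <- make_germination_series(germination_sim_spec(n_seeds = 25,
                                                    rng_seed = 1))$records
assay_summary(rec, n_total = 25, temperature = 10)
#>   temperature mgt_h t50_h t70_h early_rate_pct final_rate_pct n_total duration_days
#> 1          10 130.7   135 145.5             NA             96      25            15
```

And the full synthetic experiment (202 genotypes, 28 variables, a few
tens of seconds):

```r
res <- run_pipeline(experiment_config(rng_seed = 1), detail = "summary")
res$table[1:3, 1:3]
#>   genotype_id `SeedMass[CO_333:1000327]` `PerispVol[CO_333:1000324]`
#> 1 P001                              12.2                        1.33
#> 2 P002                              14.4                        1.32
#> 3 P003                              17.2                        1.25
```

A thin command-line front end wraps the same functions:

```sh
exec/seedphenom run --out out/ --seed 1          # full synthetic run
exec/seedphenom simulate scan --out out/ --seed 1
exec/seedphenom --help
```

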
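sphere_labeling <- function(radius_mm, spacing_mm) {
  make_seed_phantom(phantom_spec_sphere(radius_mm,
                                        voxel_spacing = spacing_mm))$labeling
}

test_that("digital spheres reproduce the analytic morphometry", {
  r <- 0.5
  lab <- sphere_labeling(r, r / 25) # radius = 25 voxels
  v <- volume_of(lab, "perisperm")
  a <- surface_area_of(lab, "perisperm")
  expect_lt(abs(v - 4 / 3 * pi * r^3) / (4 / 3 * pi * r^3), 0.02)
  expect_lt(abs(a - 4 * pi * r^2) / (4 * pi * r^2), 0.02)
  expect_lt(abs(shape_va3d(v, a) - 1), 0.02)
  expect_lt(abs(spherical_diameter(v) - 2 * r) / (2 * r), 0.02)
})

test_that("morphometry is exactly scale-equivariant in the voxel spacing", {
  lab1 <- sphere_labeling(0.5, 0.02)
  lab2 <- lab1
  lab2$spacing <- lab1$spacing * 3
  expect_equal(volume_of(lab2, "perisperm"),
               27 * volume_of(lab1, "perisperm"))
  expect_equal(surface_area_of(lab2, "perisperm"),
               9 * surface_area_of(lab1, "perisperm"))
  expect_equal(shape_va3d(volume_of(lab2, "perisperm"),
                          surface_area_of(lab2, "perisperm")),
               shape_va3d(volume_of(lab1, "perisperm"),
                          surface_area_of(lab1, "perisperm")))
  expect_equal(spherical_diameter(volume_of(lab2, "perisperm")),
               3 * spherical_diameter(volume_of(lab1, "perisperm")))
})

test_that("voxel-face surface areas overestimate smooth bodies", {
  lab <- sphere_labeling(0.5, 0.02)
  a_mesh <- surface_area_of(lab, "perisperm")
  a_faces <- surface_area_of(lab, "perisperm", method = "voxel_faces")
  expect_gt(a_faces / a_mesh, 1.3) # the classic ~1.5x staircase bias
})

test_that("compute_features covers all compartments and the envelope", {
  ph <- make_seed_phantom(phantom_spec(noise_sd = 0))
  f <- compute_features(ph$labeling, seed_index = 1L)
  expect_setequal(f$compartment,
                  c("embryo", "perisperm", "coat", "whole_seed"))
  expect_true(all(f$volume_mm3 > 0))
  expect_true(all(f$filling_factor > 0 & f$filling_factor <= 1))
  # whole seed envelope holds every part (incl. the cavity)
  env <- f$volume_mm3[f$compartment == "whole_seed"]
  expect_gt(env, sum(f$volume_mm3[f$compartment != "whole_seed"]))
})

test_that("feature summaries respect QC and error with no valid seeds", {
  ph <- make_seed_phantom(phantom_spec(noise_sd = 0))
  f1 <- compute_features(ph$labeling, seed_index = 1L)
  f2 <- compute_features(ph$labeling, seed_index = 2L)
  feats <- rbind(f1, f2)
  qc <- qc_filter(feats)
  expect_true(all(qc$status == "accepted"))
  s <- summarize_features(feats, qc, genotype_id = "G")
  expect_equal(unique(s$n_seeds), 2L)
  expect_true(all(s$sd[s$feature == "volume_mm3"] == 0)) # identical seeds
  qc_bad <- qc
  qc_bad$status <- "rejected"
  expect_error(summarize_features(feats, qc_bad, "G"), "no valid seeds")
})

test_that("QC flags empty and malformed seeds", {
  ph <- make_seed_phantom(phantom_spec(noise_sd = 0))
  good <- compute_features(ph$labeling, seed_index = 1L)
  empty <- good
  empty$seed_index <- 2L
  empty$volume_mm3[empty$compartment == "embryo"] <- 0
  odd <- good
  odd$seed_index <- 3L
  odd$shape_va3d[odd$compartment == "embryo"] <- 50 # out of the shape band
  qc <- qc_filter(rbind(good, empty, odd))
  expect_equal(qc$status[qc$seed_index == 1L], "accepted")
  expect_equal(qc$reason[qc$seed_index == 2L], "empty")
  expect_equal(qc$reason[qc$seed_index == 3L], "malformed")
})
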
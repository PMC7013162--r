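# Shared fixtures: small, fast variants of the generators.

small_scan_spec <- function(n_seeds = 4L, rng_seed = 11L) {
  scan_spec(n_seeds = n_seeds, rng_seed = rng_seed)
}

# Dice of one labeled class between two label arrays.
class_dice <- function(pred, truth, class_code) {
  dice_coefficient(pred == class_code, truth == class_code)
}

tiny_config <- function(genotypes = c("G1", "G2"), rng_seed = 7L) {
  experiment_config(genotypes = genotypes, seeds_per_scan = 4L,
                    germ_seeds_per_temp = 10L, elong_seeds = 3L,
                    rng_seed = rng_seed)
}
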
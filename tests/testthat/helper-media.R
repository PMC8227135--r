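# In-code fixtures shared across the suite: lossless media matching the
# shipped table's speeds/densities, and the reference five-layer chamber
# stack (bath / slide / sample gap / coverslip / air backing).

water0 <- function() acoustic_medium("water", 1000, 1480)
glass0 <- function() acoustic_medium("glass", 2500, 5600, 3400)
polystyrene0 <- function() acoustic_medium("polystyrene", 1050, 2350, 1120)
air0 <- function() acoustic_medium("air", 1.204, 343)

# lossless chamber stack; wall medium swappable
chamber_stack0 <- function(wall = glass0(), gap = 15e-6) {
  layer_stack(
    list(water0(), wall, water0(), wall, air0()),
    c(Inf, 1.2e-3, gap, 0.17e-3, Inf)
  )
}

# registry with all attenuation zeroed (for lossless pipeline comparisons)
lossless_materials <- function() {
  mats <- sono_materials()
  mats$alpha0_db_per_cm <- 0
  mats
}

# relative difference between two complex amplitude vectors
rel_diff <- function(a, b) max(Mod(a - b)) / max(Mod(b))
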
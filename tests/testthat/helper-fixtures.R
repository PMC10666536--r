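# Table of printed interfacial measurements used across tests:
# monolayer tension (mN/m), contact angle (deg), and the derived bilayer
# tension (mN/m) and |formation free energy| (mJ/m^2) they should reproduce.
dopc_asa_table <- function() {
  tibble::tribble(
    ~label, ~gamma_m, ~theta, ~gamma_B, ~abs_dF,
    "1:0", 1.12, 36.7, 1.80, 0.445,
    "10:1", 1.07, 35.2, 1.74, 0.391,
    "4:1", 1.02, 33.1, 1.71, 0.331,
    "2:1", 0.92, 27.1, 1.64, 0.203,
    "1:1", 0.92, 25.9, 1.66, 0.185
  )
}

# a small droplet pair that equilibrates quickly
small_pair <- function(osm1 = 300, osm2 = 100) {
  V0 <- 4 / 3 * pi * 50^3
  droplet_pair_state(V0, V0, osm1, osm2, A = pi * 20^2)
}

# standard measurement-scale pair matching the generator defaults
default_pair <- function() {
  V0 <- 4 / 3 * pi * 150^3
  droplet_pair_state(V0, V0, 300, 100, A = pi * 60^2)
}

noiseless_config <- function(seed = 1) {
  synth_config(seed = seed,
               noise = list(radius_rel = 0, dsc_abs = 0, raman_abs = 0))
}
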
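# shared shortcuts for building profiles and species in tests

make_profile <- function(pair = c("Gly", "Gly"), conformer = 1,
                         e_pair = -60, e_ts = 200, e4 = -50, e5 = 150,
                         kind = "amide") {
  reaction_profile(pair, conformer, e_pair = e_pair, e_ts = e_ts,
                   e_product_bound_water = e4, e_product_free_water = e5,
                   approximate = TRUE, kind = kind)
}

glycine <- species_info("Gly", 10, 75.07, "amino_acid")
alanine <- species_info("Ala", 13, 89.09, "amino_acid")

default_cloud <- function(uv_class = "none") {
  cloud_environment(100, 1e7, 1e-7, uv_class)
}

# profiles between two plain amino-acid monomers (excludes the tetramer row)
amide_pair_profiles <- function(lib) {
  Filter(function(p) {
    all(vapply(p$pair, function(nm) lib$species[[nm]]$kind, "") ==
          "amino_acid")
  }, lib$profiles)
}

find_profile <- function(lib, pair, conformer = 1) {
  hit <- Filter(function(p) all(p$pair == pair) && p$conformer == conformer,
                lib$profiles)
  if (!length(hit)) stop("no such profile in library")
  hit[[1]]
}
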
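#' Configuration for the synthetic profile/environment generators
#'
#' The generators draw reaction profiles and cloud environments with the
#' statistical structure of the study conditions: pair binding uniform on
#' [-100, -25] kJ/mol, transition states uniform on [-50, +300] kJ/mol,
#' the bound-water product normal around -50 kJ/mol (sd 15, clipped below
#' zero), water removal normal around +200 kJ/mol (sd 30, clipped positive),
#' H2 density log-uniform on [1e7, 1e8] cm^-3, temperature uniform on
#' [100, 200] K, fractional abundance 1e-7. Uniform and (clipped) normal
#' draws are the minimally informative choices for quantities stated only
#' as ranges or typical values.
#'
#' @param n_profiles number of profiles to draw (>= 1).
#' @param seed integer seed; identical seeds give identical output.
#' @param binding_range,ts_range kJ/mol, `c(min, max)`; the binding range
#'   must be entirely negative (a positive hydrogen-bond "binding" is a
#'   contradiction and is rejected).
#' @param state4_center,state4_spread kJ/mol.
#' @param water_removal_center,water_removal_spread kJ/mol (center > 0).
#' @param n_h2_range cm^-3; `temperature_range` K; `fractional_abundance`
#'   dimensionless.
#' @return an object of class `generator_config`.
#' @export
generator_config <- function(n_profiles = 14L, seed = 1L,
                             binding_range = c(-100, -25),
                             ts_range = c(-50, 300),
                             state4_center = -50, state4_spread = 15,
                             water_removal_center = 200,
                             water_removal_spread = 30,
                             n_h2_range = c(1e7, 1e8),
                             temperature_range = c(100, 200),
                             fractional_abundance = 1e-7) {
  n_profiles <- as.integer(n_profiles)
  if (is.na(n_profiles) || n_profiles < 1L) stop("n_profiles must be >= 1")
  chk_range <- function(r, what) {
    if (length(r) != 2L || !is.numeric(r) || r[1] >= r[2])
      stop(what, " must be a non-degenerate c(min, max) range")
  }
  chk_range(binding_range, "binding_range")
  chk_range(ts_range, "ts_range")
  chk_range(n_h2_range, "n_h2_range")
  chk_range(temperature_range, "temperature_range")
  if (binding_range[2] >= 0)
    stop("binding_range must be entirely negative: ",
         "hydrogen-bonded complexes are bound")
  if (water_removal_center <= 0)
    stop("water_removal_center must be positive")
  if (state4_spread <= 0 || water_removal_spread <= 0)
    stop("spreads must be positive")
  structure(
    list(n_profiles = n_profiles, seed = as.integer(seed),
         binding_range = binding_range, ts_range = ts_range,
         state4_center = state4_center, state4_spread = state4_spread,
         water_removal_center = water_removal_center,
         water_removal_spread = water_removal_spread,
         n_h2_range = n_h2_range, temperature_range = temperature_range,
         fractional_abundance = fractional_abundance,
         algorithm = "cloudamide-synth-v1 (Mersenne-Twister)"),
    class = "generator_config"
  )
}

# normal draw truncated to one side by redrawing (clip by rejection keeps
# the distribution shape near the center)
rnorm_clipped <- function(n, mean, sd, upper = NULL, lower = NULL) {
  x <- stats::rnorm(n, mean, sd)
  for (i in seq_len(50)) {
    bad <- (!is.null(upper) & x >= upper) | (!is.null(lower) & x <= lower)
    if (!any(bad)) break
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  if (!is.null(upper)) x <- pmin(x, upper - 1e-9)
  if (!is.null(lower)) x <- pmax(x, lower + 1e-9)
  x
}

#' Generate a synthetic reaction-profile library
#'
#' Draws `n_profiles` amide profiles between synthetic amino-acid species
#' under the configured energy distributions. Every generated profile
#' satisfies the reaction-profile invariants (bound pair, positive water
#' removal) and the whole library passes validation and a JSON round trip.
#' The seed and generator identifier are attached as attributes and written
#' into serialized output metadata.
#'
#' @param cfg a [generator_config()].
#' @return a validated `profile_library` with attributes `seed` and
#'   `algorithm`.
#' @export
generate_profiles <- function(cfg = generator_config()) {
  stopifnot(inherits(cfg, "generator_config"))
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(cfg$seed)
  n <- cfg$n_profiles
  # synthetic monomers: atom counts and masses in the amino-acid range
  n_sp <- max(2L, ceiling(sqrt(2 * n)))
  atoms <- sample(10:27, n_sp, replace = TRUE)
  species <- lapply(seq_len(n_sp), function(i) {
    species_info(sprintf("syn%02d", i), atoms[i],
                 mass = 75 + 6.5 * (atoms[i] - 10) + stats::runif(1, -3, 3),
                 kind = "amino_acid")
  })
  names(species) <- vapply(species, `[[`, "", "name")
  pair_idx <- cbind(sample.int(n_sp, n, replace = TRUE),
                    sample.int(n_sp, n, replace = TRUE))
  conf <- stats::ave(seq_len(n),
                     paste(pair_idx[, 1], pair_idx[, 2]),
                     FUN = seq_along)
  e_pair <- stats::runif(n, cfg$binding_range[1], cfg$binding_range[2])
  e_ts <- stats::runif(n, cfg$ts_range[1], cfg$ts_range[2])
  e4 <- rnorm_clipped(n, cfg$state4_center, cfg$state4_spread, upper = 0)
  dwr <- rnorm_clipped(n, cfg$water_removal_center,
                       cfg$water_removal_spread, lower = 0)
  profiles <- lapply(seq_len(n), function(i) {
    reaction_profile(
      pair = c(species[[pair_idx[i, 1]]]$name,
               species[[pair_idx[i, 2]]]$name),
      conformer = conf[i],
      e_pair = e_pair[i], e_ts = e_ts[i],
      e_product_bound_water = e4[i],
      e_product_free_water = e4[i] + dwr[i],
      approximate = TRUE, kind = "amide"
    )
  })
  lib <- profile_library(profiles, species)
  attr(lib, "seed") <- cfg$seed
  attr(lib, "algorithm") <- cfg$algorithm
  lib
}

#' Generate a synthetic cloud environment
#'
#' H2 density log-uniform over the configured range (densities are
#' scale-type quantities), temperature uniform, fractional abundance fixed
#' at the configured value.
#'
#' @param cfg a [generator_config()].
#' @param uv_class UV environment class for the generated cloud.
#' @return a `cloud_environment`.
#' @export
generate_environment <- function(cfg = generator_config(),
                                 uv_class = c("DC", "DISM", "none")) {
  stopifnot(inherits(cfg, "generator_config"))
  uv_class <- match.arg(uv_class)
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(cfg$seed + 1L)
  cloud_environment(
    temperature = stats::runif(1, cfg$temperature_range[1],
                               cfg$temperature_range[2]),
    n_h2 = 10^stats::runif(1, log10(cfg$n_h2_range[1]),
                           log10(cfg$n_h2_range[2])),
    fractional_abundance = cfg$fractional_abundance,
    uv_class = uv_class
  )
}
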
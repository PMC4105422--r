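#' UV environment photodestruction data
#'
#' Free amino acids exposed to short-wave (100-200 nm) UV are photolysed
#' with a half-life that depends on the radiation environment: ~300 yr in
#' the diffuse interstellar medium (DISM) versus ~3e7 yr inside a dark
#' cloud (DC). These half-lives are packaged empirical constants.
#'
#' @param uv_class `"DISM"` or `"DC"`.
#' @param half_life_yr override the packaged half-life (years, > 0).
#' @return an object of class `uv_environment` with fields `uv_class` and
#'   `monomer_half_life_yr`.
#' @examples
#' uv_environment("DC")
#' @export
uv_environment <- function(uv_class = c("DC", "DISM"),
                           half_life_yr = NULL) {
  uv_class <- match.arg(uv_class)
  if (is.null(half_life_yr)) {
    dat <- uv_fixture_data()
    half_life_yr <-
      dat$environments$half_life_yr[dat$environments$class == uv_class]
  }
  if (!is.numeric(half_life_yr) || half_life_yr <= 0)
    stop("half-life must be positive (years)")
  structure(
    list(uv_class = uv_class, monomer_half_life_yr = half_life_yr),
    class = "uv_environment"
  )
}

#' Packaged UV photochemistry constants
#'
#' Reads the shipped table of monomer photolysis half-lives per environment
#' class and measured peptide destruction quantum efficiencies
#' (Gly-Trp at 145 nm, 1.3e-2; Gly-Gly at 206 nm, 2.2e-2).
#'
#' @return list with data.frames `environments` (`class`, `half_life_yr`)
#'   and `peptides` (`species`, `wavelength_nm`, `quantum_efficiency`).
#' @export
uv_fixture_data <- function() {
  raw <- jsonlite::fromJSON(system.file("extdata", "uv_photochemistry.json",
                                        package = "cloudamide",
                                        mustWork = TRUE))
  list(environments = raw$environments, peptides = raw$peptides)
}

#' First-order photolysis rate from a half-life
#'
#' `ln(2) / t_half`, in s^-1. The conversion assumes first-order kinetics;
#' quoting the same destruction as a 1/e lifetime would differ by the
#' factor ln 2, which is why the convention is fixed here in one place.
#'
#' @param env_data a [uv_environment()] (or a bare half-life in years).
#' @return s^-1.
#' @export
photolysis_rate <- function(env_data) {
  half_life_yr <- if (inherits(env_data, "uv_environment"))
    env_data$monomer_half_life_yr else env_data
  stopifnot(is.numeric(half_life_yr), half_life_yr > 0)
  log(2) / convert_time(half_life_yr, "yr", "s")
}

#' Probability a monomer dimerizes before UV destruction
#'
#' Competition of two first-order channels acting on the same monomer:
#' collision-complex formation at `k_coll` versus photolysis at `k_phot`.
#' The branching probability into the complex is
#' `k_coll / (k_coll + k_phot)`. In a dark cloud (half-life 3e7 yr) with a
#' ~1600 yr collision timescale this exceeds 0.999: amino acids are
#' overwhelmingly incorporated into complexes before UV destroys them.
#'
#' @param collision_rate s^-1 (>= 0).
#' @param photolysis_rate s^-1 (>= 0); not both zero.
#' @return probability in (0, 1].
#' @export
dimerize_before_destruction <- function(collision_rate, photolysis_rate) {
  stopifnot(is.numeric(collision_rate), is.numeric(photolysis_rate),
            all(collision_rate >= 0), all(photolysis_rate >= 0))
  if (any(collision_rate + photolysis_rate == 0))
    stop("branching probability undefined when both rates are zero")
  collision_rate / (collision_rate + photolysis_rate)
}

#' Report on peptide photostability
#'
#' Echoes a measured peptide destruction quantum efficiency with its
#' wavelength and flags efficiencies below 0.05 as low — the regime in
#' which a peptide, whose absorbed photon energy is spread over many
#' vibrational modes and collisionally quenched, survives most UV
#' absorptions.
#'
#' @param species peptide label.
#' @param wavelength_nm exposure wavelength.
#' @param quantum_efficiency destruction quantum efficiency in `[0, 1]`.
#' @param low_threshold flag efficiencies strictly below this value.
#' @return list with the inputs plus logical `low_efficiency` and a
#'   one-line `note`.
#' @export
peptide_photostability_note <- function(species, wavelength_nm,
                                        quantum_efficiency,
                                        low_threshold = 0.05) {
  stopifnot(is.numeric(quantum_efficiency),
            quantum_efficiency >= 0, quantum_efficiency <= 1)
  low <- quantum_efficiency < low_threshold
  list(
    species = species,
    wavelength_nm = wavelength_nm,
    quantum_efficiency = quantum_efficiency,
    low_efficiency = low,
    note = sprintf(
      "%s at %g nm: destruction quantum efficiency %.3g (%s)",
      species, wavelength_nm, quantum_efficiency,
      if (low) "low - most absorptions do not destroy the peptide"
      else "not low")
  )
}
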
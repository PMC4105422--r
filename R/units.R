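#' Physical constants used throughout the package
#'
#' Named list of the constants every kinetic formula in the package relies on.
#' Energies are carried in molar units (kJ/mol), times in seconds with a
#' Julian-year conversion, so Arrhenius exponents evaluate as `Ea/RT`.
#'
#' \describe{
#'   \item{r_gas}{Molar gas constant, J mol^-1 K^-1 (8.314462618).}
#'   \item{kjmol_per_ev}{kJ/mol per electronvolt (96.485).}
#'   \item{avogadro}{Avogadro constant, mol^-1.}
#'   \item{seconds_per_year}{Julian year, 3.15576e7 s.}
#'   \item{amu_kg}{Atomic mass unit, kg.}
#'   \item{k_boltzmann}{Boltzmann constant, J K^-1.}
#'   \item{thermalization_timescale_s}{Timescale on which a freshly formed
#'     collision complex sheds its excess energy by collisions with ambient
#'     He/H2, 1e4 s. Adopted as a fixed empirical constant of the model, not
#'     computed from a collision model.}
#'   \item{radiative_equilibration_factor}{How much slower radiative
#'     equilibration with the cloud black-body field is than collisional
#'     equilibration at 100 K (factor 100). Fixed model constant.}
#' }
#'
#' @export
cloud_constants <- list(
  r_gas = 8.314462618,
  kjmol_per_ev = 96.485,
  avogadro = 6.02214076e23,
  seconds_per_year = 3.15576e7,
  amu_kg = 1.66053906660e-27,
  k_boltzmann = 1.380649e-23,
  thermalization_timescale_s = 1e4,
  radiative_equilibration_factor = 100
)

#' Convert energies between kJ/mol, eV, and J per molecule
#'
#' The literature on interstellar condensation mixes molar and per-molecule
#' units (a 0.6 eV hydrogen-bond depth is the same thing as ~58 kJ/mol); this
#' is the single conversion point used everywhere in the package.
#'
#' @param x numeric vector of energies.
#' @param from,to one of `"kJ/mol"`, `"eV"`, `"J"` (J means joule per
#'   molecule).
#' @return numeric vector in the `to` unit.
#' @examples
#' convert_energy(0.6, "eV", "kJ/mol") # ~57.9
#' @export
convert_energy <- function(x, from = "kJ/mol", to = "kJ/mol") {
  units <- c("kJ/mol", "eV", "J")
  from <- match.arg(from, units)
  to <- match.arg(to, units)
  # normalise to kJ/mol
  kj <- switch(from,
    "kJ/mol" = x,
    "eV" = x * cloud_constants$kjmol_per_ev,
    "J" = x * cloud_constants$avogadro / 1000
  )
  switch(to,
    "kJ/mol" = kj,
    "eV" = kj / cloud_constants$kjmol_per_ev,
    "J" = kj * 1000 / cloud_constants$avogadro
  )
}

#' Convert between seconds and Julian years
#'
#' @param x numeric vector of times.
#' @param from,to `"s"` or `"yr"` (Julian year, 3.15576e7 s).
#' @return numeric vector in the `to` unit.
#' @export
convert_time <- function(x, from = "s", to = "yr") {
  units <- c("s", "yr")
  from <- match.arg(from, units)
  to <- match.arg(to, units)
  s <- if (from == "s") x else x * cloud_constants$seconds_per_year
  if (to == "s") s else s / cloud_constants$seconds_per_year
}
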
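#' Molecular-cloud environment
#'
#' The kinetic environment assumed throughout: a warm dense cloud interior
#' with 1e7-1e8 H2 molecules cm^-3 at 100 K or more, the reacting species
#' present at a small fractional abundance (density relative to H2), and a
#' UV radiation class.
#'
#' @param temperature gas/radiation temperature in K (> 0).
#' @param n_h2 H2 number density in cm^-3 (>= 0).
#' @param fractional_abundance species density as a fraction of `n_h2`, in
#'   `[0, 1]`; 1e-7 is the canonical warm-dense-cloud value for an amino
#'   acid, giving 1 cm^-3 at 1e7 H2 cm^-3.
#' @param uv_class `"DC"` (dark cloud), `"DISM"` (diffuse interstellar
#'   medium) or `"none"`.
#' @return an object of class `cloud_environment`.
#' @examples
#' cloud_environment(100, 1e7, 1e-7, "DC")
#' @export
cloud_environment <- function(temperature = 100, n_h2 = 1e7,
                              fractional_abundance = 1e-7,
                              uv_class = c("DC", "DISM", "none")) {
  uv_class <- match.arg(uv_class)
  if (!is.numeric(temperature) || temperature <= 0)
    stop("temperature must be positive (K)")
  if (!is.numeric(n_h2) || n_h2 < 0)
    stop("n_h2 must be >= 0 (cm^-3)")
  if (!is.numeric(fractional_abundance) ||
      fractional_abundance < 0 || fractional_abundance > 1)
    stop("fractional_abundance must lie in [0, 1]")
  structure(
    list(temperature = temperature, n_h2 = n_h2,
         fractional_abundance = fractional_abundance, uv_class = uv_class),
    class = "cloud_environment"
  )
}

#' @export
print.cloud_environment <- function(x, ...) {
  cat(sprintf(
    "<cloud environment> T = %g K, n(H2) = %.3g cm^-3, fraction = %.3g, UV = %s\n",
    x$temperature, x$n_h2, x$fractional_abundance, x$uv_class))
  invisible(x)
}

#' Read / write a cloud environment as YAML
#'
#' Keys: `temperature_K`, `n_h2_cm3`, `fractional_abundance`, `uv_class`.
#'
#' @param path YAML file path.
#' @return [read_environment()] returns a `cloud_environment`;
#'   [write_environment()] returns `path` invisibly.
#' @export
read_environment <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  y <- yaml::read_yaml(path)
  need <- c("temperature_K", "n_h2_cm3", "fractional_abundance", "uv_class")
  miss <- setdiff(need, names(y))
  if (length(miss))
    stop("environment YAML missing key(s): ", paste(miss, collapse = ", "))
  # YAML 1.1 parses exponents without a sign ("1.0e7") as strings
  cloud_environment(as.numeric(y$temperature_K), as.numeric(y$n_h2_cm3),
                    as.numeric(y$fractional_abundance), y$uv_class)
}

#' @rdname read_environment
#' @param env a `cloud_environment`.
#' @export
write_environment <- function(env, path) {
  stopifnot(inherits(env, "cloud_environment"))
  yaml::write_yaml(list(
    temperature_K = env$temperature,
    n_h2_cm3 = env$n_h2,
    fractional_abundance = env$fractional_abundance,
    uv_class = env$uv_class
  ), path)
  invisible(path)
}

#' Kinetic rate parameters
#'
#' The bimolecular coefficient for hydrogen-bonded complex formation and the
#' Arrhenius pre-exponential range for its unimolecular dissociation.
#' `k2` is the product of collision cross section and mean relative speed
#' (sigma * v-bar), of order 2e-11 cm^3 s^-1 for amino acids at 100 K.
#' The pre-exponential factor runs from 1e12 s^-1 for "tight" transition
#' states to 1e15 s^-1 for "loose" ones.
#'
#' @param k2 bimolecular complex-formation coefficient, cm^3 s^-1 (> 0).
#' @param a_low,a_high bounds of the Arrhenius pre-exponential factor,
#'   s^-1 (`a_low <= a_high`).
#' @param ea_convention `"from_binding"`: the dissociation activation energy
#'   is the depth `|e_pair|` of the hydrogen-bonded complex; `"explicit"`:
#'   supplied by the caller.
#' @return an object of class `kinetic_parameters`.
#' @export
kinetic_parameters <- function(k2 = 2e-11, a_low = 1e12, a_high = 1e15,
                               ea_convention = c("from_binding", "explicit")) {
  ea_convention <- match.arg(ea_convention)
  if (!is.numeric(k2) || k2 <= 0) stop("k2 must be positive")
  if (!is.numeric(a_low) || !is.numeric(a_high) || a_low <= 0 ||
      a_low > a_high)
    stop("need 0 < a_low <= a_high")
  structure(
    list(k2 = k2, a_low = a_low, a_high = a_high,
         ea_convention = ea_convention),
    class = "kinetic_parameters"
  )
}

#' @export
print.kinetic_parameters <- function(x, ...) {
  cat(sprintf(
    "<kinetic parameters> k2 = %.3g cm^3/s, A in [%.3g, %.3g] s^-1, Ea: %s\n",
    x$k2, x$a_low, x$a_high, x$ea_convention))
  invisible(x)
}

#' Gas-kinetic rate coefficient from a cross section
#'
#' Optional route to `k2` = sigma * v-bar from a hard-sphere cross section
#' and the mean relative speed sqrt(8 kT / (pi mu)) of the colliding pair.
#' Provided for exploring departures from the default coefficient; the
#' packaged analyses always use the stated `k2 = 2e-11` cm^3 s^-1.
#'
#' @param sigma_cm2 collision cross section in cm^2.
#' @param mass1_u,mass2_u molecular masses in atomic mass units.
#' @param temperature K.
#' @return cm^3 s^-1.
#' @export
k2_from_cross_section <- function(sigma_cm2, mass1_u, mass2_u,
                                  temperature = 100) {
  stopifnot(sigma_cm2 > 0, mass1_u > 0, mass2_u > 0, temperature > 0)
  mu <- cloud_constants$amu_kg * mass1_u * mass2_u / (mass1_u + mass2_u)
  vbar_ms <- sqrt(8 * cloud_constants$k_boltzmann * temperature / (pi * mu))
  sigma_cm2 * vbar_ms * 100  # m/s -> cm/s
}

#' Number density of the reacting species
#'
#' @param env a `cloud_environment`.
#' @return cm^-3: `n_h2 * fractional_abundance`.
#' @export
species_density <- function(env) {
  stopifnot(inherits(env, "cloud_environment"))
  env$n_h2 * env$fractional_abundance
}

#' Per-monomer complex-formation rate
#'
#' The rate at which one monomer encounters a partner and forms a
#' hydrogen-bonded collision complex: `k2 * n_species`.
#'
#' @param n_species partner number density, cm^-3 (>= 0).
#' @param params [kinetic_parameters()].
#' @return s^-1.
#' @export
collision_rate <- function(n_species, params = kinetic_parameters()) {
  stopifnot(inherits(params, "kinetic_parameters"),
            is.numeric(n_species), all(n_species >= 0))
  params$k2 * n_species
}

#' Mean time for a monomer to form a collision complex
#'
#' Inverse of [collision_rate()], in Julian years. At the canonical 1 cm^-3
#' amino-acid density this is ~1.6e3 yr. Zero density returns `Inf` (the
#' documented no-collision sentinel), not an error.
#'
#' @inheritParams collision_rate
#' @return years; `Inf` when `n_species == 0`.
#' @export
collision_timescale <- function(n_species, params = kinetic_parameters()) {
  rate <- collision_rate(n_species, params)
  ifelse(rate > 0, convert_time(1 / rate, "s", "yr"), Inf)
}

#' Internal energy modes of a collision complex
#'
#' Two colliding molecules of M and N atoms merge into a complex with
#' `3(M+N-1)` internal modes (all degrees of freedom less the centre-of-mass
#' translation of the complex).
#'
#' @param m,n [species_info()] objects (or bare atom counts).
#' @return integer mode count.
#' @export
internal_mode_count <- function(m, n) {
  M <- if (inherits(m, "species_info")) m$atom_count else as.integer(m)
  N <- if (inherits(n, "species_info")) n$atom_count else as.integer(n)
  stopifnot(M >= 1, N >= 1)
  3L * (M + N - 1L)
}

#' Internal temperature rise on complex formation
#'
#' The kinetic energy of approach (3kT/2 on average) is redistributed over
#' the complex's `3(M+N-1)` internal modes, raising the energy per mode from
#' kT/2 to `(M+N) kT / (2(M+N-1))` — an effective internal temperature
#' increase by the factor `(M+N)/(M+N-1)`. For glycine (M=10) colliding with
#' alanine (N=13) the factor is 23/22 = 1.045: far too small to re-dissociate
#' the complex, which is why polyatomic hydrogen bonding proceeds as a
#' two-body process while very small molecules need a third body or a photon.
#'
#' @inheritParams internal_mode_count
#' @return dimensionless factor, strictly > 1, approaching 1 for large
#'   molecules.
#' @export
internal_temperature_factor <- function(m, n) {
  M <- if (inherits(m, "species_info")) m$atom_count else as.integer(m)
  N <- if (inherits(n, "species_info")) n$atom_count else as.integer(n)
  stopifnot(M + N >= 2)
  (M + N) / (M + N - 1)
}

#' Assess two-body sticking of a colliding pair
#'
#' Applies the internal-energy-redistribution argument: the collision
#' complex survives (sticks) when the fractional internal-temperature rise
#' is small. The dichotomy between polyatomics (stick) and very small
#' molecules (fly apart without a third body) is made operational with a
#' configurable threshold on the temperature factor.
#'
#' @inheritParams internal_mode_count
#' @param env a `cloud_environment` supplying the gas temperature.
#' @param factor_threshold sticking accepted when the temperature factor is
#'   <= this value (default 1.25).
#' @return list with `modes`, `factor`, `effective_internal_temperature_K`,
#'   and logical `two_body_sticking`.
#' @export
sticking_assessment <- function(m, n, env = cloud_environment(),
                                factor_threshold = 1.25) {
  stopifnot(inherits(env, "cloud_environment"), factor_threshold > 1)
  f <- internal_temperature_factor(m, n)
  list(
    modes = internal_mode_count(m, n),
    factor = f,
    effective_internal_temperature_K = env$temperature * f,
    two_body_sticking = f <= factor_threshold
  )
}
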
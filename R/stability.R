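#' Arrhenius dissociation specification
#'
#' Parameters of the unimolecular dissociation of a bound complex in the
#' rapid-energy-exchange (thermalised) limit: `k_D = A exp(-Ea / RT)`.
#'
#' @param pre_exponential Arrhenius pre-exponential factor A, s^-1 (> 0);
#'   1e12 for tight transition states, 1e15 for loose ones.
#' @param activation_energy Ea in kJ/mol (>= 0); under the package's default
#'   convention this is the depth `|e_pair|` of the hydrogen-bonded complex.
#' @param temperature K (> 0).
#' @return an object of class `dissociation_spec`.
#' @examples
#' dissociation_spec(1e12, 60, 100)
#' @export
dissociation_spec <- function(pre_exponential, activation_energy,
                              temperature) {
  if (!is.numeric(pre_exponential) || pre_exponential <= 0)
    stop("pre_exponential must be positive (s^-1)")
  if (!is.numeric(activation_energy) || activation_energy < 0)
    stop("activation_energy must be >= 0 (kJ/mol)")
  if (!is.numeric(temperature) || temperature <= 0)
    stop("temperature must be positive (K)")
  structure(
    list(pre_exponential = pre_exponential,
         activation_energy = activation_energy,
         temperature = temperature),
    class = "dissociation_spec"
  )
}

#' @export
print.dissociation_spec <- function(x, ...) {
  cat(sprintf(
    "<dissociation> A = %.3g s^-1, Ea = %g kJ/mol, T = %g K -> k_D = %.3g s^-1\n",
    x$pre_exponential, x$activation_energy, x$temperature,
    arrhenius_rate(x)))
  invisible(x)
}

#' Unimolecular dissociation rate constant
#'
#' `k_D = A exp(-Ea / RT)` with Ea in molar units (kJ/mol) and
#' R = 8.314462618 J mol^-1 K^-1. At Ea = 60 kJ/mol and 100 K the exponent
#' is ~ -72, so rates near 1e-20 s^-1 are routine; the exponent is evaluated
#' in log space by [log_arrhenius_rate()] where downstream arithmetic needs
#' it.
#'
#' @param spec a [dissociation_spec()].
#' @return s^-1; strictly increasing in A and T, decreasing in Ea.
#' @export
arrhenius_rate <- function(spec) {
  exp(log_arrhenius_rate(spec))
}

#' @rdname arrhenius_rate
#' @return `log_arrhenius_rate`: the natural log of the rate (does not
#'   underflow for deep wells).
#' @export
log_arrhenius_rate <- function(spec) {
  stopifnot(inherits(spec, "dissociation_spec"))
  log(spec$pre_exponential) -
    spec$activation_energy * 1000 /
      (cloud_constants$r_gas * spec$temperature)
}

#' Lifetime of the bound complex against thermal dissociation
#'
#' `1 / k_D` in Julian years. A 60 kJ/mol hydrogen-bond well at 100 K holds
#' the complex together for >= 1e6 yr for any pre-exponential factor in the
#' 1e12-1e15 s^-1 range (the loose-limit worst case evaluates to ~7e8 yr).
#'
#' @param spec a [dissociation_spec()].
#' @return years.
#' @export
complex_lifetime <- function(spec) {
  convert_time(exp(-log_arrhenius_rate(spec)), "s", "yr")
}

#' Equilibrium dimer-to-monomer ratio
#'
#' When complex formation (`k2 * n`) balances thermal dissociation (`k_D`),
#' the ratio of complexed to free monomers is `k2 * n / k_D`. With the amide
#' defaults (Ea = 60 kJ/mol, 100 K, n = 1 cm^-3) this spans ~3e5 (loose,
#' A = 1e15) to ~3e8 (tight, A = 1e12): the monomer is overwhelmingly locked
#' up in the hydrogen-bonded complex. The weaker ethylene glycol well
#' (40 kJ/mol) gives 0.015 down to 1.5e-5 under the same conditions.
#'
#' @param n_species free-monomer density, cm^-3 (>= 0).
#' @param params [kinetic_parameters()] supplying k2.
#' @param spec [dissociation_spec()] for the complex.
#' @return dimensionless ratio; linear in `n_species`, decreasing in A.
#' @export
equilibrium_dimer_ratio <- function(n_species, params = kinetic_parameters(),
                                    spec) {
  stopifnot(inherits(params, "kinetic_parameters"),
            is.numeric(n_species), all(n_species >= 0))
  # carried in log space: k_D can be ~1e-40 s^-1 for deep wells
  exp(log(params$k2) + log(n_species) - log_arrhenius_rate(spec))
}

#' Feasibility of peptide-bond formation for one profile
#'
#' Combines the pieces of the kinetic argument for a single reaction profile
#' in a given cloud: the barrier class (condensation proceeds out of the
#' hydrogen-bonded complex only past a low barrier), the equilibrium
#' complex-to-monomer ratio at both ends of the pre-exponential range with
#' Ea = |e_pair|, and whether the product is stabilised by its retained
#' water of condensation.
#'
#' @param profile a `reaction_profile`.
#' @param env a `cloud_environment`.
#' @param params [kinetic_parameters()].
#' @param threshold barrier classification threshold, kJ/mol.
#' @return list with `pair`, `conformer`, `barrier_class`,
#'   `ratio_at_a_low`, `ratio_at_a_high` (a_low gives the larger ratio),
#'   `proceeds_to_bond`, `stabilized_by_water`.
#' @export
feasibility_report <- function(profile, env = cloud_environment(),
                               params = kinetic_parameters(),
                               threshold = barrier_threshold_default()) {
  stopifnot(inherits(profile, "reaction_profile"),
            inherits(env, "cloud_environment"))
  n <- species_density(env)
  ea <- abs(binding_energy(profile))
  ratio_at <- function(a) {
    equilibrium_dimer_ratio(
      n, params, dissociation_spec(a, ea, env$temperature))
  }
  cls <- classify_barrier(profile, threshold)
  list(
    pair = paste(profile$pair, collapse = "-"),
    conformer = profile$conformer,
    barrier_class = cls,
    ratio_at_a_low = ratio_at(params$a_low),
    ratio_at_a_high = ratio_at(params$a_high),
    # a surmountable barrier is not enough: the product (with its bound
    # water) must itself be bound, or the bond does not form
    proceeds_to_bond = cls == "low" && profile$e_product_bound_water < 0,
    stabilized_by_water = !is.na(profile$e_product_free_water) &&
      water_removal_energy(profile) > 0
  )
}

#' Kinetics report over a whole profile library
#'
#' One row per profile: the [feasibility_report()] fields plus the
#' environment's collision timescale, complex lifetime range and UV survival
#' probability, i.e. the full desk-scale kinetic summary.
#'
#' @param lib a `profile_library`.
#' @inheritParams feasibility_report
#' @return a data.frame with columns `pair`, `conformer`, `barrier_class`,
#'   `ratio_at_A12`, `ratio_at_A15`, `proceeds`, `stabilized_by_water`,
#'   `collision_timescale_yr`, `lifetime_low_yr`, `lifetime_high_yr`,
#'   `survival_probability`.
#' @export
kinetics_report <- function(lib, env = cloud_environment(),
                            params = kinetic_parameters(),
                            threshold = barrier_threshold_default()) {
  stopifnot(inherits(lib, "profile_library"))
  n <- species_density(env)
  t_coll <- collision_timescale(n, params)
  k_coll <- collision_rate(n, params)
  k_uv <- if (env$uv_class == "none") 0 else
    photolysis_rate(uv_environment(env$uv_class))
  p_survive <- if (k_coll == 0 && k_uv == 0) NA_real_ else
    dimerize_before_destruction(k_coll, k_uv)
  rows <- lapply(lib$profiles, function(p) {
    fr <- feasibility_report(p, env, params, threshold)
    ea <- abs(binding_energy(p))
    data.frame(
      pair = fr$pair, conformer = fr$conformer,
      barrier_class = fr$barrier_class,
      ratio_at_A12 = equilibrium_dimer_ratio(
        n, params, dissociation_spec(params$a_low, ea, env$temperature)),
      ratio_at_A15 = equilibrium_dimer_ratio(
        n, params, dissociation_spec(params$a_high, ea, env$temperature)),
      proceeds = fr$proceeds_to_bond,
      stabilized_by_water = fr$stabilized_by_water,
      collision_timescale_yr = t_coll,
      lifetime_low_yr = complex_lifetime(
        dissociation_spec(params$a_high, ea, env$temperature)),
      lifetime_high_yr = complex_lifetime(
        dissociation_spec(params$a_low, ea, env$temperature)),
      survival_probability = p_survive,
      stringsAsFactors = FALSE
    )
  })
  if (!length(rows)) {
    return(data.frame(
      pair = character(), conformer = integer(), barrier_class = character(),
      ratio_at_A12 = numeric(), ratio_at_A15 = numeric(),
      proceeds = logical(), stabilized_by_water = logical(),
      collision_timescale_yr = numeric(), lifetime_low_yr = numeric(),
      lifetime_high_yr = numeric(), survival_probability = numeric(),
      stringsAsFactors = FALSE
    ))
  }
  do.call(rbind, rows)
}
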
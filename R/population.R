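#' Build a polymerization reaction network
#'
#' Assembles the deterministic rate-equation network for growth from free
#' monomers to n-mers in a cloud. Species are the monomer and bound n-mers
#' up to `max_length`; every bound species forms bimolecularly (coefficient
#' `k2`) and dissociates unimolecularly at the Arrhenius rate with
#' activation energy `|e_pair|` of the governing profile. The transition
#' state acts as a gate: growth past the hydrogen-bonded dimer complex is
#' only possible when the profile's barrier class is low (a high barrier
#' stalls the system at the complex). A separate dimer + dimer channel to
#' the tetramer can be enabled by a second profile — the route by which
#' high-barrier pairs such as Gly-Gly reach longer polymers, since the
#' barrier drops when a bond forms between two dimers.
#'
#' Water of condensation is bookkept as bound: it travels with the growing
#' polymer and is not tracked as a free species.
#'
#' @param profile the `reaction_profile` governing monomer addition, or a
#'   `profile_library` (non-empty) whose first profile — or the profile
#'   selected by `pair` — is used.
#' @param env a `cloud_environment`.
#' @param params [kinetic_parameters()].
#' @param max_length maximum polymer length L (>= 2).
#' @param pre_exponential Arrhenius A for dissociation, s^-1; defaults to
#'   `params$a_low` (tight transition states, the slow-dissociation end).
#' @param dimer_dimer optional `reaction_profile` for the dimer + dimer ->
#'   tetramer step (requires `max_length >= 4`); the channel opens when its
#'   barrier class is low.
#' @param pair optional `c(name, name)` selecting a profile from a library.
#' @param include_photolysis apply the environment's UV class as a
#'   first-order loss on free monomers (default `FALSE`; `uv_class =
#'   "none"` always means no photolysis).
#' @param threshold barrier classification threshold, kJ/mol.
#' @return an object of class `reaction_network`: species table (name,
#'   length), edge table (reactant indices, product index, `kf` cm^3 s^-1,
#'   `kr` s^-1), monomer photolysis rate, and the resolved configuration.
#' @export
build_network <- function(profile, env = cloud_environment(),
                          params = kinetic_parameters(),
                          max_length = 2L,
                          pre_exponential = NULL,
                          dimer_dimer = NULL,
                          pair = NULL,
                          include_photolysis = FALSE,
                          threshold = barrier_threshold_default()) {
  if (inherits(profile, "profile_library")) {
    if (!length(profile$profiles))
      stop("cannot build a network from an empty profile library")
    if (!is.null(pair)) {
      hit <- Filter(function(p) all(p$pair == pair), profile$profiles)
      if (!length(hit))
        stop("no profile for pair ", paste(pair, collapse = "-"),
             " in library")
      profile <- hit[[1]]
    } else {
      profile <- profile$profiles[[1]]
    }
  }
  stopifnot(inherits(profile, "reaction_profile"),
            inherits(env, "cloud_environment"),
            inherits(params, "kinetic_parameters"))
  max_length <- as.integer(max_length)
  if (max_length < 2L) stop("max_length must be >= 2")
  if (is.null(pre_exponential)) pre_exponential <- params$a_low

  kd_for <- function(p) {
    arrhenius_rate(dissociation_spec(pre_exponential, abs(binding_energy(p)),
                                     env$temperature))
  }
  gate_open <- classify_barrier(profile, threshold) == "low"

  lengths <- seq_len(max_length)
  species <- data.frame(
    name = ifelse(lengths == 1L, "monomer",
                  ifelse(lengths == 2L & !gate_open, "complex_2",
                         paste0("n", lengths))),
    length = lengths,
    stringsAsFactors = FALSE
  )

  edges <- data.frame(r1 = integer(), r2 = integer(), product = integer(),
                      kf = numeric(), kr = numeric())
  # monomer + monomer -> dimer: the hydrogen-bonded complex always forms;
  # whether it is a stalled complex or a covalent dimer is the gate's affair
  edges <- rbind(edges, data.frame(r1 = 1L, r2 = 1L, product = 2L,
                                   kf = params$k2, kr = kd_for(profile)))
  if (gate_open && max_length > 2L) {
    for (i in 2:(max_length - 1L)) {
      edges <- rbind(edges, data.frame(r1 = 1L, r2 = i, product = i + 1L,
                                       kf = params$k2, kr = kd_for(profile)))
    }
  }
  dd_open <- FALSE
  if (!is.null(dimer_dimer)) {
    stopifnot(inherits(dimer_dimer, "reaction_profile"))
    if (max_length < 4L)
      stop("dimer + dimer channel needs max_length >= 4")
    dd_open <- classify_barrier(dimer_dimer, threshold) == "low"
    if (dd_open) {
      edges <- rbind(edges, data.frame(r1 = 2L, r2 = 2L, product = 4L,
                                       kf = params$k2,
                                       kr = kd_for(dimer_dimer)))
    }
  }

  kp <- 0
  if (include_photolysis && env$uv_class != "none")
    kp <- photolysis_rate(uv_environment(env$uv_class))

  structure(
    list(species = species, edges = edges, photolysis = kp,
         config = list(
           pair = paste(profile$pair, collapse = "-"),
           conformer = profile$conformer,
           gate_open = gate_open,
           dimer_dimer_open = dd_open,
           max_length = max_length,
           k2 = params$k2,
           pre_exponential = pre_exponential,
           activation_energy = abs(binding_energy(profile)),
           temperature = env$temperature,
           photolysis_rate = kp
         )),
    class = "reaction_network"
  )
}

#' @export
print.reaction_network <- function(x, ...) {
  cat(sprintf(
    "<reaction network> %s, L = %d, %d species, %d reaction(s)%s%s\n",
    x$config$pair, x$config$max_length, nrow(x$species), nrow(x$edges),
    if (x$config$gate_open) ", condensation gate open"
    else ", stalled at H-bonded complex",
    if (x$config$dimer_dimer_open) ", dimer+dimer channel open" else ""))
  invisible(x)
}

#' Initial population state for a network
#'
#' @param network a `reaction_network`.
#' @param monomer initial free-monomer density, cm^-3.
#' @return named numeric vector of densities, all mass in the monomer
#'   unless other entries are set by name afterwards.
#' @export
population_state <- function(network, monomer = 1) {
  stopifnot(inherits(network, "reaction_network"), monomer >= 0)
  y <- stats::setNames(numeric(nrow(network$species)), network$species$name)
  y["monomer"] <- monomer
  y
}

network_derivs <- function(t, y, net) {
  dy <- numeric(length(y))
  e <- net$edges
  for (k in seq_len(nrow(e))) {
    flux <- e$kf[k] * y[e$r1[k]] * y[e$r2[k]] - e$kr[k] * y[e$product[k]]
    dy[e$r1[k]] <- dy[e$r1[k]] - flux
    dy[e$r2[k]] <- dy[e$r2[k]] - flux
    dy[e$product[k]] <- dy[e$product[k]] + flux
  }
  if (net$photolysis > 0) dy[1] <- dy[1] - net$photolysis * y[1]
  list(dy)
}

#' Integrate the rate equations
#'
#' Stiff-capable integration (deSolve, `lsoda`) of the network's
#' deterministic rate equations. Dissociation rates for deep hydrogen-bond
#' wells at 100 K sit near 1e-20 s^-1 while formation rates are ~1e-11
#' s^-1, so output is requested on a logarithmic time grid and tolerances
#' default tight (`rtol` 1e-8). Densities that round off slightly negative
#' at the solver tolerance are clipped to zero in the returned trajectory.
#'
#' @param network a `reaction_network`.
#' @param initial named density vector from [population_state()].
#' @param t_end end time, s (> 0).
#' @param rel_tol,abs_tol solver tolerances (defaults 1e-8 and 1e-25
#'   cm^-3).
#' @param n_out number of output times (log-spaced from `t_end * 1e-12`,
#'   plus t = 0).
#' @param times explicit output time grid (s), overriding `n_out`.
#' @return a `trajectory`: data.frame-convertible object with `time_s` and
#'   one density column per species.
#' @export
simulate_network <- function(network, initial = population_state(network),
                             t_end, rel_tol = 1e-8, abs_tol = 1e-25,
                             n_out = 200L, times = NULL) {
  stopifnot(inherits(network, "reaction_network"), t_end > 0,
            all(initial >= 0), length(initial) == nrow(network$species))
  if (is.null(times)) {
    times <- c(0, 10^seq(log10(t_end) - 12, log10(t_end),
                         length.out = n_out))
  }
  sol <- deSolve::ode(
    y = initial, times = times, func = network_derivs, parms = network,
    method = "lsoda", rtol = rel_tol, atol = abs_tol
  )
  if (attr(sol, "istate")[1] < 0)
    stop("ODE integration failed near t = ",
         format(sol[nrow(sol), 1], digits = 4), " s")
  dens <- pmax(unclass(sol)[, -1, drop = FALSE], 0)
  structure(
    list(time_s = sol[, 1], densities = dens,
         species = network$species, network = network),
    class = "trajectory"
  )
}

#' @export
as.data.frame.trajectory <- function(x, ...) {
  data.frame(time_s = x$time_s, x$densities, check.names = FALSE)
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d times to %.3g s, species: %s\n",
              length(x$time_s), max(x$time_s),
              paste(x$species$name, collapse = ", ")))
  invisible(x)
}

#' Total monomer-equivalent density of a trajectory
#'
#' Sum over species of density times polymer length; conserved (to solver
#' tolerance) when photolysis is off.
#'
#' @param traj a `trajectory`.
#' @return numeric vector, one value per output time.
#' @export
monomer_equivalents <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  as.numeric(traj$densities %*% traj$species$length)
}

#' Analytic steady state of a network
#'
#' The network's formation edges form a tree (every bound species has one
#' formation route), so at steady state every edge balances individually:
#' `n_product = kf * n_r1 * n_r2 / kr`. Densities are therefore determined
#' by the free-monomer density alone, which is found by root-finding on the
#' monomer-equivalent conservation constraint. For the two-species network
#' this reduces to the closed-form complex-to-monomer ratio
#' `k2 * n_monomer / k_D`.
#'
#' Requires photolysis off (an open system has no conserved total). If any
#' enabled formation edge has zero dissociation there is no finite
#' equilibrium: the result then carries `finite = FALSE` with `NA`
#' densities (a sentinel, not an error).
#'
#' @param network a `reaction_network`.
#' @param total_monomer total monomer-equivalent density, cm^-3 (> 0).
#' @return list with `densities` (named vector), `monomer`, `finite`.
#' @export
steady_state <- function(network, total_monomer = 1) {
  stopifnot(inherits(network, "reaction_network"), total_monomer > 0)
  if (network$photolysis > 0)
    stop("steady state is defined for the closed network (photolysis off)")
  e <- network$edges
  active <- e[e$kf > 0, , drop = FALSE]
  if (anyDuplicated(active$product))
    stop("steady state requires a single formation route per species; ",
         "this network has a cycle (use simulate_network instead)")
  if (nrow(active) && any(active$kr == 0)) {
    return(list(
      densities = stats::setNames(rep(NA_real_, nrow(network$species)),
                                  network$species$name),
      monomer = NA_real_, finite = FALSE
    ))
  }
  lens <- network$species$length
  densities_at <- function(n1) {
    y <- numeric(nrow(network$species))
    y[1] <- n1
    # formation edges are ordered so reactants precede products
    for (k in seq_len(nrow(e))) {
      if (e$kf[k] > 0)
        y[e$product[k]] <- e$kf[k] * y[e$r1[k]] * y[e$r2[k]] / e$kr[k]
    }
    y
  }
  excess <- function(log_n1) sum(densities_at(exp(log_n1)) * lens) -
    total_monomer
  lo <- log(total_monomer) - 400
  hi <- log(total_monomer)
  if (excess(hi) <= 0) {
    # no bound species can hold mass; all of it stays in the monomer
    y <- densities_at(total_monomer)
  } else {
    root <- stats::uniroot(excess, c(lo, hi), tol = 1e-14)
    y <- densities_at(exp(root$root))
  }
  list(
    densities = stats::setNames(y, network$species$name),
    monomer = y[1], finite = TRUE
  )
}

#' Write a trajectory and its provenance to disk
#'
#' Emits `<stem>.csv` (`time_s` plus one column per species) and
#' `<stem>.json` echoing the resolved network configuration, so a run can
#' be re-executed bit-identically.
#'
#' @param traj a `trajectory`.
#' @param stem output path without extension.
#' @return character vector of the two paths written, invisibly.
#' @export
write_trajectory <- function(traj, stem) {
  stopifnot(inherits(traj, "trajectory"))
  csv <- paste0(stem, ".csv")
  cfg <- paste0(stem, ".json")
  utils::write.csv(as.data.frame(traj), csv, row.names = FALSE)
  jsonlite::write_json(
    c(traj$network$config,
      list(package_version = as.character(utils::packageVersion("cloudamide")))),
    cfg, auto_unbox = TRUE, digits = NA)
  invisible(c(csv, cfg))
}
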
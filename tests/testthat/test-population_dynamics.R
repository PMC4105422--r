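# independent closed-form oracle for the 2-species network:
# k2 n^2 = kD d with n + 2d = total  =>  quadratic in n
two_species_equilibrium <- function(k2, kd, total) {
  n <- (-kd + sqrt(kd^2 + 8 * k2 * kd * total)) / (4 * k2)
  c(monomer = n, dimer = (total - n) / 2)
}

# end time long enough to relax onto the equilibrium
relaxation_t_end <- function(k2, kd, total) {
  n_eq <- two_species_equilibrium(k2, kd, total)[1]
  30 / (4 * k2 * n_eq + kd) + 1 / (2 * k2 * n_eq)
}

test_that("network construction encodes gates and channels", {
  lib <- cloudamide_profiles()
  env <- default_cloud()

  net <- build_network(find_profile(lib, c("Glu", "Ala")), env)
  expect_equal(nrow(net$species), 2)
  expect_equal(nrow(net$edges), 1)
  expect_gt(net$edges$kf, 0)
  expect_gt(net$edges$kr, 0)
  expect_true(net$config$gate_open)

  stall <- build_network(find_profile(lib, c("Gly", "Gly")), env,
                         max_length = 3)
  expect_false(stall$config$gate_open)
  # growth past the complex is gated off: only the dimerization edge
  expect_equal(nrow(stall$edges), 1)
  expect_identical(stall$species$name[2], "complex_2")

  over <- build_network(find_profile(lib, c("Gly", "Gly")), env,
                        max_length = 4,
                        dimer_dimer = find_profile(lib,
                                                   c("Gly-Gly", "Gly-Ala")))
  expect_true(over$config$dimer_dimer_open)
  expect_equal(nrow(over$edges), 2)
  expect_equal(over$edges$product[2], 4)

  expect_error(build_network(profile_library(list(), list()), env), "empty")
  expect_error(build_network(find_profile(lib, c("Gly", "Gly")), env,
                             max_length = 2,
                             dimer_dimer = find_profile(
                               lib, c("Gly-Gly", "Gly-Ala"))),
               "max_length")
  # selecting a profile from the library by pair
  byname <- build_network(lib, env, pair = c("Asn", "Pro"))
  expect_identical(byname$config$pair, "Asn-Pro")
})

test_that("degenerate networks behave trivially", {
  lib <- cloudamide_profiles()
  net <- build_network(find_profile(lib, c("Glu", "Ala")), default_cloud())
  # all rates zero: densities constant
  frozen <- net
  frozen$edges$kf <- 0
  frozen$edges$kr <- 0
  y0 <- population_state(frozen, monomer = 0.7)
  y0["n2"] <- 0.1
  tr <- simulate_network(frozen, y0, t_end = 1e15)
  expect_true(all(abs(tr$densities[, "monomer"] - 0.7) < 1e-12))
  expect_true(all(abs(tr$densities[, "n2"] - 0.1) < 1e-12))

  # photolysis only: exponential decay at the photolysis rate
  dism <- build_network(find_profile(lib, c("Glu", "Ala")),
                        cloud_environment(100, 1e7, 1e-7, "DISM"),
                        include_photolysis = TRUE)
  dism$edges$kf <- 0
  dism$edges$kr <- 0
  kp <- photolysis_rate(uv_environment("DISM"))
  t_half <- convert_time(300, "yr", "s")
  tr <- simulate_network(dism, t_end = 2 * t_half,
                         times = c(0, t_half, 2 * t_half))
  expect_equal(unname(tr$densities[, "monomer"]), c(1, 0.5, 0.25),
               tolerance = 1e-6)
})

test_that("two-species ODE relaxes onto the analytic equilibrium", {
  lib <- cloudamide_profiles()
  env <- default_cloud()
  net <- build_network(find_profile(lib, c("Glu", "Ala")), env,
                       kinetic_parameters(), pre_exponential = 1e12)
  k2 <- net$edges$kf[1]; kd <- net$edges$kr[1]
  oracle <- two_species_equilibrium(k2, kd, 1)

  tr <- simulate_network(net, t_end = relaxation_t_end(k2, kd, 1))
  last <- tr$densities[nrow(tr$densities), ]
  expect_equal(unname(last["monomer"]), unname(oracle["monomer"]),
               tolerance = 1e-4)

  # the terminal ratio agrees with the closed-form k2 n / kD at the
  # terminal free-monomer density to within 1%
  ratio_ode <- last["n2"] / last["monomer"]
  ratio_closed <- equilibrium_dimer_ratio(
    last["monomer"], kinetic_parameters(),
    dissociation_spec(1e12, net$config$activation_energy, 100))
  expect_equal(unname(ratio_ode / ratio_closed), 1, tolerance = 0.01)

  # algebraic steady state matches the independent quadratic oracle
  ss <- steady_state(net, 1)
  expect_true(ss$finite)
  expect_equal(unname(ss$densities["monomer"]), unname(oracle["monomer"]),
               tolerance = 1e-9)
  expect_equal(unname(ss$densities["n2"]), unname(oracle["dimer"]),
               tolerance = 1e-9)
})

test_that("ODE matches the closed form across randomized cloud conditions", {
  set.seed(19)
  for (i in 1:6) {
    ea <- runif(1, 30, 90)
    A <- 10^runif(1, 12, 15)
    T0 <- runif(1, 100, 200)
    total <- 10^runif(1, -1, 1)
    params <- kinetic_parameters()
    env <- cloud_environment(T0, 1e7, 1e-7, "none")
    prof <- make_profile(e_pair = -ea, e_ts = 0)
    net <- build_network(prof, env, params, pre_exponential = A)
    k2 <- net$edges$kf[1]; kd <- net$edges$kr[1]
    oracle <- two_species_equilibrium(k2, kd, total)
    tr <- simulate_network(net, population_state(net, total),
                           t_end = relaxation_t_end(k2, kd, total))
    last <- tr$densities[nrow(tr$densities), ]
    expect_equal(unname(last["n2"] / last["monomer"]),
                 unname(oracle["dimer"] / oracle["monomer"]),
                 tolerance = 0.01)
  }
})

test_that("mass is conserved and dimer growth is monotone without photolysis", {
  lib <- cloudamide_profiles()
  net <- build_network(find_profile(lib, c("Glu", "Ala")), default_cloud())
  k2 <- net$edges$kf[1]; kd <- net$edges$kr[1]
  tr <- simulate_network(net, t_end = relaxation_t_end(k2, kd, 1))
  me <- monomer_equivalents(tr)
  expect_lt(max(abs(me - me[1])) / me[1], 1e-6)
  expect_true(all(tr$densities >= 0))
  dimer <- tr$densities[, "n2"]
  expect_true(all(diff(dimer) > -1e-12))
})

test_that("steady state handles stalls, overrides, and sentinels", {
  lib <- cloudamide_profiles()
  env <- default_cloud()

  # formation switched off: all mass stays in the monomer
  net <- build_network(find_profile(lib, c("Glu", "Ala")), env)
  off <- net; off$edges$kf <- 0
  ss <- steady_state(off, 1)
  expect_equal(unname(ss$densities["monomer"]), 1)
  expect_equal(unname(ss$densities["n2"]), 0)

  # no dissociation channel: no finite equilibrium (sentinel, not error)
  irrev <- net; irrev$edges$kr <- 0
  ss_irrev <- steady_state(irrev, 1)
  expect_false(ss_irrev$finite)
  expect_true(all(is.na(ss_irrev$densities)))

  # glycol: only a trace of molecules are dimerized at equilibrium
  eg <- build_network(find_profile(lib, c("EG", "EG")), env,
                      pre_exponential = 1e12)
  ss_eg <- steady_state(eg, 1)
  frac <- ss_eg$densities[2] / (ss_eg$densities[1] + ss_eg$densities[2])
  ratio_cap <- equilibrium_dimer_ratio(
    1, kinetic_parameters(), dissociation_spec(1e12, 40, 100))
  expect_lte(unname(frac), ratio_cap / (1 + ratio_cap))
  expect_equal(unname(frac), 0.015 / 1.015, tolerance = 0.1)

  # dimer+dimer override: tetramer carries the mass, trimer stays empty
  over <- build_network(find_profile(lib, c("Gly", "Gly")), env,
                        max_length = 4,
                        dimer_dimer = find_profile(lib,
                                                   c("Gly-Gly", "Gly-Ala")))
  ss_over <- steady_state(over, 1)
  expect_gt(unname(ss_over$densities["n4"]), 0.2)
  expect_equal(unname(ss_over$densities["n3"]), 0)
  expect_equal(sum(ss_over$densities * over$species$length), 1,
               tolerance = 1e-9)

  expect_error(steady_state(build_network(
    find_profile(lib, c("Glu", "Ala")), cloud_environment(100, 1e7, 1e-7, "DC"),
    include_photolysis = TRUE), 1), "photolysis")
})

test_that("trajectories serialize with their provenance", {
  lib <- cloudamide_profiles()
  net <- build_network(find_profile(lib, c("Glu", "Ala")), default_cloud())
  tr <- simulate_network(net, t_end = 1e10, n_out = 20)
  stem <- file.path(withr::local_tempdir(), "run")
  paths <- write_trajectory(tr, stem)
  df <- utils::read.csv(paste0(stem, ".csv"), check.names = FALSE)
  expect_named(df, c("time_s", "monomer", "n2"))
  expect_equal(nrow(df), length(tr$time_s))
  cfg <- jsonlite::fromJSON(paste0(stem, ".json"))
  expect_identical(cfg$pair, "Glu-Ala")
  expect_equal(cfg$k2, 2e-11)
})
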
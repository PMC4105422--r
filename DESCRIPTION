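Package: cloudamide
Title: Gas-Phase Amino Acid Polymerization Kinetics in Warm Dense Molecular Clouds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Kinetic model of gas-phase peptide-bond formation in warm dense
    molecular clouds (~1e7-1e8 H2 cm-3, >=100 K). Provides a data model and
    packaged library of five-state condensation-reaction energy profiles
    (separated monomers, hydrogen-bonded pair, transition state, dipeptide
    with bound water of condensation, dipeptide with water removed),
    collision-complex formation rates and timescales, an internal-energy
    redistribution (sticking) criterion for polyatomic collisions, Arrhenius
    dissociation of the hydrogen-bonded complex and the resulting equilibrium
    dimer-to-monomer ratio, ultraviolet photodestruction competition, a
    deterministic rate-equation network for growth to n-mers with an analytic
    steady-state oracle, and seeded synthetic generators for profiles and
    cloud environments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
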
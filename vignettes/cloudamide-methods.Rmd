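---
title: "Kinetics of gas-phase peptide-bond formation in warm dense clouds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetics of gas-phase peptide-bond formation in warm dense clouds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cloudamide)
```

## The model

`cloudamide` models the fate of amino acid monomers in the interior of a
warm dense molecular cloud (~10^7^–10^8^ H~2~ cm^-3^, ≥ 100 K): whether two
monomers that collide form a hydrogen-bonded complex, whether that complex
survives long enough to pass over the transition state into a covalent
dipeptide, and how the population partitions between monomers, complexes
and longer n-mers over time. Ethylene glycol is carried through the same
machinery as a negative control.

The energetics enter through **five-state reaction profiles**: energies in
kJ/mol, relative to the separated reactants (state 1 ≡ 0), of the
hydrogen-bonded pair in proximity (state 2, `e_pair`), the transition state
(state 3, `e_ts`), the dipeptide with its water of condensation still
hydrogen-bonded (state 4), and the dipeptide with that water removed to
infinity (state 5). These are ab initio quantities that the package does
*not* compute; they are data. The packaged library anchors them to stated
typical values and ranges — pair binding between −25 and −100 kJ/mol
(typical −60), bound-water product near −50 kJ/mol, water removal near
+200 kJ/mol, the Gly-Gly barrier at 200 kJ/mol, ethylene glycol at
−40/290 kJ/mol — and flags every profile `approximate`, because per-pair
decimals are not published as a table. Tests and analyses therefore assert
ranges and classifications, never per-pair decimals.

The kinetic chain is:

1. **Collision-complex formation.** Per monomer, complexes form at
   $k_2 n$ with $k_2 = \sigma\bar v \approx 2\times10^{-11}$ cm^3^ s^-1^ at
   100 K. At the canonical fractional abundance 10^-7^ in a 10^7^ cm^-3^
   cloud ($n = 1$ cm^-3^) the collision timescale is
   $1/(k_2 n) \approx 1.6\times10^3$ yr.
2. **Sticking.** The relative kinetic energy (3kT/2) redistributes over the
   complex's $3(M+N-1)$ internal modes, raising the internal temperature by
   $(M+N)/(M+N-1)$ — 23/22 = 1.045 for glycine (M = 10) + alanine (N = 13).
   Because this excess is tiny for polyatomics, complex formation is a
   two-body process; very small molecules (factor 4/3 for two diatomics)
   would fly apart. The package makes the dichotomy operational with a
   threshold on the factor, default 1.25: comfortably above every
   amino-acid pairing (≤ 6/5 already for water–water) and below the
   diatomic 4/3. No published numeric cutoff exists; the value is a package
   choice.
3. **Thermal dissociation.** In the thermalised limit the complex
   dissociates at $k_D = A\,e^{-E_a/RT}$, with $A$ between 10^12^ s^-1^
   (tight) and 10^15^ s^-1^ (loose) and $E_a = |e_\mathrm{pair}|$ — the
   association depth is the only consistent reading of the dimer-ratio
   arithmetic. At $E_a = 60$ kJ/mol and 100 K, $k_D \le 4.6\times10^{-17}$
   s^-1^: lifetimes of 7×10^8^ yr or more, comfortably past the 10^6^-yr
   benchmark.
4. **Equilibrium.** Balancing formation against dissociation gives the
   dimer/monomer ratio $k_2 n / k_D$: 4.4×10^5^–4.4×10^8^ for the amide
   defaults (printed as 3×10^5^–3×10^8^; the factor ≈ 1.5 is rounding in
   the source values, so the package tests these endpoints at one order of
   magnitude and does not chase the printed digits), and 1.6×10^-2^ down to
   1.6×10^-5^ for ethylene glycol's 40 kJ/mol well (within 5% of the
   quoted 0.015 and 1.5×10^-5^, tested at 10%).
5. **The transition-state gate.** Condensation proceeds out of the complex
   when the barrier is at or below ~0.6 eV (57.9 kJ/mol, at 96.485 kJ/mol
   per eV), the typical association energy. The comparison is inclusive
   ("less than or of the same order") and, matching the convention under
   which the pair lists are quoted, measured from the separated-monomer
   zero; `barrier_height()` exposes the bound-pair reference too, since the
   physical escape is from state 2. Four packaged pairs (Glu-Ala, Asp-Ile,
   Ser-Leu, Asn-Pro) classify low; Lys-Phe, Phe-Gly, Ala-Ala, Gly-Gly and
   Ala-Gly classify high. A low barrier is necessary but not sufficient:
   `feasibility_report()` additionally requires the state-4 product to be
   bound ($e_4 < 0$), because the zero-barrier ethylene glycol conformers
   have no bound product and form no bond at all.
6. **UV competition.** Free monomers are photolysed with half-lives of
   300 yr (diffuse medium) or 3×10^7^ yr (dark cloud); these are packaged
   constants, converted to first-order rates with the ln 2 factor (the
   half-life reading; a 1/e-lifetime reading would differ by exactly that
   factor, which is why the convention is centralised in
   `photolysis_rate()`). Competing first-order channels give a dimerization
   probability $k_c/(k_c+k_p)$: > 0.999 in a dark cloud, ~0.21 in the
   diffuse medium. Peptide (as opposed to monomer) photodestruction is
   deliberately *not* modelled as a rate — only quantum efficiencies are
   available, with no photon flux — so those numbers surface in reports
   only.

## The population network

`build_network()` turns a profile plus an environment into a deterministic
rate-equation network: monomer, dimer (a stalled hydrogen-bonded complex
when the barrier is high, a covalent dimer when low), and — gate
permitting — n-mers up to `max_length`. Every bound species forms with
coefficient $k_2$ and dissociates at the Arrhenius rate with
$E_a = |e_\mathrm{pair}|$; n-mers inherit the dimer convention unless a
per-length override profile is supplied, because no independent n-mer
dissociation data exist. A separate dimer + dimer → tetramer channel opens
when its own profile classifies low; this is the route by which
high-barrier pairs such as Gly-Gly reach longer polymers, the barrier
dropping once a bond forms between two dimers. The passage over a low
barrier itself is treated as instantaneous relative to complex formation
(gate open/closed, no intermediate rate): no rate for that step is
published, and inventing one would dominate no observable in the model's
regime. Water of condensation travels with the polymer and is not a free
species; with photolysis off, monomer equivalents
$\sum_i i\,n_i$ are conserved exactly.

Numerics: rates in one network span ~30 decades ($k_2 n \sim 10^{-11}$
s^-1^ against $k_D \sim 10^{-20}$ s^-1^ and below), so Arrhenius exponents
are carried in log space (`log_arrhenius_rate()`) and the ODE system is
integrated with a stiff-capable solver (deSolve's `lsoda`) at a default
relative tolerance of 10^-8^, output on a logarithmic time grid. Densities
that round off marginally negative at the solver tolerance are clipped to
zero in the returned trajectory. The integration horizon in the analyses is
set from the analytic relaxation rate $4k_2 n^* + k_D$ of the two-species
system, not guessed.

`steady_state()` is the analytic oracle: the formation edges form a tree,
so each edge balances individually at equilibrium and all densities follow
from the free-monomer density, found by `uniroot` on the conservation
constraint. For two species this reduces to the closed-form ratio
$k_2 n/k_D$. Note the closed form quotes the ratio at a *fixed* monomer
density (n = 1 cm^-3^ in the headline numbers), while a closed network
depletes its monomers; the ODE tests therefore compare the terminal ratio
against $k_2 n_M(\infty)/k_D$ evaluated at the terminal monomer density,
which is the self-consistent statement of the same equilibrium. Networks
with two formation routes to the same species (a cycle) are refused by the
oracle and handled by integration only.

## The synthetic generator

`generate_profiles()` draws amide libraries with the study-condition
structure: binding uniform on [−100, −25] kJ/mol, transition states uniform
on [−50, +300] kJ/mol, the bound-water product normal around −50 (sd 15,
clipped below zero), water removal normal around +200 (sd 30, clipped
positive). Uniform and clipped-normal are the minimally informative choices
for quantities stated only as ranges or typical values; the true
distribution of barriers over amino-acid pair space is unknown, which is
exactly why the ranges are configurable. `generate_environment()` draws
H~2~ density log-uniform on [10^7^, 10^8^] cm^-3^ (densities are
scale-type), temperature uniform on [100, 200] K, fractional abundance
10^-7^. Generation is seed-parameterised, byte-reproducible, restores the
caller's RNG state, and stamps the generator identifier into the library's
metadata.

What the generator does *not* emulate: per-residue chemistry (a synthetic
"Ser-Leu" is just an energy tuple), correlations between binding depth and
barrier height, conformer multiplicity structure, or any geometry. Passing
tests on synthetic libraries therefore demonstrates that the *kinetic
machinery* is correct over the stated energy ranges — not that real
amino-acid pairs have these energies.

## Problem sizes and verification

All headline quantities are closed-form evaluations that run in
milliseconds. The ODE checks use two- to four-species networks integrated
over ~200 log-spaced output points to several relaxation times; the
distribution checks draw 10^4^ synthetic profiles. The test suite verifies
the ODE terminal state against the independent quadratic equilibrium (to
10^-4^ and, as a ratio, 1%), mass conservation to 10^-6^ relative drift,
Arrhenius monotonicity and branching-probability complementarity over
randomised parameters, JSON round trips, and the exact low/high
classification lists.

## Known limitations

- Energies are fixture data at a single level of theory with no conformer
  search; the package knowingly interpolates text-anchored values.
- The thermalised Arrhenius limit is assumed throughout — no RRKM or
  master-equation treatment, no pressure dependence.
- The 10^4^-s collisional thermalisation time and the 100× radiative
  factor are stored constants (`cloud_constants`), not derived.
- No spatial structure, no grain-surface chemistry, no accretion of other
  ices onto the growing water collective, no photon-flux-resolved peptide
  photodestruction.
- The repository is organised as an analysis workflow: the numbered
  scripts under `analysis/` are the command-line surface (profiles,
  kinetics, simulation, synthetic validation), each a thin driver over the
  exported functions, writing its tables under `results/`.
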
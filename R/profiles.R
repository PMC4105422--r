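#' Gas-phase species descriptor
#'
#' A monomer (or pre-formed oligomer) that can take part in a condensation
#' reaction: its label, atom count `M` (which sets the number of internal
#' energy modes available after a collision), and molecular mass.
#'
#' @param name species label, e.g. `"Gly"`.
#' @param atom_count integer number of atoms per molecule (>= 3 for any
#'   molecule that can hydrogen-bond; glycine has 10, alanine 13).
#' @param mass molecular mass in atomic mass units.
#' @param kind one of `"amino_acid"`, `"glycol"`, `"water"`, `"polymer"`.
#' @return an object of class `species_info`.
#' @examples
#' glycine <- species_info("Gly", 10, 75.07, "amino_acid")
#' @export
species_info <- function(name, atom_count, mass,
                         kind = c("amino_acid", "glycol", "water", "polymer")) {
  kind <- match.arg(kind)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  atom_count <- as.integer(atom_count)
  if (is.na(atom_count) || atom_count < 3L)
    stop("atom_count must be an integer >= 3 (got ", atom_count, ")")
  if (!is.numeric(mass) || mass <= 0)
    stop("mass must be positive")
  structure(
    list(name = name, atom_count = atom_count, mass = mass, kind = kind),
    class = "species_info"
  )
}

#' @export
print.species_info <- function(x, ...) {
  cat(sprintf("<species> %s (%s): %d atoms, %.2f u\n",
              x$name, x$kind, x$atom_count, x$mass))
  invisible(x)
}

#' Five-state condensation-reaction energy profile
#'
#' The energy diagram of one condensation reaction, with all energies in
#' kJ/mol relative to state 1, the sum of the separated reactant energies
#' (defined as zero):
#' state 2 = hydrogen-bonded pair in proximity (`e_pair`, negative for a
#' bound complex), state 3 = transition state (`e_ts`), state 4 = product
#' with the water of condensation still hydrogen-bonded (`e_product_bound_water`),
#' state 5 = product with the water removed to infinity
#' (`e_product_free_water`, may be `NA` when not characterised, as for the
#' glycol comparisons).
#'
#' @param pair character vector of two species names, ordered (first species
#'   donates the C-terminus).
#' @param conformer integer conformer index; `(pair, conformer)` identifies a
#'   profile uniquely within a library.
#' @param e_pair,e_ts,e_product_bound_water,e_product_free_water energies in
#'   kJ/mol relative to the separated reactants.
#' @param approximate logical; `TRUE` when the values are anchored to stated
#'   ranges/typical values rather than a per-reaction number.
#' @param kind reaction family: `"amide"` (peptide-bond condensation) or
#'   `"glycol"` (ether condensation of ethylene glycol).
#' @return an object of class `reaction_profile`.
#' @examples
#' p <- reaction_profile(c("Gly", "Gly"), 1, e_pair = -60, e_ts = 200,
#'                       e_product_bound_water = -50,
#'                       e_product_free_water = 150)
#' binding_energy(p)
#' @export
reaction_profile <- function(pair, conformer = 1L,
                             e_pair, e_ts,
                             e_product_bound_water,
                             e_product_free_water = NA_real_,
                             approximate = TRUE,
                             kind = c("amide", "glycol")) {
  kind <- match.arg(kind)
  if (length(pair) != 2L || !is.character(pair))
    stop("pair must be two species names")
  conformer <- as.integer(conformer)
  for (e in list(e_pair, e_ts, e_product_bound_water))
    if (!is.numeric(e) || length(e) != 1L || is.na(e))
      stop("states 2-4 require finite energies in kJ/mol")
  structure(
    list(
      pair = pair, conformer = conformer,
      e_pair = as.numeric(e_pair), e_ts = as.numeric(e_ts),
      e_product_bound_water = as.numeric(e_product_bound_water),
      e_product_free_water = as.numeric(e_product_free_water),
      approximate = isTRUE(approximate), kind = kind
    ),
    class = "reaction_profile"
  )
}

#' @export
print.reaction_profile <- function(x, ...) {
  cat(sprintf(
    "<reaction profile> %s-%s #%d (%s)%s\n  e2 pair %.1f | e3 ts %.1f | e4 bound-water %.1f | e5 free-water %s kJ/mol\n",
    x$pair[1], x$pair[2], x$conformer, x$kind,
    if (x$approximate) " [approximate]" else "",
    x$e_pair, x$e_ts, x$e_product_bound_water,
    if (is.na(x$e_product_free_water)) "n/a" else
      sprintf("%.1f", x$e_product_free_water)
  ))
  invisible(x)
}

profile_id <- function(p) {
  paste0(p$pair[1], "|", p$pair[2], "#", p$conformer)
}

#' Assemble a profile library
#'
#' @param profiles list of [reaction_profile()] objects.
#' @param species list of [species_info()] objects covering every name that
#'   appears in a profile pair.
#' @param validate check library invariants (see
#'   [validate_profile_library()]).
#' @return an object of class `profile_library`.
#' @export
profile_library <- function(profiles = list(), species = list(),
                            validate = TRUE) {
  stopifnot(is.list(profiles), is.list(species))
  names(species) <- vapply(species, `[[`, "", "name")
  lib <- structure(list(profiles = profiles, species = species),
                   class = "profile_library")
  if (validate) validate_profile_library(lib)
  lib
}

#' Validate a profile library against its invariants
#'
#' Checks, for every profile: both pair members resolve to known species;
#' `(pair, conformer)` is unique; the hydrogen-bonded complex is bound
#' (`e_pair < 0`); and for amide profiles with a characterised state 5,
#' removing the water of condensation costs energy
#' (`e_product_free_water > e_product_bound_water`).
#'
#' @param lib a `profile_library`.
#' @return `lib`, invisibly; errors name the offending record.
#' @export
validate_profile_library <- function(lib) {
  stopifnot(inherits(lib, "profile_library"))
  seen <- character(0)
  for (p in lib$profiles) {
    id <- profile_id(p)
    unknown <- setdiff(p$pair, names(lib$species))
    if (length(unknown))
      stop("profile ", id, ": unknown species reference: ",
           paste(unknown, collapse = ", "))
    if (id %in% seen)
      stop("duplicate profile id: ", id)
    seen <- c(seen, id)
    if (!(p$e_pair < 0))
      stop("profile ", id, ": hydrogen-bonded complex must be bound ",
           "(e_pair < 0, got ", p$e_pair, ")")
    if (p$kind == "amide" && !is.na(p$e_product_free_water) &&
        !(p$e_product_free_water > p$e_product_bound_water))
      stop("profile ", id, ": water removal must cost energy ",
           "(e_product_free_water > e_product_bound_water)")
  }
  invisible(lib)
}

#' @export
print.profile_library <- function(x, ...) {
  kinds <- vapply(x$profiles, `[[`, "", "kind")
  cat(sprintf("<profile library> %d profiles (%d amide, %d glycol), %d species\n",
              length(x$profiles), sum(kinds == "amide"),
              sum(kinds == "glycol"), length(x$species)))
  invisible(x)
}

#' @export
length.profile_library <- function(x) length(x$profiles)

#' Read a profile library from its JSON interchange format
#'
#' The format is a top-level object
#' `{"species": [...], "profiles": [...]}` where each species record has
#' fields `name`, `atom_count`, `mass_u`, `kind`, and each profile record has
#' `pair` (two names), `conformer`, `e_pair`, `e_ts`, `e4`, `e5` (number or
#' null), `approximate`. All energies kJ/mol relative to the separated
#' reactants; the state-1-zero convention is mandatory. A profile's `kind`
#' is derived from its species (`glycol` species give glycol profiles).
#'
#' @param path path to a JSON file.
#' @return a validated [profile_library()].
#' @seealso [write_profiles()], [cloudamide_profiles()] for the packaged
#'   library.
#' @export
load_profiles <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!is.list(raw) || !all(c("species", "profiles") %in% names(raw)))
    stop("profile JSON must have top-level 'species' and 'profiles' arrays")
  species <- lapply(raw$species, function(s) {
    need <- c("name", "atom_count", "mass_u", "kind")
    miss <- setdiff(need, names(s))
    if (length(miss))
      stop("species record ", deparse(s$name),
           ": missing field(s) ", paste(miss, collapse = ", "))
    species_info(s$name, s$atom_count, s$mass_u, s$kind)
  })
  names(species) <- vapply(species, `[[`, "", "name")
  profiles <- lapply(raw$profiles, function(p) {
    need <- c("pair", "conformer", "e_pair", "e_ts", "e4")
    miss <- setdiff(need, names(p))
    if (length(miss))
      stop("profile record ", paste(unlist(p$pair), collapse = "-"),
           ": missing field(s) ", paste(miss, collapse = ", "))
    pair <- as.character(unlist(p$pair))
    kinds <- vapply(pair, function(nm) {
      if (is.null(species[[nm]]))
        stop("profile ", paste(pair, collapse = "-"),
             ": unknown species reference: ", nm)
      species[[nm]]$kind
    }, "")
    kind <- if (any(kinds == "glycol")) "glycol" else "amide"
    reaction_profile(
      pair = pair, conformer = p$conformer,
      e_pair = p$e_pair, e_ts = p$e_ts,
      e_product_bound_water = p$e4,
      e_product_free_water = if (is.null(p$e5)) NA_real_ else p$e5,
      approximate = isTRUE(p$approximate), kind = kind
    )
  })
  profile_library(profiles, species)
}

#' Write a profile library to the JSON interchange format
#'
#' Inverse of [load_profiles()]: a load/write/load round trip reproduces a
#' semantically identical library.
#'
#' @param lib a `profile_library`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(lib, path) {
  stopifnot(inherits(lib, "profile_library"))
  species <- lapply(unname(lib$species), function(s) list(
    name = s$name, atom_count = s$atom_count, mass_u = s$mass, kind = s$kind
  ))
  profiles <- lapply(lib$profiles, function(p) list(
    pair = p$pair, conformer = p$conformer,
    e_pair = p$e_pair, e_ts = p$e_ts,
    e4 = p$e_product_bound_water,
    e5 = if (is.na(p$e_product_free_water)) NULL else p$e_product_free_water,
    approximate = p$approximate
  ))
  jsonlite::write_json(list(species = species, profiles = profiles), path,
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(path)
}

#' Import species from a CSV table
#'
#' Columns: `name`, `atom_count`, `mass_u`, `kind`.
#'
#' @param path CSV file path.
#' @return named list of [species_info()] objects.
#' @export
read_species_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "atom_count", "mass_u", "kind")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("species CSV missing column(s): ", paste(miss, collapse = ", "))
  species <- lapply(seq_len(nrow(df)), function(i) {
    species_info(df$name[i], df$atom_count[i], df$mass_u[i], df$kind[i])
  })
  names(species) <- df$name
  species
}

#' The packaged reaction-profile library
#'
#' Loads the library shipped with the package: 14 amide profiles over 10
#' amino-acid pairs (with repeated conformers for some pairs), 7 ethylene
#' glycol profiles, and one tetramer profile for the condensation of two
#' glycine-containing dimers. Per-profile energies are anchored to stated
#' typical values and ranges rather than per-reaction tables, and are all
#' flagged `approximate`.
#'
#' @return a `profile_library`.
#' @export
cloudamide_profiles <- function() {
  load_profiles(system.file("extdata", "reaction_profiles.json",
                            package = "cloudamide", mustWork = TRUE))
}

#' Depth of the hydrogen-bonded collision complex
#'
#' Returns the state-2 energy: how far the hydrogen-bonded pair sits below
#' the separated monomers (signed; around -60 kJ/mol for a typical amide
#' pair, -40 kJ/mol for ethylene glycol).
#'
#' @param profile a `reaction_profile`.
#' @return kJ/mol (negative for a bound complex).
#' @export
binding_energy <- function(profile) {
  stopifnot(inherits(profile, "reaction_profile"))
  profile$e_pair
}

#' Transition-state barrier of a condensation reaction
#'
#' @param profile a `reaction_profile`.
#' @param reference `"separated"` measures the barrier from the separated
#'   monomers (state 1, the convention under which pairs are classified);
#'   `"bound_pair"` measures the climb out of the hydrogen-bonded complex
#'   (state 2, the relevant height for a complex that has already formed and
#'   thermalised).
#' @return kJ/mol.
#' @export
barrier_height <- function(profile, reference = c("separated", "bound_pair")) {
  stopifnot(inherits(profile, "reaction_profile"))
  reference <- match.arg(reference)
  switch(reference,
    separated = profile$e_ts,
    bound_pair = profile$e_ts - profile$e_pair
  )
}

#' Energy to remove the water of condensation to infinity
#'
#' State 5 minus state 4: positive for every packaged amide profile
#' (typically ~200 kJ/mol), which is why gas-phase dipeptide formation is
#' only energetically viable while the water of condensation stays bound.
#'
#' @param profile a `reaction_profile`.
#' @return kJ/mol.
#' @export
water_removal_energy <- function(profile) {
  stopifnot(inherits(profile, "reaction_profile"))
  if (is.na(profile$e_product_free_water))
    stop("profile ", profile_id(profile),
         ": free-water state (state 5) not available")
  profile$e_product_free_water - profile$e_product_bound_water
}

#' Default barrier classification threshold
#'
#' 0.6 eV — the typical hydrogen-bond association energy of an amide pair —
#' expressed in kJ/mol (57.9).
#'
#' @return kJ/mol.
#' @export
barrier_threshold_default <- function() {
  convert_energy(0.6, "eV", "kJ/mol")
}

#' Classify a condensation barrier as low or high
#'
#' Condensation proceeds out of the hydrogen-bonded complex when the
#' transition state lies at or below roughly the complex association energy
#' (~0.6 eV); the comparison is inclusive and, matching the convention under
#' which pairs are listed, measured from the separated-monomer zero.
#'
#' @param profile a `reaction_profile`.
#' @param threshold classification threshold in kJ/mol (> 0); defaults to
#'   [barrier_threshold_default()].
#' @return `"low"` or `"high"`.
#' @export
classify_barrier <- function(profile, threshold = barrier_threshold_default()) {
  stopifnot(inherits(profile, "reaction_profile"),
            is.numeric(threshold), threshold > 0)
  if (barrier_height(profile, "separated") <= threshold) "low" else "high"
}

#' Tabulate a profile library
#'
#' One row per profile: identifiers, binding energy, barriers under both
#' reference conventions, water-removal energy, whether the product (with
#' bound water) is itself bound relative to the separated monomers, and the
#' low/high barrier class.
#'
#' @param lib a `profile_library`.
#' @param threshold barrier classification threshold in kJ/mol.
#' @return a data.frame.
#' @export
profile_table <- function(lib, threshold = barrier_threshold_default()) {
  stopifnot(inherits(lib, "profile_library"))
  rows <- lapply(lib$profiles, function(p) {
    data.frame(
      pair = paste(p$pair, collapse = "-"),
      conformer = p$conformer,
      kind = p$kind,
      binding_kjmol = binding_energy(p),
      barrier_separated_kjmol = barrier_height(p, "separated"),
      barrier_bound_kjmol = barrier_height(p, "bound_pair"),
      water_removal_kjmol = if (is.na(p$e_product_free_water)) NA_real_
                            else water_removal_energy(p),
      product_bound = p$e_product_bound_water < 0,
      barrier_class = classify_barrier(p, threshold),
      approximate = p$approximate,
      stringsAsFactors = FALSE
    )
  })
  if (!length(rows)) {
    return(data.frame(
      pair = character(), conformer = integer(), kind = character(),
      binding_kjmol = numeric(), barrier_separated_kjmol = numeric(),
      barrier_bound_kjmol = numeric(), water_removal_kjmol = numeric(),
      product_bound = logical(), barrier_class = character(),
      approximate = logical(), stringsAsFactors = FALSE
    ))
  }
  do.call(rbind, rows)
}
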
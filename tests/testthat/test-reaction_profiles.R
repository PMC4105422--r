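test_that("packaged library has the documented composition", {
  lib <- cloudamide_profiles()
  amide_pairs <- amide_pair_profiles(lib)
  glycols <- Filter(function(p) p$kind == "glycol", lib$profiles)
  polymers <- Filter(function(p) {
    any(vapply(p$pair, function(nm) lib$species[[nm]]$kind, "") == "polymer")
  }, lib$profiles)

  expect_length(amide_pairs, 14)
  expect_length(glycols, 7)
  expect_length(polymers, 1)
  # 14 amide rows cover 10 distinct pairs (repeated conformers for some)
  pairs <- unique(vapply(amide_pairs, function(p)
    paste(p$pair, collapse = "-"), ""))
  expect_length(pairs, 10)
  expect_equal(polymers[[1]]$pair, c("Gly-Gly", "Gly-Ala"))
})

test_that("packaged amide profiles respect the stated energy ranges", {
  lib <- cloudamide_profiles()
  for (p in Filter(function(p) p$kind == "amide", lib$profiles)) {
    expect_gte(p$e_pair, -100)
    expect_lte(p$e_pair, -25)
    expect_gt(water_removal_energy(p), 0)
    expect_gte(barrier_height(p, "bound_pair"), 0)
    expect_true(p$approximate)
  }
})

test_that("barrier classification reproduces the low/high pair lists", {
  lib <- cloudamide_profiles()
  low_pairs <- c("Glu-Ala", "Asp-Ile", "Ser-Leu", "Asn-Pro")
  high_pairs <- c("Lys-Phe", "Phe-Gly", "Ala-Ala", "Gly-Gly", "Ala-Gly")
  for (p in amide_pair_profiles(lib)) {
    id <- paste(p$pair, collapse = "-")
    if (id %in% low_pairs) expect_identical(classify_barrier(p), "low")
    if (id %in% high_pairs) expect_identical(classify_barrier(p), "high")
  }
  # Gly-Gly barrier itself carries the reference value
  expect_equal(barrier_height(find_profile(lib, c("Gly", "Gly")),
                              "separated"), 200)
})

test_that("energy accessors follow the five-state conventions", {
  p <- make_profile(e_pair = -60, e_ts = 25, e4 = -50, e5 = 150)
  expect_equal(binding_energy(p), -60)
  expect_equal(barrier_height(p, "separated"), 25)
  expect_equal(barrier_height(p, "bound_pair"), 85)
  expect_equal(water_removal_energy(p), 200)

  flat <- make_profile(e_pair = 0, e_ts = 0, e4 = 0, e5 = 0)
  expect_equal(binding_energy(flat), 0)
  expect_equal(barrier_height(flat, "bound_pair"), 0)
  expect_equal(water_removal_energy(flat), 0)

  no5 <- make_profile(e5 = NA_real_)
  expect_error(water_removal_energy(no5), "state 5")
})

test_that("classification threshold is 0.6 eV and inclusive", {
  thr <- barrier_threshold_default()
  expect_equal(thr, 0.6 * 96.485)
  at <- make_profile(e_ts = thr)
  above <- make_profile(e_ts = thr + 1e-9)
  expect_identical(classify_barrier(at), "low")
  expect_identical(classify_barrier(above), "high")
  # a user threshold reclassifies
  expect_identical(classify_barrier(make_profile(e_ts = 200), 250), "low")
})

test_that("library IO round-trips semantically", {
  lib <- cloudamide_profiles()
  tmp <- withr::local_tempfile(fileext = ".json")
  write_profiles(lib, tmp)
  lib2 <- load_profiles(tmp)
  expect_equal(length(lib2), length(lib))
  for (i in seq_along(lib$profiles)) {
    expect_equal(lib2$profiles[[i]], lib$profiles[[i]])
  }
  expect_equal(names(lib2$species), names(lib$species))
  for (nm in names(lib$species))
    expect_equal(lib2$species[[nm]], lib$species[[nm]])
})

test_that("validation rejects malformed libraries and accepts empty ones", {
  species <- list(Gly = glycine, Ala = alanine)

  expect_silent(profile_library(list(), species))
  expect_equal(length(profile_library(list(), list())), 0)

  unbound <- make_profile(pair = c("Gly", "Ala"), e_pair = 10)
  expect_error(profile_library(list(unbound), species), "bound")

  unknown <- make_profile(pair = c("Gly", "Trp"))
  expect_error(profile_library(list(unknown), species), "unknown species")

  dup <- make_profile(pair = c("Gly", "Ala"))
  expect_error(profile_library(list(dup, dup), species), "duplicate")

  inverted <- make_profile(pair = c("Gly", "Ala"), e4 = -50, e5 = -60)
  expect_error(profile_library(list(inverted), species), "water removal")

  expect_error(load_profiles(tempfile()), "no such file")
})

test_that("species constructor and CSV import enforce invariants", {
  expect_error(species_info("X", 2, 10, "amino_acid"), "atom_count")
  expect_error(species_info("X", 10, -1, "amino_acid"), "mass")

  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("name,atom_count,mass_u,kind",
               "Gly,10,75.07,amino_acid",
               "EG,10,62.07,glycol"), tmp)
  sp <- read_species_csv(tmp)
  expect_named(sp, c("Gly", "EG"))
  expect_equal(sp$Gly$atom_count, 10L)
  expect_identical(sp$EG$kind, "glycol")
})

test_that("profile_table summarises a library row per profile", {
  lib <- cloudamide_profiles()
  tab <- profile_table(lib)
  expect_equal(nrow(tab), 22)
  expect_equal(sum(tab$kind == "amide" & tab$barrier_class == "low" &
                     !grepl("Gly-Gly", tab$pair)), 4)
  # zero-barrier glycol conformers have an unbound product
  eg0 <- tab[tab$kind == "glycol" & tab$barrier_separated_kjmol == 0, ]
  expect_true(all(!eg0$product_bound))
  expect_equal(nrow(profile_table(profile_library(list(), list()))), 0)
})
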
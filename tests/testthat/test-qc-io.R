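test_that("ORCA-style output parses energy and charges as printed", {
  txt <- c("some preamble",
           "FINAL SINGLE POINT ENERGY      -551.123456789012",
           "",
           "------------------",
           "HIRSHFELD ANALYSIS",
           "------------------",
           "",
           "  ATOM     CHARGE      SPIN",
           sprintf("  %3d C    %.6f    0.000000", 0:8,
                   c(0.10, -0.05, -0.05, 0.02, -0.02, 0.01, -0.01, 0.03, -0.03)),
           "",
           "  TOTAL   0.000000")
  st <- parse_orca_output(txt, "N")
  expect_s3_class(st, "electronic_state")
  expect_identical(st$energy, -551.123456789012)
  expect_identical(st$energy_unit, "hartree")
  expect_length(st$charges, 9)
  expect_identical(st$charges[1:3], c(0.10, -0.05, -0.05))
  expect_identical(st$label, "N")
})

test_that("parser errors name the missing or ambiguous structure", {
  expect_error(parse_orca_output("", "N"), "FINAL SINGLE POINT ENERGY")
  expect_error(parse_orca_output(character(0), "N"),
               "FINAL SINGLE POINT ENERGY")

  base <- c("FINAL SINGLE POINT ENERGY   -1.5",
            "HIRSHFELD ANALYSIS",
            "  ATOM     CHARGE      SPIN",
            "   0 C    0.100000    0.0",
            "")
  expect_error(parse_orca_output(c(base, base), "N"), "ambiguous")
  expect_error(
    parse_orca_output(c("FINAL SINGLE POINT ENERGY   -1.5",
                        "FINAL SINGLE POINT ENERGY   -1.6",
                        base[-1]), "N"),
    "ambiguous")
  # energy alone, no charge block
  expect_error(parse_orca_output("FINAL SINGLE POINT ENERGY  -1.5", "N"),
               "HIRSHFELD ANALYSIS")
})

test_that("a malformed charge row is reported with its line number", {
  txt <- c("FINAL SINGLE POINT ENERGY   -1.5",
           "HIRSHFELD ANALYSIS",
           "  ATOM     CHARGE      SPIN",
           "   0 C    0.100000    0.0",
           "   1 C    garbage     0.0",
           "")
  expect_error(parse_orca_output(txt, "N"), "line 5")
})

test_that("species table round-trips through JSON bit-identically", {
  recs <- generate_species(fixture_spec(seed = 11, n_species = 8))
  path <- withr::local_tempfile(fileext = ".json")
  write_species_table(recs, path)
  back <- read_species_table(path)
  expect_length(back, 8)
  for (i in seq_along(recs)) {
    expect_identical(back[[i]]$species_id, recs[[i]]$species_id)
    expect_identical(back[[i]]$alpha_atom_indices,
                     recs[[i]]$alpha_atom_indices)
    expect_identical(back[[i]]$gibbs_activation, recs[[i]]$gibbs_activation)
    for (lab in c("N", "N-1", "N+1")) {
      a <- get_state(back[[i]], lab); b <- get_state(recs[[i]], lab)
      expect_identical(a$energy, b$energy)
      expect_identical(a$charges, b$charges)
      expect_identical(a$energy_unit, b$energy_unit)
    }
  }
})

test_that("round-trip holds across many generated tables", {
  path <- withr::local_tempfile(fileext = ".json")
  for (seed in c(2, 3)) {
    recs <- generate_species(fixture_spec(seed = seed, n_species = 25))
    write_species_table(recs, path)
    back <- read_species_table(path)
    energies <- function(rs) {
      unlist(lapply(rs, function(r) vapply(r$states, `[[`, 0, "energy")))
    }
    charges <- function(rs) {
      unlist(lapply(rs, function(r) lapply(r$states, `[[`, "charges")))
    }
    expect_identical(energies(back), energies(recs))
    expect_identical(charges(back), charges(recs))
  }
})

test_that("an empty record list writes a valid empty document", {
  path <- withr::local_tempfile(fileext = ".json")
  write_species_table(list(), path)
  expect_identical(read_species_table(path), list())
})

test_that("eV unit tags survive the round trip", {
  rec <- make_record(unit = "eV")
  path <- withr::local_tempfile(fileext = ".json")
  write_species_table(list(rec), path)
  back <- read_species_table(path)[[1]]
  expect_identical(get_state(back, "N")$energy_unit, "eV")
  expect_identical(get_state(back, "N")$energy, -100)
})

test_that("duplicate ids and missing states are rejected by name", {
  rec <- make_record(id = "dup")
  path <- withr::local_tempfile(fileext = ".json")
  expect_error(write_species_table(list(rec, rec), path), "dup")

  write_species_table(list(rec), path)
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  doc$species[[1]]$states[["N+1"]] <- NULL
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17))
  expect_error(read_species_table(path), "dup.*N\\+1|N\\+1.*dup")
})

test_that("record validation enforces the triplet invariants", {
  st <- function(label) electronic_state(label, -1, c(0, 0), "eV")
  expect_error(
    species_record("x", list(st("N"), st("N"), st("N+1")), c(0L, 1L)),
    "'N' present 2 times")
  expect_error(
    species_record("x", list(st("N"),
                             electronic_state("N-1", -1, c(0, 0, 0), "eV"),
                             st("N+1")), c(0L, 1L)),
    "differ in length")
  expect_error(
    species_record("x", list(st("N"), st("N-1"), st("N+1")), c(1L, 1L)),
    "distinct")
  expect_error(
    species_record("x", list(st("N"), st("N-1"), st("N+1")), c(0L, 5L)),
    "out of range")
})

test_that("the flat species summary exposes energies and alpha charges", {
  rec <- make_record(qN = c(0.10, -0.05, -0.05), qP = c(0.02, -0.01, -0.01),
                     alpha = c(0L, 2L))
  tbl <- species_summary_tbl(list(rec))
  expect_identical(nrow(tbl), 1L)
  expect_equal(tbl$q2_N, 0.10)
  expect_equal(tbl$q5_N, -0.05)
  expect_equal(tbl$q2_Np1, 0.02)
  # eV energies are converted to hartree in the flat export
  expect_equal(tbl$E_N, -100 / 27.211386245988)
})
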
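test_that("vertical IP and EA follow the finite-difference definitions", {
  rec <- make_record(E_N = -100, E_Nm1 = -95, E_Np1 = -101, unit = "eV")
  expect_equal(vertical_ionization_potential(rec), 5)
  expect_equal(vertical_electron_affinity(rec), 1)

  # equal energies give zero
  rec0 <- make_record(E_N = -100, E_Nm1 = -100, E_Np1 = -100)
  expect_equal(vertical_ionization_potential(rec0), 0)
  expect_equal(vertical_electron_affinity(rec0), 0)

  # an anion above the neutral gives a negative VEA, unclamped
  recn <- make_record(E_N = -100, E_Nm1 = -93, E_Np1 = -99.5)
  expect_equal(vertical_electron_affinity(recn), -0.5)

  # hartree inputs are converted before subtraction
  h <- 27.211386245988
  rech <- make_record(E_N = -100 / h, E_Nm1 = -95 / h, E_Np1 = -101 / h,
                      unit = "hartree")
  expect_equal(vertical_ionization_potential(rech), 5, tolerance = 1e-12)
})

test_that("global descriptors satisfy their defining relations", {
  rec <- make_record(E_N = -100, E_Nm1 = -95, E_Np1 = -101)  # VIP 5, VEA 1
  g <- global_descriptors(rec)
  expect_equal(g$chi_M, 3.0)
  expect_equal(g$mu, -3.0)
  expect_equal(g$eta, 4.0)
  expect_equal(g$S_global, 0.25)
  expect_equal(g$omega, 1.125)

  rec2 <- make_record(E_N = -100, E_Nm1 = -92, E_Np1 = -100)  # VIP 8, VEA 0
  g2 <- global_descriptors(rec2)
  expect_equal(g2$chi_M, 4.0)
  expect_equal(g2$eta, 8.0)
  expect_equal(g2$S_global, 0.125)
})

test_that("a degenerate gap leaves softness undefined", {
  rec <- make_record(E_N = -100, E_Nm1 = -95, E_Np1 = -105)  # VIP = VEA = 5
  expect_error(global_descriptors(rec), "undefined")
  g <- global_descriptors(rec, strict = FALSE)
  expect_true(is.na(g$S_global))
  expect_true(is.na(g$omega))
  expect_equal(g$chi_M, 5.0)  # still defined
})

test_that("condensed Fukui functions are charge finite differences", {
  rec <- make_record(E_N = -100, E_Nm1 = -95, E_Np1 = -101, # S = 0.25
                     qN = c(0.10, 0.0, -0.10),
                     qP = c(-0.05, 0.0, -0.10),
                     qM = c(0.20, 0.0, -0.10))
  loc <- condensed_local(rec)
  expect_equal(loc$f_plus[1], 0.15)
  expect_equal(loc$s_plus[1], 0.0375)
  expect_equal(loc$f_minus[1], 0.10)
  expect_equal(loc$f_zero, (loc$f_plus + loc$f_minus) / 2)
  # identical charges across states give zero Fukui values
  expect_equal(loc$f_plus[3], 0)
  expect_equal(loc$f_minus[2], 0)
})

test_that("descriptor invariants hold on generated species", {
  recs <- generate_species(fixture_spec(seed = 5, n_species = 30))
  for (rec in recs) {
    g <- global_descriptors(rec)
    # exact same-float identities
    expect_identical(g$chi_M, (g$vip + g$vea) / 2)
    expect_identical(g$mu, -g$chi_M)
    expect_lt(abs(g$S_global * g$eta - 1), 1e-12)
    loc <- condensed_local(rec, g)
    expect_identical(loc$f_zero, (loc$f_plus + loc$f_minus) / 2)
    # Fukui sum rule on charge-conserving fixtures
    expect_lt(abs(sum(loc$f_plus) - 1), 1e-12)
    expect_lt(abs(sum(loc$f_minus) - 1), 1e-12)
  }
})

test_that("descriptors are invariant to the energy unit of the input", {
  recs <- generate_species(fixture_spec(seed = 6, n_species = 10))
  for (rec in recs) {
    rec_ev <- rec
    rec_ev$states <- lapply(rec$states, function(s) {
      electronic_state(s$label, hartree_to_ev(s$energy), s$charges,
                       energy_unit = "eV")
    })
    a <- global_descriptors(rec)
    b <- global_descriptors(rec_ev)
    for (col in c("vip", "vea", "chi_M", "eta", "S_global", "omega")) {
      expect_lt(rel_err(a[[col]], b[[col]]), 1e-10)
    }
  }
})

test_that("nucleophilicity needs an explicit reference", {
  rec <- make_record(E_N = -100, E_Nm1 = -95, E_Np1 = -99)  # VIP 5
  expect_equal(nucleophilicity_index(rec, reference_energy = -5), 0)
  expect_equal(nucleophilicity_index(rec, reference_energy = -9), 4)
  expect_error(nucleophilicity_index(rec), "reference_energy")
})

test_that("feature packaging picks the alpha-carbon values", {
  rec <- make_record(E_N = -100, E_Nm1 = -95, E_Np1 = -101,  # S = 0.25
                     qN = c(0.10, 0.02, -0.12),
                     qP = c(-0.05, 0.01, -0.12),
                     alpha = c(0L, 1L))
  ft <- thiophene_features(rec)
  expect_identical(nrow(ft), 1L)
  expect_equal(ft$q2, 0.10)
  expect_equal(ft$q5, 0.02)
  expect_equal(ft$s2_plus, 0.25 * 0.15)
  expect_equal(ft$s5_plus, 0.25 * 0.01)
  expect_equal(ft$S_global, 0.25)
  expect_equal(ft$chi_M, 3.0)

  # a symmetric molecule has equal alpha-carbon features
  sym <- make_record(qN = c(0.07, 0.07, -0.14), qP = c(0.01, 0.01, -0.02),
                     alpha = c(0L, 1L))
  fs <- thiophene_features(sym)
  expect_identical(fs$q2, fs$q5)
  expect_identical(fs$s2_plus, fs$s5_plus)

  # out-of-range alpha index is rejected at construction
  expect_error(make_record(alpha = c(0L, 999L)), "out of range")
})

test_that("the flat descriptor table matches its parts", {
  recs <- generate_species(fixture_spec(seed = 9, n_species = 5))
  tbl <- cdft_descriptor_table(recs)
  expect_identical(nrow(tbl), 5L)
  ft <- thiophene_features(recs)
  expect_equal(tbl$s2_plus, ft$s2_plus)
  expect_equal(tbl$q5, ft$q5)
  g1 <- global_descriptors(recs[[1]])
  expect_identical(tbl$omega[1], g1$omega)

  path <- withr::local_tempfile(fileext = ".csv")
  write_descriptor_csv(tbl, path)
  back <- utils::read.csv(path, comment.char = "#")
  expect_equal(back$chi_M, tbl$chi_M, tolerance = 1e-12)
})
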
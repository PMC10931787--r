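#' Specification for synthetic fixtures
#'
#' Deterministic generators stand in for a real computed dataset: a set of
#' species with plausible electronic-state energies and exactly
#' charge-conserving Hirshfeld charges, and descriptor/response tables with
#' a planted formula. The defaults emulate a screening set of ~90 thiophene
#' derivatives: vertical ionization potentials of 6-10 eV and electron
#' affinities of -0.5 to 3 eV (so the fundamental gap is always positive),
#' 8-20 atoms, and alpha carbons at 0-based indices 1 and 4 as in a bare
#' thiophene ring (S first, then C2..C5). Fixtures are statistical
#' stand-ins, not electronic-structure mimics.
#'
#' @param seed Integer RNG seed (mandatory).
#' @param n_species Number of species / rows. Default 90.
#' @param atom_range Integer range of atom counts. Default `c(8, 20)`.
#' @param vip_range VIP range, eV. Default `c(6, 10)`.
#' @param vea_range VEA range, eV. Default `c(-0.5, 3)`.
#' @param charge_dispersion SD of per-atom charge noise, e. Default 0.08.
#' @param gibbs_range Range of Gibbs activation energies, kJ/mol. Default
#'   `c(40, 90)`.
#' @param alpha_indices 0-based indices of the two alpha carbons. Default
#'   `c(1, 4)`.
#' @param planted_model For regression datasets: `"eq1"` (the fitted
#'   reactivity model evaluated on descriptor-range features), `"linear"`
#'   (`3.2 x0 - 1.5 x1`), `"fshape"` (`log10(2 x0 + 0.5 / x1)` on
#'   electronegativity/softness-like ranges), or a function taking the
#'   feature tibble and returning the response.
#' @param noise_sd SD of Gaussian noise added to the planted response.
#'   Default 0.
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(seed, n_species = 90, atom_range = c(8L, 20L),
                         vip_range = c(6, 10), vea_range = c(-0.5, 3),
                         charge_dispersion = 0.08, gibbs_range = c(40, 90),
                         alpha_indices = c(1L, 4L),
                         planted_model = "eq1", noise_sd = 0) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  stopifnot(n_species >= 1, atom_range[1] <= atom_range[2],
            vip_range[1] <= vip_range[2], vea_range[1] <= vea_range[2],
            charge_dispersion > 0, noise_sd >= 0)
  if (atom_range[1] < 5L) {
    stop("atom_range minimum must be >= 5 (thiophene core)", call. = FALSE)
  }
  if (vea_range[2] >= vip_range[1]) {
    stop("vea_range must lie entirely below vip_range so the gap is positive",
         call. = FALSE)
  }
  structure(
    list(seed = as.integer(seed), n_species = as.integer(n_species),
         atom_range = as.integer(atom_range), vip_range = vip_range,
         vea_range = vea_range, charge_dispersion = charge_dispersion,
         gibbs_range = gibbs_range, alpha_indices = as.integer(alpha_indices),
         planted_model = planted_model, noise_sd = noise_sd),
    class = "fixture_spec"
  )
}

# Charges with an exact target sum: noise is recentred so the molecular
# charge is conserved to machine precision, making the Fukui sum rule
# (sum f+ = 1 e) a sharp test.
charges_with_sum <- function(n, total, dispersion) {
  q <- stats::rnorm(n, 0, dispersion)
  q - mean(q) + total / n
}

# A condensed-Fukui distribution summing exactly to 1 e, with a sizeable
# positive share on the alpha carbons (the reactive sites) so downstream
# local softness sums are strictly positive, as the reactivity model's
# domain requires.
fukui_distribution <- function(n, alpha_idx1) {
  f <- numeric(n)
  f[alpha_idx1] <- stats::runif(2, 0.08, 0.30)
  rest <- setdiff(seq_len(n), alpha_idx1)
  w <- stats::runif(length(rest))
  f[rest] <- w / sum(w) * (1 - sum(f[alpha_idx1]))
  f
}

#' Generate a set of synthetic species records
#'
#' Energies are constructed so that VIP and VEA land uniformly in the
#' requested ranges (the N-state energy itself is an arbitrary large
#' negative hartree value); per-state charges sum exactly to the molecular
#' charge of that state (0 for N, -1 e for N+1, +1 e for N-1), so condensed
#' Fukui functions obey the sum rules to machine precision. The alpha
#' carbons always receive a positive condensed Fukui share (they are the
#' reactive sites), keeping the summed alpha local softness strictly
#' positive as the reactivity model's F term requires. All records pass
#' [validate_species_record()] and have a positive fundamental gap.
#'
#' @param spec A [fixture_spec()].
#' @return List of `spec$n_species` [species_record()] objects.
#' @examples
#' recs <- generate_species(fixture_spec(seed = 42, n_species = 3))
#' thiophene_features(recs)
#' @export
generate_species <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  lapply(seq_len(spec$n_species), function(i) {
    natoms <- sample(seq(spec$atom_range[1], spec$atom_range[2]), 1L)
    E_N <- stats::runif(1, -600, -400)               # hartree
    vip <- stats::runif(1, spec$vip_range[1], spec$vip_range[2])   # eV
    vea <- stats::runif(1, spec$vea_range[1], spec$vea_range[2])   # eV
    E_Nm1 <- E_N + vip / thio_constants$hartree_ev
    E_Np1 <- E_N - vea / thio_constants$hartree_ev
    alpha1 <- spec$alpha_indices + 1L
    qN <- charges_with_sum(natoms, 0, spec$charge_dispersion)
    qP <- qN - fukui_distribution(natoms, alpha1)   # N+1: one extra electron
    qM <- qN + fukui_distribution(natoms, alpha1)   # N-1: one electron removed
    mk <- function(label, energy, charges) {
      electronic_state(
        label = label, energy = energy, energy_unit = "hartree",
        charges = charges,
        method_label = "synthetic", charge_scheme_label = "Hirshfeld"
      )
    }
    species_record(
      species_id = sprintf("syn-%03d", i),
      states = list(mk("N", E_N, qN), mk("N-1", E_Nm1, qM),
                    mk("N+1", E_Np1, qP)),
      alpha_atom_indices = spec$alpha_indices,
      gibbs_activation = stats::runif(1, spec$gibbs_range[1],
                                      spec$gibbs_range[2]),
      notes = "synthetic fixture"
    )
  })
}

#' Write an electronic state as ORCA-style single-point output
#'
#' Emits the plain-text dialect [parse_orca_output()] reads: a
#' `FINAL SINGLE POINT ENERGY` line (hartree) and a `HIRSHFELD ANALYSIS`
#' table. Numbers are printed with enough decimals that
#' `parse_orca_output(write_orca_fixture(s))` reproduces the energy and
#' charges exactly.
#'
#' @param state An [electronic_state()] with hartree energy.
#' @param path Output path, or `NULL` to return the lines invisibly.
#' @return Character vector of lines, invisibly.
#' @export
write_orca_fixture <- function(state, path = NULL) {
  stopifnot(inherits(state, "electronic_state"))
  if (state$energy_unit != "hartree") {
    stop("ORCA-style output stores hartree energies; convert first",
         call. = FALSE)
  }
  fmt_q <- vapply(state$charges, function(q) {
    format(q, digits = 17, scientific = FALSE, trim = TRUE, nsmall = 1)
  }, character(1))
  rows <- sprintf("  %3d C  %24s   0.000000",
                  seq_along(state$charges) - 1L, fmt_q)
  lines <- c(
    "                     *** synthetic single-point output ***",
    "",
    "-------------------------   --------------------",
    sprintf("FINAL SINGLE POINT ENERGY  %25.17f", state$energy),
    "-------------------------   --------------------",
    "",
    "------------------",
    "HIRSHFELD ANALYSIS",
    "------------------",
    "",
    "Total integrated alpha density  =     0.000000",
    "",
    "  ATOM     CHARGE      SPIN",
    rows,
    "",
    sprintf("  TOTAL  %20.17f", sum(state$charges))
  )
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' Generate a descriptor/response table with a planted formula
#'
#' Features are drawn in model-plausible descriptor ranges —
#' electronegativity `chi_M` in 2-6 eV, global softness `S_global` in
#' 0.1-0.6 1/eV, alpha-carbon local softness `s2_plus`/`s5_plus` each in
#' 0.025-0.75 eV^-1 e (so their sum spans 0.05-1.5), charges `q2`/`q5` in
#' -0.15 to 0.15 e — chosen so the F-term logarithm argument is always
#' positive. The response is the planted model plus Gaussian noise of
#' `spec$noise_sd`.
#'
#' Planted models: `"eq1"` evaluates the fitted reactivity model with its
#' published constants on the descriptor features; `"linear"` is
#' `3.2 x0 - 1.5 x1` on uniform(-1, 1) features; `"fshape"` is
#' `log10(2 x0 + 0.5 / x1)` with `x0` on the electronegativity range and
#' `x1` on the summed-softness range; a function is applied to the feature
#' tibble.
#'
#' @param spec A [fixture_spec()]; `n_species` sets the row count.
#' @return A tibble of feature columns plus a `response` column, ready for
#'   [gp_evolve()].
#' @export
generate_regression_dataset <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed + 1L)
  n <- spec$n_species
  pm <- spec$planted_model
  if (is.function(pm)) {
    feats <- tibble::tibble(
      chi_M = stats::runif(n, 2, 6),
      S_global = stats::runif(n, 0.1, 0.6),
      s2_plus = stats::runif(n, 0.025, 0.75),
      s5_plus = stats::runif(n, 0.025, 0.75),
      q2 = stats::runif(n, -0.15, 0.15),
      q5 = stats::runif(n, -0.15, 0.15)
    )
    y <- pm(feats)
  } else if (identical(pm, "eq1")) {
    feats <- tibble::tibble(
      chi_M = stats::runif(n, 2, 6),
      S_global = stats::runif(n, 0.1, 0.6),
      s2_plus = stats::runif(n, 0.025, 0.75),
      s5_plus = stats::runif(n, 0.025, 0.75),
      q2 = stats::runif(n, -0.15, 0.15),
      q5 = stats::runif(n, -0.15, 0.15)
    )
    y <- predict_log_krel_ideal(feats$q2, feats$q5, feats$chi_M,
                                feats$S_global, feats$s2_plus, feats$s5_plus)
  } else if (identical(pm, "linear")) {
    feats <- tibble::tibble(
      x0 = stats::runif(n, -1, 1),
      x1 = stats::runif(n, -1, 1)
    )
    y <- 3.2 * feats$x0 - 1.5 * feats$x1
  } else if (identical(pm, "fshape")) {
    feats <- tibble::tibble(
      x0 = stats::runif(n, 2, 6),
      x1 = stats::runif(n, 0.05, 1.5)
    )
    y <- log10(2 * feats$x0 + 0.5 / feats$x1)
  } else {
    stop("unknown planted_model '", pm, "'", call. = FALSE)
  }
  if (spec$noise_sd > 0) {
    y <- y + stats::rnorm(n, 0, spec$noise_sd)
  }
  if (stats::sd(y) == 0) {
    stop("planted response is constant; infeasible spec", call. = FALSE)
  }
  dplyr::mutate(feats, response = y)
}
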
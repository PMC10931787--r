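#' Vertical ionization potential
#'
#' Energy difference between the N-1 and N electron states,
#' `E(N-1) - E(N)`, at the N-electron geometry, in eV. Both states must be
#' present; hartree energies are converted before subtraction.
#'
#' @param rec A [species_record()].
#' @return VIP in eV.
#' @export
vertical_ionization_potential <- function(rec) {
  state_energy_ev(get_state(rec, "N-1")) - state_energy_ev(get_state(rec, "N"))
}

#' Vertical electron affinity
#'
#' Energy difference between the N and N+1 electron states,
#' `E(N) - E(N+1)`, at the N-electron geometry, in eV. A negative value
#' (unbound anion) is returned as-is; no clamping is applied.
#'
#' @param rec A [species_record()].
#' @return VEA in eV.
#' @export
vertical_electron_affinity <- function(rec) {
  state_energy_ev(get_state(rec, "N")) - state_energy_ev(get_state(rec, "N+1"))
}

#' Global conceptual-DFT descriptors of one species
#'
#' Finite-difference (vertical) definitions over the N, N-1 and N+1 states:
#' Mulliken electronegativity `chi_M = (VIP + VEA)/2`, chemical potential
#' `mu = -chi_M`, hardness `eta = VIP - VEA` (the fundamental gap), global
#' softness `S = 1/eta`, and electrophilicity index
#' `omega = mu^2 / (2 eta)`. When `eta <= 0` the softness and
#' electrophilicity are undefined: with `strict = TRUE` (default) this is an
#' error, otherwise those fields are `NA`.
#'
#' @param rec A [species_record()].
#' @param strict Error on a non-positive gap? Default `TRUE`.
#' @return A one-row tibble: `species_id`, `vip`, `vea`, `chi_M`, `mu`,
#'   `eta` (all eV), `S_global` (1/eV), `omega` (eV).
#' @examples
#' # VIP = 5 eV, VEA = 1 eV gives chi_M = 3, eta = 4, S = 0.25, omega = 1.125
#' @export
global_descriptors <- function(rec, strict = TRUE) {
  vip <- vertical_ionization_potential(rec)
  vea <- vertical_electron_affinity(rec)
  chi_M <- (vip + vea) / 2
  mu <- -chi_M
  eta <- vip - vea
  if (eta > 0) {
    S_global <- 1 / eta
    omega <- mu^2 / (2 * eta)
  } else {
    if (strict) {
      stop("species '", rec$species_id, "': hardness eta = ", eta,
           " eV <= 0; global softness and electrophilicity are undefined",
           call. = FALSE)
    }
    S_global <- NA_real_
    omega <- NA_real_
  }
  tibble::tibble(
    species_id = rec$species_id,
    vip = vip, vea = vea, chi_M = chi_M, mu = mu, eta = eta,
    S_global = S_global, omega = omega
  )
}

#' Condensed Fukui functions and local softness
#'
#' Per-atom finite differences of Hirshfeld charges across the three states:
#' `f+_k = q_k(N) - q_k(N+1)` (susceptibility to nucleophile-generating,
#' electron-accepting attack), `f-_k = q_k(N-1) - q_k(N)`, and
#' `f0_k = (f+_k + f-_k)/2`. Condensed local softness is the global softness
#' times the condensed Fukui function, `s± = S f±` (1/eV e). When the
#' charge sets conserve total molecular charge exactly, the f+ values sum to
#' 1 e.
#'
#' @param rec A [species_record()].
#' @param global Optional one-row tibble from [global_descriptors()];
#'   computed from `rec` if omitted.
#' @return A tibble with one row per atom: `species_id`, `atom` (0-based
#'   index), `q_N`, `f_plus`, `f_minus`, `f_zero` (e), `s_plus`, `s_minus`
#'   (1/eV e).
#' @export
condensed_local <- function(rec, global = NULL) {
  if (is.null(global)) global <- global_descriptors(rec)
  qN <- get_state(rec, "N")$charges
  qM <- get_state(rec, "N-1")$charges
  qP <- get_state(rec, "N+1")$charges
  if (length(qN) != length(qM) || length(qN) != length(qP)) {
    stop("species '", rec$species_id,
         "': charge-sequence length mismatch across states", call. = FALSE)
  }
  f_plus <- qN - qP
  f_minus <- qM - qN
  tibble::tibble(
    species_id = rec$species_id,
    atom = seq_along(qN) - 1L,
    q_N = qN,
    f_plus = f_plus,
    f_minus = f_minus,
    f_zero = (f_plus + f_minus) / 2,
    s_plus = global$S_global * f_plus,
    s_minus = global$S_global * f_minus
  )
}

#' Nucleophilicity index relative to a caller-supplied reference
#'
#' Nucleophilicity indices are relative quantities: `Nu = -VIP - E_ref`,
#' where `E_ref` is the HOMO-proxy energy (here, -VIP) of a reference
#' electrophile chosen by the caller. No default reference is assumed: if
#' the reference is missing the index is absent, not defaulted.
#'
#' @param rec A [species_record()].
#' @param reference_energy Reference energy in eV (e.g. -VIP of the
#'   reference species).
#' @return Nucleophilicity in eV.
#' @export
nucleophilicity_index <- function(rec, reference_energy) {
  if (missing(reference_energy) || is.null(reference_energy)) {
    stop("nucleophilicity requires an explicit `reference_energy` (eV); ",
         "no default reference is assumed", call. = FALSE)
  }
  -vertical_ionization_potential(rec) - reference_energy
}

#' Model features of one or many species
#'
#' Packages, per species, the six inputs consumed by the fitted reactivity
#' model: the N-state Hirshfeld charges `q2`, `q5` at the alpha carbons, the
#' condensed local softness for nucleophilic attack `s2_plus`, `s5_plus` at
#' the same atoms, the global softness `S_global`, and the Mulliken
#' electronegativity `chi_M`. Bookkeeping only: all quantities come from
#' [global_descriptors()] and [condensed_local()].
#'
#' @param records A [species_record()] or list of them.
#' @return A tibble with one row per species: `species_id`, `q2`, `q5` (e),
#'   `s2_plus`, `s5_plus` (1/eV e), `S_global` (1/eV), `chi_M` (eV).
#' @export
thiophene_features <- function(records) {
  if (inherits(records, "species_record")) records <- list(records)
  purrr::map_dfr(records, function(rec) {
    g <- global_descriptors(rec)
    loc <- condensed_local(rec, g)
    i2 <- rec$alpha_atom_indices[1] + 1L
    i5 <- rec$alpha_atom_indices[2] + 1L
    tibble::tibble(
      species_id = rec$species_id,
      q2 = loc$q_N[i2],
      q5 = loc$q_N[i5],
      s2_plus = loc$s_plus[i2],
      s5_plus = loc$s_plus[i5],
      S_global = g$S_global,
      chi_M = g$chi_M
    )
  })
}

#' Full descriptor table for a set of species
#'
#' Convenience wrapper joining [global_descriptors()] and the alpha-carbon
#' columns of [condensed_local()] into the flat per-species table used for
#' export and model fitting.
#'
#' @param records List of [species_record()] objects.
#' @return A tibble, one row per species: `species_id`, `vip`, `vea`,
#'   `chi_M`, `mu`, `eta`, `S_global`, `omega`, `q2`, `q5`, `f2_plus`,
#'   `f5_plus`, `s2_plus`, `s5_plus`.
#' @export
cdft_descriptor_table <- function(records) {
  if (inherits(records, "species_record")) records <- list(records)
  purrr::map_dfr(records, function(rec) {
    g <- global_descriptors(rec)
    loc <- condensed_local(rec, g)
    i2 <- rec$alpha_atom_indices[1] + 1L
    i5 <- rec$alpha_atom_indices[2] + 1L
    dplyr::bind_cols(
      g,
      tibble::tibble(
        q2 = loc$q_N[i2], q5 = loc$q_N[i5],
        f2_plus = loc$f_plus[i2], f5_plus = loc$f_plus[i5],
        s2_plus = loc$s_plus[i2], s5_plus = loc$s_plus[i5]
      )
    )
  })
}

#' Write the descriptor table to CSV
#'
#' One row per species; a leading comment line records the units
#' (eV for energies, 1/eV for softness, e for charges and Fukui values).
#'
#' @param descriptors Tibble from [cdft_descriptor_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_descriptor_csv <- function(descriptors, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# units: vip/vea/chi_M/mu/eta/omega eV; S_global/s2_plus/",
                    "s5_plus 1/eV; q2/q5/f2_plus/f5_plus e"), con)
  utils::write.csv(descriptors, con, row.names = FALSE)
  invisible(path)
}
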
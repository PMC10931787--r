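#' Electronic state of a species at fixed geometry
#'
#' One electron-count state (N, N-1 or N+1) of a molecule: its total
#' electronic energy and the per-atom Hirshfeld charges, all computed at the
#' geometry optimised for the N-electron system. Three such states make up a
#' [species_record()].
#'
#' @param label One of `"N"`, `"N-1"`, `"N+1"`.
#' @param energy Total electronic energy (scalar).
#' @param energy_unit Unit of `energy`: `"hartree"` (default) or `"eV"`.
#' @param charges Numeric vector of per-atom Hirshfeld charges, in electron
#'   units, in the atom order of the originating calculation.
#' @param method_label Free-text level-of-theory label, e.g.
#'   `"wB97X-D3/def2-TZVP"`.
#' @param charge_scheme_label Free-text charge-partitioning label, e.g.
#'   `"Hirshfeld"`.
#' @return An object of class `electronic_state`.
#' @seealso [species_record()], [parse_orca_output()]
#' @export
electronic_state <- function(label, energy, charges,
                             energy_unit = "hartree",
                             method_label = "",
                             charge_scheme_label = "Hirshfeld") {
  label <- match.arg(label, c("N", "N-1", "N+1"))
  energy_unit <- match.arg(energy_unit, c("hartree", "eV"))
  if (!is.numeric(energy) || length(energy) != 1L || !is.finite(energy)) {
    stop("`energy` must be a single finite number", call. = FALSE)
  }
  if (!is.numeric(charges) || length(charges) < 1L || anyNA(charges)) {
    stop("`charges` must be a non-empty numeric vector without NA",
         call. = FALSE)
  }
  structure(
    list(
      label = label,
      energy = as.numeric(energy),
      energy_unit = energy_unit,
      charges = as.numeric(charges),
      method_label = method_label,
      charge_scheme_label = charge_scheme_label
    ),
    class = "electronic_state"
  )
}

#' Energy of an electronic state in eV
#'
#' @param state An [electronic_state()].
#' @return Scalar energy in eV.
#' @export
state_energy_ev <- function(state) {
  stopifnot(inherits(state, "electronic_state"))
  if (state$energy_unit == "hartree") hartree_to_ev(state$energy) else state$energy
}

#' A species with its N, N-1 and N+1 electronic states
#'
#' The unit of input for descriptor computation: a species identifier, the
#' three electron-count states (all at the N-electron geometry), and the
#' indices of the two alpha carbons of the thiophene core (the 2- and
#' 5-positions attacked by singlet oxygen). Atom indices are 0-based,
#' following ORCA output conventions.
#'
#' @param species_id Character scalar, unique within a table.
#' @param states List of three [electronic_state()] objects labelled
#'   `"N"`, `"N-1"`, `"N+1"` (each exactly once, any order).
#' @param alpha_atom_indices Integer vector of length 2: 0-based atom indices
#'   of the 2- and 5-carbons.
#' @param gibbs_activation Optional Gibbs free energy of activation, kJ/mol,
#'   for transition-state-theory kinetics; `NA` if not available.
#' @param n_geometry_states Logical flag asserting that all three states were
#'   computed at the N-electron geometry. This is input metadata; it cannot be
#'   verified numerically from energies and charges.
#' @param notes Free text.
#' @return An object of class `species_record`.
#' @export
species_record <- function(species_id, states, alpha_atom_indices,
                           gibbs_activation = NA_real_,
                           n_geometry_states = TRUE,
                           notes = "") {
  rec <- structure(
    list(
      species_id = as.character(species_id),
      states = states,
      alpha_atom_indices = as.integer(alpha_atom_indices),
      gibbs_activation = as.numeric(gibbs_activation),
      n_geometry_states = isTRUE(n_geometry_states),
      notes = notes
    ),
    class = "species_record"
  )
  validate_species_record(rec)
  rec
}

#' Validate a species record
#'
#' Checks the structural invariants: each of the three state labels present
#' exactly once; identical atom counts across states; alpha atom indices
#' distinct and in range (0-based).
#'
#' @param rec A [species_record()].
#' @return `rec`, invisibly, if valid; otherwise an error.
#' @export
validate_species_record <- function(rec) {
  if (!inherits(rec, "species_record")) {
    stop("not a species_record", call. = FALSE)
  }
  if (length(rec$species_id) != 1L || is.na(rec$species_id) ||
      !nzchar(rec$species_id)) {
    stop("species_id must be a non-empty string", call. = FALSE)
  }
  labels <- vapply(rec$states, function(s) {
    if (!inherits(s, "electronic_state")) {
      stop("species '", rec$species_id, "': states must be electronic_state objects",
           call. = FALSE)
    }
    s$label
  }, character(1))
  for (lab in c("N", "N-1", "N+1")) {
    n <- sum(labels == lab)
    if (n != 1L) {
      stop("species '", rec$species_id, "': state '", lab, "' present ",
           n, " times (need exactly once)", call. = FALSE)
    }
  }
  natoms <- vapply(rec$states, function(s) length(s$charges), integer(1))
  if (length(unique(natoms)) != 1L) {
    stop("species '", rec$species_id,
         "': charge vectors differ in length across states (",
         paste(natoms, collapse = ", "), ")", call. = FALSE)
  }
  ai <- rec$alpha_atom_indices
  if (length(ai) != 2L || anyNA(ai)) {
    stop("species '", rec$species_id,
         "': alpha_atom_indices must be two integers", call. = FALSE)
  }
  if (ai[1] == ai[2]) {
    stop("species '", rec$species_id,
         "': alpha_atom_indices must be distinct", call. = FALSE)
  }
  if (any(ai < 0L) || any(ai >= natoms[1])) {
    stop("species '", rec$species_id, "': alpha atom index out of range [0, ",
         natoms[1] - 1L, "]", call. = FALSE)
  }
  invisible(rec)
}

#' Fetch one electronic state from a species record by label
#'
#' @param rec A [species_record()].
#' @param label `"N"`, `"N-1"` or `"N+1"`.
#' @return The matching [electronic_state()].
#' @export
get_state <- function(rec, label) {
  stopifnot(inherits(rec, "species_record"))
  label <- match.arg(label, c("N", "N-1", "N+1"))
  for (s in rec$states) {
    if (s$label == label) return(s)
  }
  stop("species '", rec$species_id, "': missing state '", label, "'",
       call. = FALSE)
}

#' @export
print.species_record <- function(x, ...) {
  cat("<species_record> ", x$species_id, "\n", sep = "")
  cat("  atoms: ", length(get_state(x, "N")$charges),
      ", alpha carbons (0-based): ",
      paste(x$alpha_atom_indices, collapse = ", "), "\n", sep = "")
  for (lab in c("N", "N-1", "N+1")) {
    s <- get_state(x, lab)
    cat(sprintf("  E(%s) = %.10f %s\n", lab, s$energy, s$energy_unit))
  }
  if (is.finite(x$gibbs_activation)) {
    cat("  Gibbs activation: ", x$gibbs_activation, " kJ/mol\n", sep = "")
  }
  invisible(x)
}
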
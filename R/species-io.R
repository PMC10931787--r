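#' Read a canonical species document
#'
#' The canonical on-disk format is JSON with top level
#' `{format_version, index_base, species: [...]}`; each species entry holds
#' `species_id`, `alpha_atom_indices` (0-based), optional
#' `gibbs_activation_kJmol`, and a `states` object keyed `N`, `N-1`, `N+1`,
#' each with `energy`, `energy_unit`, `charges`, `method_label` and
#' `charge_scheme_label`. Energies and charges are written at full double
#' precision so read(write(x)) round-trips exactly.
#'
#' @param path Path to a species JSON document.
#' @return A list of [species_record()] objects, in file order.
#' @seealso [write_species_table()], [species_summary_tbl()]
#' @export
read_species_table <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(doc$species)) {
    stop("'", path, "': not a species document (no 'species' field)",
         call. = FALSE)
  }
  if (!identical(doc$index_base, 0L) && !identical(doc$index_base, 0)) {
    stop("'", path, "': index_base must be 0 (0-based atom indices)",
         call. = FALSE)
  }
  recs <- lapply(doc$species, function(sp) {
    if (is.null(sp$species_id)) {
      stop("'", path, "': species entry without species_id", call. = FALSE)
    }
    states <- lapply(names(sp$states), function(lab) {
      st <- sp$states[[lab]]
      if (!lab %in% c("N", "N-1", "N+1")) {
        stop("species '", sp$species_id, "': unknown state label '", lab, "'",
             call. = FALSE)
      }
      electronic_state(
        label = lab,
        energy = st$energy,
        energy_unit = st$energy_unit %||% "hartree",
        charges = unlist(st$charges),
        method_label = st$method_label %||% "",
        charge_scheme_label = st$charge_scheme_label %||% "Hirshfeld"
      )
    })
    if (length(states) != 3L) {
      missing <- setdiff(c("N", "N-1", "N+1"), names(sp$states))
      stop("species '", sp$species_id, "': missing state ",
           paste(sQuote(missing), collapse = ", "), call. = FALSE)
    }
    species_record(
      species_id = sp$species_id,
      states = states,
      alpha_atom_indices = unlist(sp$alpha_atom_indices),
      gibbs_activation = sp$gibbs_activation_kJmol %||% NA_real_,
      notes = sp$notes %||% ""
    )
  })
  ids <- vapply(recs, function(r) r$species_id, character(1))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    stop("'", path, "': duplicate species_id: ",
         paste(sQuote(unique(dup)), collapse = ", "), call. = FALSE)
  }
  recs
}

#' Write species records to a canonical JSON document
#'
#' Inverse of [read_species_table()]; energies and charges are emitted at
#' full double precision, so the document re-reads bit-identically. An empty
#' record list produces a valid empty document.
#'
#' @param records List of [species_record()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_species_table <- function(records, path) {
  lapply(records, validate_species_record)
  ids <- vapply(records, function(r) r$species_id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate species_id: ",
         paste(sQuote(unique(ids[duplicated(ids)])), collapse = ", "),
         call. = FALSE)
  }
  doc <- list(
    format_version = "1.0",
    index_base = 0L,
    species = lapply(records, function(r) {
      states <- stats::setNames(
        lapply(r$states, function(s) {
          list(
            energy = s$energy,
            energy_unit = s$energy_unit,
            charges = s$charges,
            method_label = s$method_label,
            charge_scheme_label = s$charge_scheme_label
          )
        }),
        vapply(r$states, function(s) s$label, character(1))
      )
      out <- list(
        species_id = r$species_id,
        alpha_atom_indices = r$alpha_atom_indices,
        states = states
      )
      if (is.finite(r$gibbs_activation)) {
        out$gibbs_activation_kJmol <- r$gibbs_activation
      }
      if (nzchar(r$notes)) out$notes <- r$notes
      out
    })
  )
  tryCatch(
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                         pretty = TRUE),
    error = function(e) {
      stop("failed to write species document '", path, "': ",
           conditionMessage(e), call. = FALSE)
    }
  )
  invisible(path)
}

#' Tabular summary of species records
#'
#' One row per species: state energies in hartree and the alpha-carbon
#' Hirshfeld charges of the N and N+1 states, as used by the condensed Fukui
#' functions. Useful as a flat CSV export of the nested species document.
#'
#' @param records List of [species_record()] objects.
#' @return A tibble with columns `species_id`, `E_N`, `E_Nm1`, `E_Np1`
#'   (hartree), `q2_N`, `q5_N`, `q2_Np1`, `q5_Np1` (e).
#' @export
species_summary_tbl <- function(records) {
  purrr::map_dfr(records, function(r) {
    to_hartree <- function(s) {
      if (s$energy_unit == "eV") s$energy / thio_constants$hartree_ev else s$energy
    }
    i2 <- r$alpha_atom_indices[1] + 1L
    i5 <- r$alpha_atom_indices[2] + 1L
    sN <- get_state(r, "N"); sP <- get_state(r, "N+1")
    tibble::tibble(
      species_id = r$species_id,
      E_N = to_hartree(sN),
      E_Nm1 = to_hartree(get_state(r, "N-1")),
      E_Np1 = to_hartree(sP),
      q2_N = sN$charges[i2],
      q5_N = sN$charges[i5],
      q2_Np1 = sP$charges[i2],
      q5_Np1 = sP$charges[i5]
    )
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
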
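#' Parse an ORCA-style single-point output into an electronic state
#'
#' Reads the total electronic energy from the line containing the literal
#' token `FINAL SINGLE POINT ENERGY` and the per-atom Hirshfeld charges from
#' the `HIRSHFELD ANALYSIS` table (atom index, element, charge columns).
#' The energy is in hartree; atom ordering is preserved as printed. Exactly
#' one energy marker line and one Hirshfeld block are required: duplicates
#' are an ambiguity error rather than last-wins, because a silent misparse is
#' worse than a failure. Mulliken or Loewdin charge blocks are ignored.
#'
#' @param text Output file contents: a single string or a character vector of
#'   lines.
#' @param electron_count_label State label for the resulting object:
#'   `"N"`, `"N-1"` or `"N+1"`.
#' @param method_label Optional level-of-theory label to attach.
#' @return An [electronic_state()] with energy in hartree.
#' @examples
#' txt <- c("FINAL SINGLE POINT ENERGY      -551.123456789012",
#'          "------------------",
#'          "HIRSHFELD ANALYSIS",
#'          "------------------",
#'          "  ATOM     CHARGE      SPIN",
#'          "   0 C    0.100000    0.000000",
#'          "   1 S   -0.050000    0.000000",
#'          "",
#'          "  TOTAL   0.050000")
#' parse_orca_output(txt, "N")
#' @export
parse_orca_output <- function(text, electron_count_label,
                              method_label = "") {
  stopifnot(is.character(text))
  lines <- if (length(text) == 1L && grepl("\n", text, fixed = TRUE)) {
    strsplit(text, "\n", fixed = TRUE)[[1]]
  } else {
    text
  }

  e_idx <- grep("FINAL SINGLE POINT ENERGY", lines, fixed = TRUE)
  if (length(e_idx) == 0L) {
    stop("parse error: no 'FINAL SINGLE POINT ENERGY' line found",
         call. = FALSE)
  }
  if (length(e_idx) > 1L) {
    stop("ambiguous output: ", length(e_idx),
         " 'FINAL SINGLE POINT ENERGY' lines (lines ",
         paste(e_idx, collapse = ", "), ")", call. = FALSE)
  }
  e_match <- regmatches(lines[e_idx],
                        regexpr("-?[0-9]+\\.[0-9]+", lines[e_idx]))
  if (length(e_match) != 1L) {
    stop("parse error: malformed energy on line ", e_idx, ": '",
         lines[e_idx], "'", call. = FALSE)
  }
  energy <- as.numeric(e_match)

  h_idx <- grep("HIRSHFELD ANALYSIS", lines, fixed = TRUE)
  if (length(h_idx) == 0L) {
    stop("parse error: no 'HIRSHFELD ANALYSIS' block found", call. = FALSE)
  }
  if (length(h_idx) > 1L) {
    stop("ambiguous output: ", length(h_idx), " 'HIRSHFELD ANALYSIS' blocks",
         call. = FALSE)
  }

  hdr <- grep("^\\s*ATOM\\s+CHARGE", lines)
  hdr <- hdr[hdr > h_idx]
  if (length(hdr) == 0L) {
    stop("parse error: no 'ATOM  CHARGE' header after HIRSHFELD ANALYSIS",
         call. = FALSE)
  }
  row_re <- "^\\s*([0-9]+)\\s+([A-Za-z]{1,2})\\s+(-?[0-9]+\\.[0-9]+)"
  charges <- numeric(0)
  i <- hdr[1] + 1L
  while (i <= length(lines)) {
    ln <- lines[i]
    if (grepl("^\\s*$", ln) || grepl("^\\s*TOTAL", ln)) break
    m <- regexec(row_re, ln)[[1]]
    if (m[1] == -1L) {
      stop("parse error: malformed Hirshfeld charge row on line ", i, ": '",
           ln, "'", call. = FALSE)
    }
    parts <- regmatches(ln, regexec(row_re, ln))[[1]]
    charges <- c(charges, as.numeric(parts[4]))
    i <- i + 1L
  }
  if (length(charges) == 0L) {
    stop("parse error: Hirshfeld block contains no charge rows",
         call. = FALSE)
  }

  electronic_state(
    label = electron_count_label,
    energy = energy,
    energy_unit = "hartree",
    charges = charges,
    method_label = method_label,
    charge_scheme_label = "Hirshfeld"
  )
}
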
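#' Eyring transition-state-theory rate constant
#'
#' `k = gamma (kB T / h) exp(-dG / (R T))` with the CODATA-2018 defining
#' constants. The transmission coefficient defaults to 1. Activation free
#' energies are in kJ/mol (use `unit = "kcal/mol"` to convert explicitly);
#' bimolecular standard-state subtleties are ignored since downstream use is
#' via rate ratios where the prefactor cancels.
#'
#' @param delta_G_activation Gibbs free energy of activation (vector).
#' @param temperature Temperature in K, default 298.15.
#' @param transmission_coeff Transmission coefficient gamma, default 1.
#' @param unit Unit of `delta_G_activation`: `"kJ/mol"` (default) or
#'   `"kcal/mol"`.
#' @return Rate constant(s) in 1/s.
#' @examples
#' eyring_rate(0)               # kB*T/h at 298.15 K, ~6.21e12 /s
#' eyring_rate(50, temperature = 310)
#' @export
eyring_rate <- function(delta_G_activation, temperature = 298.15,
                        transmission_coeff = 1, unit = c("kJ/mol", "kcal/mol")) {
  unit <- match.arg(unit)
  if (any(temperature <= 0)) {
    stop("temperature must be > 0 K", call. = FALSE)
  }
  if (any(transmission_coeff <= 0)) {
    stop("transmission coefficient must be > 0", call. = FALSE)
  }
  dG <- delta_G_activation * 1000          # kJ/mol -> J/mol
  if (unit == "kcal/mol") dG <- dG * 4.184
  with(thio_constants,
       transmission_coeff * (kB * temperature / h) *
         exp(-dG / (R * temperature)))
}

#' Log10 rate constant relative to a reference barrier
#'
#' Decades between two Eyring rates at the same temperature:
#' `-(dG - dG_ref) / (R T ln 10)`. The transmission coefficient and the
#' `kB T / h` prefactor cancel, so only the barrier difference matters. Used
#' to normalise each derivative's rate to the unmodified parent compound.
#'
#' @param delta_G Activation free energy, kJ/mol (vector).
#' @param delta_G_ref Reference activation free energy, kJ/mol.
#' @param temperature Temperature in K, default 298.15.
#' @return log10(k / k_ref), in decades.
#' @export
log10_relative_rate <- function(delta_G, delta_G_ref, temperature = 298.15) {
  if (any(temperature <= 0)) {
    stop("temperature must be > 0 K", call. = FALSE)
  }
  -(delta_G - delta_G_ref) * 1000 / (thio_constants$R * temperature * log(10))
}

#' Squared Pearson correlation
#'
#' The square of the sample Pearson correlation coefficient, the statistic
#' used to benchmark levels of theory against experimental rate data. Both
#' inputs must be non-constant and of equal length >= 3.
#'
#' @param xs,ys Numeric vectors.
#' @return r-squared in `[0, 1]`.
#' @export
pearson_r2 <- function(xs, ys) {
  if (length(xs) != length(ys)) {
    stop("xs and ys must have equal length", call. = FALSE)
  }
  if (length(xs) < 3L) {
    stop("need at least 3 paired observations", call. = FALSE)
  }
  if (stats::sd(xs) == 0 || stats::sd(ys) == 0) {
    stop("correlation undefined for constant input", call. = FALSE)
  }
  stats::cor(xs, ys)^2
}

#' Eyring rates and relative logs for a table of species
#'
#' Tibble-in / tibble-out wrapper around [eyring_rate()] and
#' [log10_relative_rate()]: computes the absolute TST rate constant for each
#' row and, when a reference species is named, the log10 rate ratio versus
#' that reference.
#'
#' @param data Data frame with columns `species_id` and `delta_G_kJmol`.
#' @param temperature Temperature in K, default 298.15.
#' @param transmission_coeff Transmission coefficient, default 1.
#' @param reference_id Optional `species_id` whose barrier defines the
#'   denominator of the rate ratio.
#' @return The input tibble with `k` (1/s) and, if `reference_id` is given,
#'   `log10_k_rel` (decades) appended.
#' @export
eyring_table <- function(data, temperature = 298.15, transmission_coeff = 1,
                         reference_id = NULL) {
  stopifnot(is.data.frame(data))
  if (!all(c("species_id", "delta_G_kJmol") %in% names(data))) {
    stop("`data` needs columns species_id and delta_G_kJmol", call. = FALSE)
  }
  out <- dplyr::mutate(
    tibble::as_tibble(data),
    k = eyring_rate(.data$delta_G_kJmol, temperature = temperature,
                    transmission_coeff = transmission_coeff)
  )
  if (!is.null(reference_id)) {
    ref <- out$delta_G_kJmol[out$species_id == reference_id]
    if (length(ref) != 1L) {
      stop("reference_id '", reference_id, "' matches ", length(ref),
           " rows (need exactly 1)", call. = FALSE)
    }
    out <- dplyr::mutate(
      out,
      log10_k_rel = log10_relative_rate(.data$delta_G_kJmol, ref,
                                        temperature = temperature)
    )
  }
  out
}
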
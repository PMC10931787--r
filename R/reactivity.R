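#' Coefficients of the fitted reactivity model
#'
#' The model for the log10 rate constant of singlet-oxygen cycloaddition
#' relative to unmodified thiophene (gas phase, wB97X-D3/def2-TZVP
#' reference):
#'
#' `log10(k/kH)_ideal = 8.61 (q2 + q5) - 76.00 F + 53.25`, with
#' `F = log10( chi_M (S + alpha/(s2+ + s5+)) + beta/(s2+ + s5+) )`,
#' `alpha = 30.75` 1/(eV^2 e) and `beta = 0.03822` eV^-1 e.
#'
#' Defaults are exactly the fitted constants; every coefficient can be
#' overridden for refitting experiments.
#'
#' @param c_charge Coefficient on `q2 + q5`, per e. Default 8.61.
#' @param c_F Coefficient on the F term. Default -76.00.
#' @param c_intercept Intercept. Default 53.25.
#' @param alpha Softness-scaling constant inside F, 1/(eV^2 e). Default 30.75.
#' @param beta Additive constant inside F, eV^-1 e. Default 0.03822.
#' @return An object of class `model_coefficients`.
#' @export
model_coefficients <- function(c_charge = 8.61, c_F = -76.00,
                               c_intercept = 53.25, alpha = 30.75,
                               beta = 0.03822) {
  structure(
    list(c_charge = c_charge, c_F = c_F, c_intercept = c_intercept,
         alpha = alpha, beta = beta),
    class = "model_coefficients"
  )
}

#' Coefficients of the methanol calibration
#'
#' Affine map from the ideal (gas-phase, vs unmodified thiophene) scale to
#' the experimental methanol scale (vs 2-tert-butylthiophene):
#' `log10(k/k2T)_MeOH = 0.525 log10(k/kH)_ideal + 8.646`.
#'
#' @param slope Default 0.525.
#' @param intercept Default 8.646.
#' @return An object of class `calibration_coefficients`.
#' @export
calibration_coefficients <- function(slope = 0.525, intercept = 8.646) {
  structure(list(slope = slope, intercept = intercept),
            class = "calibration_coefficients")
}

#' The F term of the reactivity model
#'
#' `F = log10( chi_M (S_global + alpha/sigma) + beta/sigma )` with
#' `sigma = s2_plus + s5_plus`. The term couples electronegativity, global
#' softness and the condensed local softness of the two alpha carbons; it
#' carries almost all of the model's predictive power and enters with a
#' negative coefficient, so larger F means lower reactivity. Domain
#' violations (non-positive sigma or a non-positive logarithm argument) are
#' errors, not protected values: the fitted constants presuppose descriptors
#' in their valid ranges.
#'
#' @param chi_M Mulliken electronegativity, eV (vector).
#' @param S_global Global softness, 1/eV.
#' @param s2_plus,s5_plus Condensed local softness at the 2- and 5-carbons,
#'   eV^-1 e.
#' @param coeffs A [model_coefficients()].
#' @return F (dimensionless, base-10 log scale).
#' @examples
#' # chi_M = 2 eV, S = 0.5 1/eV, sigma = 3.075 eV^-1 e:
#' # inner = 2*(0.5 + 10) + 0.03822/3.075 = 21.012429..., F = 1.322477
#' f_term(2, 0.5, 1.5, 1.575)
#' @export
f_term <- function(chi_M, S_global, s2_plus, s5_plus,
                   coeffs = model_coefficients()) {
  sigma <- s2_plus + s5_plus
  if (any(sigma <= 0)) {
    stop("s2_plus + s5_plus must be > 0 (got ", min(sigma), ")",
         call. = FALSE)
  }
  inner <- chi_M * (S_global + coeffs$alpha / sigma) + coeffs$beta / sigma
  if (any(inner <= 0)) {
    stop("argument of the F-term logarithm is non-positive (",
         min(inner), "); descriptors outside the model's domain",
         call. = FALSE)
  }
  log10(inner)
}

#' Predicted log10 relative rate on the ideal scale
#'
#' Evaluates `c_charge (q2 + q5) + c_F F + c_intercept` for vectors of
#' descriptor values; see [f_term()] for F.
#'
#' @inheritParams f_term
#' @param q2,q5 N-state Hirshfeld charges at the alpha carbons, e.
#' @return log10(k/kH) on the ideal (gas-phase) scale, in decades.
#' @export
predict_log_krel_ideal <- function(q2, q5, chi_M, S_global, s2_plus, s5_plus,
                                   coeffs = model_coefficients()) {
  Fv <- f_term(chi_M, S_global, s2_plus, s5_plus, coeffs)
  coeffs$c_charge * (q2 + q5) + coeffs$c_F * Fv + coeffs$c_intercept
}

#' Map ideal-scale predictions onto the methanol scale
#'
#' Affine calibration `slope * x + intercept` taking the gas-phase
#' log10(k/kH) prediction to the experimental log10(k/k2T) scale measured in
#' methanol against 2-tert-butylthiophene.
#'
#' @param log_krel_ideal Ideal-scale values (vector).
#' @param cal A [calibration_coefficients()].
#' @return Methanol-scale values, decades.
#' @examples
#' calibrate_to_methanol(-3.39)  # 6.866
#' @export
calibrate_to_methanol <- function(log_krel_ideal,
                                  cal = calibration_coefficients()) {
  cal$slope * log_krel_ideal + cal$intercept
}

#' Efficiency/safety classification of photosensitizers
#'
#' A photosensitizer resistant to singlet-oxygen self-oxidation can sustain
#' photodynamic action ("efficient"); one that degrades is "safer" but less
#' potent. The rule: efficient iff `log10(k/kH)_ideal <= -3`, or, when only
#' the methanol scale is available, `log10(k/k2T)_MeOH <= -4`. Thresholds
#' are inclusive on the efficient side. When both scales are present the
#' ideal-scale verdict wins; a warning is raised if they disagree, since the
#' two thresholds are independent rules on their own scales.
#'
#' @param log_krel_ideal Ideal-scale values (vector; may contain NA).
#' @param log_krel_methanol Methanol-scale values (vector; may contain NA).
#' @param threshold_ideal Default -3.
#' @param threshold_methanol Default -4.
#' @return A tibble with columns `classification` (`"efficient"` or
#'   `"safer"`) and `threshold_basis` (`"ideal"` or `"methanol"`).
#' @export
classify_reactivity <- function(log_krel_ideal = NA_real_,
                                log_krel_methanol = NA_real_,
                                threshold_ideal = -3,
                                threshold_methanol = -4) {
  n <- max(length(log_krel_ideal), length(log_krel_methanol))
  ideal <- rep_len(log_krel_ideal, n)
  meoh <- rep_len(log_krel_methanol, n)
  if (all(is.na(ideal) & is.na(meoh))) {
    stop("classification needs at least one of the ideal or methanol scales",
         call. = FALSE)
  }
  basis <- ifelse(!is.na(ideal), "ideal", "methanol")
  verdict <- ifelse(
    basis == "ideal",
    ifelse(ideal <= threshold_ideal, "efficient", "safer"),
    ifelse(meoh <= threshold_methanol, "efficient", "safer")
  )
  both <- !is.na(ideal) & !is.na(meoh)
  if (any(both)) {
    meoh_verdict <- ifelse(meoh[both] <= threshold_methanol,
                           "efficient", "safer")
    if (any(meoh_verdict != verdict[both])) {
      warning("ideal- and methanol-scale verdicts disagree for ",
              sum(meoh_verdict != verdict[both]),
              " species; the ideal-scale verdict is reported",
              call. = FALSE)
    }
  }
  if (any(is.na(verdict))) {
    stop("classification undefined: a species has neither scale",
         call. = FALSE)
  }
  tibble::tibble(classification = verdict, threshold_basis = basis)
}

#' Predict reactivity for a feature table
#'
#' The main pipeline verb: takes the per-species feature tibble from
#' [thiophene_features()] (or any data frame with columns `q2`, `q5`,
#' `s2_plus`, `s5_plus`, `S_global`, `chi_M`) and appends the F term, the
#' ideal-scale prediction, optionally the methanol calibration, and the
#' efficiency/safety classification.
#'
#' @param data Feature data frame (one row per species).
#' @param coeffs A [model_coefficients()].
#' @param cal A [calibration_coefficients()], or `NULL` to skip the
#'   methanol scale.
#' @param classify Append the classification columns? Default `TRUE`.
#' @return The input tibble with `F_term`, `log_krel_ideal`,
#'   `log_krel_methanol` (if `cal` is given) and, when `classify = TRUE`,
#'   `classification` and `threshold_basis` appended.
#' @examples
#' library(dplyr)
#' fixture_spec(n_species = 5, seed = 1) |>
#'   generate_species() |>
#'   thiophene_features() |>
#'   predict_reactivity()
#' @export
predict_reactivity <- function(data, coeffs = model_coefficients(),
                               cal = calibration_coefficients(),
                               classify = TRUE) {
  stopifnot(is.data.frame(data))
  need <- c("q2", "q5", "s2_plus", "s5_plus", "S_global", "chi_M")
  miss <- setdiff(need, names(data))
  if (length(miss) > 0L) {
    stop("feature table is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  out <- dplyr::mutate(
    tibble::as_tibble(data),
    F_term = f_term(.data$chi_M, .data$S_global, .data$s2_plus,
                    .data$s5_plus, coeffs),
    log_krel_ideal = coeffs$c_charge * (.data$q2 + .data$q5) +
      coeffs$c_F * .data$F_term + coeffs$c_intercept
  )
  if (!is.null(cal)) {
    out <- dplyr::mutate(
      out, log_krel_methanol = calibrate_to_methanol(.data$log_krel_ideal, cal)
    )
  }
  if (classify) {
    cls <- classify_reactivity(
      out$log_krel_ideal,
      if (!is.null(cal)) out$log_krel_methanol else NA_real_
    )
    out <- dplyr::bind_cols(out, cls)
  }
  out
}

#' Fit an affine calibration between two reactivity scales
#'
#' Ordinary least squares of observed (experimental-scale) values on
#' computed ideal-scale values, the procedure that produced the fixed
#' methanol calibration. Returns the slope/intercept as
#' [calibration_coefficients()] plus the fit's r-squared (identical to
#' [pearson_r2()] of the two vectors for a simple linear fit).
#'
#' @param ideal Computed ideal-scale values (length >= 3, non-constant).
#' @param observed Observed values, same length.
#' @return An object of class `thio_calibration`: list with `coefficients`
#'   (a [calibration_coefficients()]), `r2`, `fit` (the underlying `lm`),
#'   and `data`.
#' @export
fit_linear_calibration <- function(ideal, observed) {
  if (length(ideal) != length(observed)) {
    stop("ideal and observed must have equal length", call. = FALSE)
  }
  if (length(ideal) < 3L) {
    stop("need at least 3 paired observations", call. = FALSE)
  }
  if (stats::sd(ideal) == 0) {
    stop("degenerate design: ideal values are constant", call. = FALSE)
  }
  d <- data.frame(ideal = ideal, observed = observed)
  fit <- stats::lm(observed ~ ideal, data = d)
  structure(
    list(
      coefficients = calibration_coefficients(
        slope = unname(stats::coef(fit)[["ideal"]]),
        intercept = unname(stats::coef(fit)[["(Intercept)"]])
      ),
      r2 = if (stats::sd(observed) == 0) NA_real_ else pearson_r2(ideal, observed),
      fit = fit,
      data = tibble::as_tibble(d)
    ),
    class = "thio_calibration"
  )
}

#' @export
print.thio_calibration <- function(x, ...) {
  cat("<thio_calibration>\n")
  cat(sprintf("  observed = %.6g * ideal + %.6g   (r2 = %.6g, n = %d)\n",
              x$coefficients$slope, x$coefficients$intercept, x$r2,
              nrow(x$data)))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname fit_linear_calibration
#' @param x,... A `thio_calibration` object; further arguments ignored.
#' @export
tidy.thio_calibration <- function(x, ...) {
  tibble::tibble(
    term = c("intercept", "slope"),
    estimate = c(x$coefficients$intercept, x$coefficients$slope),
    std.error = suppressWarnings(summary(x$fit))$coefficients[, "Std. Error"]
  )
}

#' @rdname fit_linear_calibration
#' @export
glance.thio_calibration <- function(x, ...) {
  tibble::tibble(
    r.squared = x$r2,
    sigma = suppressWarnings(summary(x$fit))$sigma,
    nobs = nrow(x$data)
  )
}

#' Baseline one-descriptor model: log relative rate vs log electronegativity
#'
#' The simplest reactivity correlation: OLS of the log10 relative rate on
#' log10 of the Mulliken electronegativity. An optional exclusion list drops
#' outlier species (fused six-membered-ring scaffolds are the known failure
#' mode of this one-descriptor picture) before fitting.
#'
#' @param data Data frame with columns `species_id`, `chi_M` and the
#'   response named by `response`.
#' @param response Name of the response column, default `"log_krel"`.
#' @param exclude Character vector of `species_id` values to drop before
#'   fitting.
#' @return An object of class `thio_baseline`: list with `slope`,
#'   `intercept`, `r2`, `fit`, `excluded`, `data`.
#' @export
fit_baseline_chiM <- function(data, response = "log_krel", exclude = NULL) {
  stopifnot(is.data.frame(data))
  need <- c("species_id", "chi_M", response)
  miss <- setdiff(need, names(data))
  if (length(miss) > 0L) {
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  keep <- tibble::as_tibble(data)
  if (!is.null(exclude)) {
    keep <- dplyr::filter(keep, !.data$species_id %in% exclude)
  }
  if (nrow(keep) < 3L) {
    stop("need at least 3 species after exclusions", call. = FALSE)
  }
  if (any(keep$chi_M <= 0)) {
    stop("chi_M must be > 0 for the log; offending species: ",
         paste(keep$species_id[keep$chi_M <= 0], collapse = ", "),
         call. = FALSE)
  }
  d <- data.frame(log_chi = log10(keep$chi_M), y = keep[[response]])
  if (stats::sd(d$log_chi) == 0) {
    stop("degenerate design: log10(chi_M) is constant", call. = FALSE)
  }
  fit <- stats::lm(y ~ log_chi, data = d)
  structure(
    list(
      slope = unname(stats::coef(fit)[["log_chi"]]),
      intercept = unname(stats::coef(fit)[["(Intercept)"]]),
      r2 = if (stats::sd(d$y) == 0) 1 else pearson_r2(d$log_chi, d$y),
      fit = fit,
      excluded = exclude %||% character(0),
      response = response,
      data = keep
    ),
    class = "thio_baseline"
  )
}

#' @export
print.thio_baseline <- function(x, ...) {
  cat("<thio_baseline>\n")
  cat(sprintf("  y = %.6g * log10(chi_M) + %.6g   (r2 = %.6g, n = %d",
              x$slope, x$intercept, x$r2, nrow(x$data)))
  if (length(x$excluded) > 0L) {
    cat(", excluded: ", paste(x$excluded, collapse = ", "), sep = "")
  }
  cat(")\n")
  invisible(x)
}

#' @rdname fit_baseline_chiM
#' @param x,... A `thio_baseline` object; further arguments ignored.
#' @export
tidy.thio_baseline <- function(x, ...) {
  tibble::tibble(
    term = c("intercept", "log10(chi_M)"),
    estimate = c(x$intercept, x$slope),
    std.error = suppressWarnings(summary(x$fit))$coefficients[, "Std. Error"]
  )
}

#' @rdname fit_baseline_chiM
#' @export
glance.thio_baseline <- function(x, ...) {
  tibble::tibble(
    r.squared = x$r2,
    sigma = suppressWarnings(summary(x$fit))$sigma,
    nobs = nrow(x$data),
    n.excluded = length(x$excluded)
  )
}

#' Sample standard deviation of prediction residuals
#'
#' On the log10 rate scale one residual SD unit is one order of magnitude in
#' the relative rate constant.
#'
#' @param predicted,reference Equal-length numeric vectors.
#' @return Sample SD of `predicted - reference`.
#' @export
residual_sd <- function(predicted, reference) {
  if (length(predicted) != length(reference)) {
    stop("predicted and reference must have equal length", call. = FALSE)
  }
  stats::sd(predicted - reference)
}
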
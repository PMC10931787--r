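---
title: "Predicting singlet-oxygen reactivity of thiophene photosensitizers: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting singlet-oxygen reactivity of thiophene photosensitizers: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thioreact)
```

## The problem

A thiophene-containing photosensitizer produces singlet oxygen under
irradiation, and that same singlet oxygen can destroy the sensitizer by
[4+2] cycloaddition across the 2- and 5-carbons of the thiophene ring. A
molecule that resists this self-oxidation sustains photodynamic action
("efficient"); one that succumbs degrades harmlessly ("safer"). `thioreact`
predicts which side of that divide a candidate falls on from
electronic-structure descriptors alone, with no transition-state search.

## Conceptual-DFT descriptors

The input unit is a species triplet: total energies and per-atom Hirshfeld
charges for the N, N−1 and N+1 electron states, all at the geometry
optimised for N electrons. All descriptors are vertical finite differences:

* VIP = E(N−1) − E(N); VEA = E(N) − E(N+1), both in eV. A negative VEA
  (unbound anion) is legitimate and is never clamped: downstream formulas
  only require χ_M > 0.
* χ_M = (VIP+VEA)/2, μ = −χ_M, η = VIP − VEA, S = 1/η, ω = μ²/2η. A
  non-positive gap η leaves S and ω undefined; by default this is an error
  rather than an NA, because every downstream quantity needs S.
* f⁺_k = q_k(N) − q_k(N+1), f⁻_k = q_k(N−1) − q_k(N),
  f⁰_k = (f⁺_k + f⁻_k)/2, s±_k = S·f±_k. On charge-conserving inputs the
  f⁺ values sum to exactly 1 e, which the test suite asserts at machine
  precision.

No orbital-energy (Koopmans-style) fallback is provided: the
finite-difference definitions are the ones the model was built on, and
mixing conventions silently would corrupt predictions. The
hartree-to-electronvolt factor is the CODATA-2018 value 27.211386245988,
stored in a single place (`thio_constants`); conversions are always
explicit. The nucleophilicity index is relative by construction, so it
requires a caller-supplied reference energy and is never defaulted; it is
computed for completeness but unused by the reactivity model.

## The reactivity model and its calibration

The fitted model for the log₁₀ rate of singlet-oxygen cycloaddition
relative to unmodified thiophene is

$$\log_{10}(k/k_H)_{ideal} = 8.61\,(q_2+q_5) - 76.00\,F + 53.25,$$
$$F = \log_{10}\!\left(\chi_M\left[S + \frac{\alpha}{s_2^+ + s_5^+}\right] +
\frac{\beta}{s_2^+ + s_5^+}\right),$$

with α = 30.75 (eV²·e)⁻¹ and β = 0.03822 eV⁻¹·e. Three numerical choices
deserve comment:

* **All logarithms are base 10.** The response scale is "orders of
  magnitude of relative rate", and the model's residual SD is itself
  described as one order of magnitude, so decades are the natural unit
  throughout, including inside F.
* **Bracket grouping.** F is evaluated as
  `log10(chi_M * (S + alpha/sigma) + beta/sigma)` with
  σ = s₂⁺ + s₅⁺. This is the only grouping consistent with treating
  `beta/sigma` as an additive term and `chi_M [S + alpha/sigma]` as a
  product, which is how the two pieces behave: F rises with χ_M at fixed
  softness and falls as σ grows (both checked as monotonicity tests).
* **No protected operators.** σ ≤ 0 or a non-positive logarithm argument
  is an error, not a patched value: the fitted constants presuppose
  descriptors in their valid ranges, and a silently "protected" prediction
  would be meaningless. (The symbolic-regression engine, which must search
  through arbitrary expressions, is the opposite case and does use
  protected semantics.)

The experimental calibration
$\log_{10}(k/k_{2T})_{MeOH} = 0.525 x + 8.646$ maps the ideal scale onto
rates measured in methanol against 2-tert-butylthiophene.
`fit_linear_calibration()` reproduces this kind of adjustment by ordinary
least squares for any paired (computed, observed) set. The baseline
one-descriptor model — OLS of the response on log₁₀ χ_M — is retained as
`fit_baseline_chiM()` with caller-controlled outlier exclusion, because
fused six-membered-ring scaffolds are a known failure mode of the
one-descriptor picture and exclusion decisions belong to the analyst, not
the library.

### Classification

Efficient iff log₁₀(k/k_H)_ideal ≤ −3; with only the methanol scale,
efficient iff log₁₀(k/k₂T)_MeOH ≤ −4. Both thresholds are inclusive on the
efficient side, matching the "≤" phrasing of the rule. The two thresholds
are **not** images of one another under the calibration (0.525·(−3)+8.646 =
+7.07, far from −4), so they are treated as independent rules on their own
scales; when both scales are present and disagree, the ideal-scale verdict
is reported and a warning is attached rather than silently resolving the
tension.

## Eyring kinetics

`eyring_rate()` implements k = γ(k_B T/h)·exp(−ΔG‡/RT) with the exact SI
defining constants, default T = 298.15 K and γ = 1. Barriers are kJ/mol;
kcal/mol only via an explicit flag. Standard-state subtleties of the
bimolecular cycloaddition are ignored deliberately: every downstream use is
a rate *ratio*, where the prefactor and standard-state terms cancel.
`log10_relative_rate()` therefore depends only on ΔΔG‡ and telescopes
exactly. The level-of-theory benchmarking statistic is the square of the
sample Pearson correlation (`pearson_r2()`), which errors on constant input
rather than returning NaN.

## Symbolic regression by genetic programming

`gp_evolve()` is a from-scratch tree-GP engine over the function set add,
sub, mul, div, sqrt, log, inv. The configuration mirrors the study setup:
population 5000, 10000 generations, crossover 0.7, subtree mutation 0.1,
subsample fraction 0.9, parsimony coefficient 0.01, R² as the fitness
metric. Choices the configuration leaves open were fixed as follows and are
all overridable in `gp_config()`:

* **Fitness R²** is the squared Pearson correlation between predictions
  and response. Constant or non-finite predictions score 0 — a tree that
  predicts nothing should not poison selection with errors or NaN.
* **Selection** is tournament selection (size 20); the remaining 0.2 of the
  operator probability mass is plain reproduction, the minimal-assumption
  reading when only crossover and mutation probabilities are named.
* **Protected semantics**: div(a,b) = 1 when |b| < 1e−6; log(x) =
  log₁₀|x| with log(0) = 0; sqrt|x|; inv(x) = 1 when |x| < 1e−6. These
  keep evaluation total on finite inputs (a tested invariant). The log is
  base 10 to match the response scale.
* **Structure limits**: ramped half-and-half initialisation at depths 2–6,
  hard depth cap 8 enforced by rejection (bounded retries, then the parent
  is kept), mutant subtrees grown to depth ≤ 4, ephemeral constants
  uniform on (−5, 5), terminals are constants with probability 0.3.
* **Elitism and monotonicity.** Each generation the population is scored
  on a fresh subsample of ⌈0.9·n⌉ rows; the generation's best (penalised)
  individual is re-scored on the full data, and the best-so-far individual
  by full-data raw R² is tracked, recorded in the history, and copied into
  the next generation. Tracking best-so-far on the *full* data makes the
  history curve non-decreasing by construction — with per-generation
  subsampling alone, the "best" would jitter with the subsample — and
  makes same-seed reruns bit-identical, both of which are tested.

Desk-scale recovery experiments (the ones run in the test suite) use
population 200 × 50 generations for a planted linear law and 1000 × 200
for a planted log-composite law on 200 rows; these complete in seconds to
half a minute on one CPU while the full-scale configuration remains
available for real refits.

## Synthetic fixtures

`generate_species()` fabricates species triplets: N-state energies are
arbitrary large negative values, VIP and VEA are drawn uniformly in 6–10 eV
and −0.5–3 eV (disjoint ranges, so the gap is always positive, matching a
closed-shell screening set), and the N±1 energies are back-computed from
them. Charges are built the other way around: per-atom condensed-Fukui
distributions are drawn first — each alpha carbon receives U(0.08, 0.30)
and the remainder is spread over the other atoms so the total is exactly
1 e — and the N±1 charges are derived by subtraction. This makes the Fukui
sum rules exact (a sharp test, not an approximate one) and keeps the summed
alpha local softness strictly positive, so every generated species lies in
the reactivity model's domain. Regression fixtures draw descriptors in
model-plausible ranges (χ_M 2–6 eV, S 0.1–0.6 eV⁻¹, s₂⁺/s₅⁺ 0.025–0.75
eV⁻¹·e, q ±0.15 e), which keeps the F-term argument positive by
construction; planted responses are the fitted model itself, a linear law
3.2x₀ − 1.5x₁, or a log-composite log₁₀(2x₀ + 0.5/x₁) with the same
descriptor-like feature ranges.

What the fixtures deliberately do **not** emulate: real thiophene
electronic structure (no correlation between charges and energies, no
substituent chemistry), solvent effects, or the narrow descriptor
correlations of a real congeneric series. Passing tests therefore
demonstrate the correctness of the arithmetic, the parsers, the fitting and
the search — not transferability of the fitted constants to new chemistry,
which only quantum-chemistry inputs can probe.

## File formats and parsing

Species triplets live in a JSON document (format_version, index_base 0,
per-species states keyed N/N−1/N+1). Numbers are written with 17
significant digits so read(write(x)) is bit-identical — an invariant the
suite checks — since 15-digit default printing silently perturbs energies
in the 10⁻¹³ hartree range. The ORCA-style parser takes the energy from the
unique `FINAL SINGLE POINT ENERGY` line and charges from the unique
`HIRSHFELD ANALYSIS` table; duplicated markers are an ambiguity *error*
rather than last-wins, and malformed charge rows are reported with their
line number, because a silent misparse is worse than a failure. Atom
indices are 0-based end to end, matching the ORCA printing convention.
Mulliken/Löwdin charge blocks and geometry handling are out of scope.

## Problem sizes and limitations

The test suite and `scripts/acceptance.R` use 200-species descriptor
screens, 90-row regression tables (the size of a realistic derivative
screen), 100-replicate noise studies, and the two desk-scale GP runs above;
everything is seeded and completes in about a minute altogether. Known
limitations: the fitted constants are specific to the level of theory and
charge scheme they were derived with; the classifier inherits the
independent (non-commuting) thresholds described above; the GP engine does
no constant optimisation beyond ephemeral constants and mutation, so exact
constant recovery relies on correlation-invariance of the fitness rather
than numerical refinement; and absolute Eyring rates ignore bimolecular
standard-state corrections, so only ratios should be interpreted.
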
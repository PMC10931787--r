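# Hand-built species records with chosen state energies (eV or hartree)
# and charges, used across the unit tests.

make_record <- function(id = "t1",
                        E_N = -100, E_Nm1 = -95, E_Np1 = -101,
                        unit = "eV",
                        qN = c(0.10, -0.05, -0.05),
                        qM = qN, qP = qN,
                        alpha = c(0L, 1L),
                        gibbs = NA_real_) {
  st <- function(label, e, q) {
    electronic_state(label, e, q, energy_unit = unit,
                     method_label = "test")
  }
  species_record(
    species_id = id,
    states = list(st("N", E_N, qN), st("N-1", E_Nm1, qM),
                  st("N+1", E_Np1, qP)),
    alpha_atom_indices = alpha,
    gibbs_activation = gibbs
  )
}

# Independent brute-force descriptor oracle: direct arithmetic on the raw
# record fields, bypassing the package's descriptor functions. Used to
# cross-check global and condensed descriptors.
oracle_descriptors <- function(rec) {
  ev <- function(s) if (s$energy_unit == "hartree") s$energy * 27.211386245988 else s$energy
  states <- stats::setNames(rec$states,
                            vapply(rec$states, `[[`, "", "label"))
  eN <- ev(states[["N"]]); eM <- ev(states[["N-1"]]); eP <- ev(states[["N+1"]])
  vip <- eM - eN
  vea <- eN - eP
  chi <- (vip + vea) / 2
  eta <- vip - vea
  S <- 1 / eta
  qN <- states[["N"]]$charges
  qM <- states[["N-1"]]$charges
  qP <- states[["N+1"]]$charges
  fp <- qN - qP
  fm <- qM - qN
  list(vip = vip, vea = vea, chi_M = chi, mu = -chi, eta = eta,
       S_global = S, omega = chi^2 / (2 * eta),
       f_plus = fp, f_minus = fm, f_zero = (fp + fm) / 2,
       s_plus = S * fp, s_minus = S * fm)
}

rel_err <- function(a, b) {
  denom <- pmax(abs(a), abs(b), 1e-300)
  abs(a - b) / denom
}
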
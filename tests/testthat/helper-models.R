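# Small fixture builders shared across the suite. Everything is generated in
# code; temperatures in degrees C, rate coefficients in L mol^-1 s^-1.

# Temperature-independent toy chemistry with tunable side reactions.
toy_model <- function(kp11 = 0.3, kp12 = 0.3, kp21 = 0.1, kp22 = 0.2,
                      ki = 0.3, ktr = 0, kpm = 0, name = "toy") {
  k <- function(v) if (v > 0) arrhenius_params(v) else NULL
  kinetic_model(
    monomers = monomer_set(c("M1", "M2")),
    k_i = list(k(ki), k(ki)),
    k_p = list(list(k(kp11), k(kp12)), list(k(kp21), k(kp22))),
    k_trM = if (ktr > 0) list(list(k(ktr), k(ktr)), list(k(ktr), k(ktr))),
    k_pm = if (kpm > 0) list(k(kpm), k(kpm)),
    name = name
  )
}

toy_run <- function(target_dp = 50, f2_0 = 0.5, n_chains = 500, ...) {
  run_config(temperature = 140, target_dp = target_dp, f2_0 = f2_0,
             n_chains = n_chains, ...)
}

# Hand-built population for distribution tests.
manual_population <- function(cl, func, status = "dead", branch = 0) {
  cl <- as.integer(cl)
  func <- as.integer(func)
  tibble::tibble(
    chain_id = seq_along(cl), cl = cl, n1 = cl - func, n2 = func, func = func,
    terminal = 1L,
    status = factor(rep_len(status, length(cl)), levels = funcld:::.STATUS_LEVELS),
    branch_count = rep_len(branch, length(cl))
  )
}

# Integer mass-balance check for a trajectory: units in chains + free monomer
# (+ monomer consumed by the suppressed-re-initiation ablation) must equal the
# total monomer ever charged, per monomer type.
expect_mass_balance <- function(traj) {
  pop <- traj$population
  in_chains <- c(sum(pop$n1), sum(pop$n2))
  lhs <- in_chains + traj$free_monomer + traj$aborted_reinitiations
  expect_identical(as.numeric(lhs), as.numeric(traj$added_monomer))
  expect_identical(as.numeric(in_chains), as.numeric(traj$incorporated))
}
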
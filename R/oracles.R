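#' Mean-field (deterministic) conversion profile
#'
#' Integrates the concentration ODEs of the same terminal-model reaction
#' network the stochastic engine simulates, as an independent deterministic
#' twin for verification: monomer balances include initiation, propagation
#' and transfer consumption; active-chain balances are resolved by terminal
#' unit; macromonomer concentration grows by transfer and is consumed by
#' macropropagation. ATRP models additionally carry initiator
#' activation/deactivation, dormant-chain exchange and radical termination.
#' Chain-length-independent coefficients are assumed throughout.
#'
#' @param model A [kinetic_model()].
#' @param run A [run_config()] (concentrations, temperature and stop
#'   criterion are taken from it; chain-resolved settings are ignored).
#' @param times Output time grid, s. Defaults to 400 points spanning an
#'   automatic estimate of the time to the stop conversion.
#' @param rtol,atol Solver tolerances (deSolve::lsoda).
#' @return Tibble with time, species concentrations (mol L^-1), per-monomer
#'   and overall conversions.
#' @export
ode_conversion <- function(model, run, times = NULL, rtol = 1e-8, atol = 1e-12) {
  stopifnot(inherits(model, "kinetic_model"), inherits(run, "run_config"))
  Tk <- celsius_to_kelvin(run$temperature)
  k_i <- vapply(model$k_i, .rate0, 0, temperature = Tk)
  k_p <- matrix(0, 2, 2)
  k_tr <- matrix(0, 2, 2)
  for (i in 1:2) for (j in 1:2) {
    k_p[i, j] <- .rate0(model$k_p[[i]][[j]], Tk)
    if (!run$ideal_mode && !run$disable_transfer) {
      k_tr[i, j] <- .rate0(model$k_trM[[i]][[j]], Tk)
    }
  }
  k_pm <- if (run$ideal_mode || run$disable_macropropagation) c(0, 0) else {
    vapply(model$k_pm, .rate0, 0, temperature = Tk)
  }
  atrp <- !is.null(model$atrp)
  conc_I <- run$total_monomer_conc / run$target_dp
  M0 <- run$total_monomer_conc * c(1 - run$f2_0, run$f2_0)

  if (atrp) {
    ka_i <- .rate0(model$atrp$k_a_i, Tk); kda_i <- .rate0(model$atrp$k_da_i, Tk)
    ka <- .rate0(model$atrp$k_a, Tk);     kda <- .rate0(model$atrp$k_da, Tk)
    kt <- .rate0(model$atrp$k_t_rad, Tk)
    y0 <- c(I = conc_I, M1 = M0[1], M2 = M0[2], P1 = 0, P2 = 0,
            D1 = 0, D2 = 0, R0 = 0,
            Act = conc_I * run$activator_eq, Deact = conc_I * run$deactivator_eq,
            Dead = 0)
    deriv <- function(t, y, parms) {
      M <- c(y[["M1"]], y[["M2"]]); P <- c(y[["P1"]], y[["P2"]])
      Dm <- c(y[["D1"]], y[["D2"]]); Ptot <- sum(P)
      init_j <- k_i * y[["R0"]] * M
      prop_in <- as.vector(t(k_p) %*% P) * M     # gain of terminal j
      prop_out <- P * as.vector(k_p %*% M)       # loss of terminal i
      act_j <- ka * Dm * y[["Act"]]
      deact_j <- kda * P * y[["Deact"]]
      term <- 2 * kt * Ptot * P                  # per-terminal loss
      dI <- -ka_i * y[["I"]] * y[["Act"]] + kda_i * y[["R0"]] * y[["Deact"]]
      dR0 <- -dI - sum(init_j)
      dM <- -init_j - as.vector(t(k_p) %*% P) * M
      dP <- init_j + prop_in - prop_out + act_j - deact_j - term
      dD <- deact_j - act_j
      dAct <- -ka_i * y[["I"]] * y[["Act"]] + kda_i * y[["R0"]] * y[["Deact"]] -
        sum(act_j) + sum(deact_j)
      dDead <- sum(term)
      list(c(dI, dM[1], dM[2], dP[1], dP[2], dD[1], dD[2], dR0,
             dAct, -dAct, dDead))
    }
    k_scale <- max(k_p %*% (M0 + 1e-12)) * conc_I * 1e-4 + 1e-12
  } else {
    y0 <- c(I = conc_I, M1 = M0[1], M2 = M0[2],
            P1 = if (run$ideal_mode) conc_I * (1 - run$f2_0) else 0,
            P2 = if (run$ideal_mode) conc_I * run$f2_0 else 0,
            D = 0)
    if (run$ideal_mode) y0[["I"]] <- 0
    deriv <- function(t, y, parms) {
      M <- c(y[["M1"]], y[["M2"]]); P <- c(y[["P1"]], y[["P2"]])
      init_j <- k_i * y[["I"]] * M
      if (run$ideal_mode) init_j <- c(0, 0)
      # terminal switching by propagation and by transfer-born carriers
      gain_j <- as.vector(t(k_p + k_tr) %*% P) * M
      loss_i <- P * as.vector((k_p + k_tr) %*% M)
      dI <- -sum(init_j)
      dM <- -init_j - as.vector(t(k_p + k_tr) %*% P) * M
      dP <- init_j + gain_j - loss_i
      dD <- sum(P * as.vector(k_tr %*% M)) - sum(k_pm * P) * y[["D"]]
      list(c(dI, dM[1], dM[2], dP[1], dP[2], dD))
    }
    k_scale <- sum((k_p %*% M0) * conc_I)
  }

  if (is.null(times)) {
    rate0 <- max(k_scale, 1e-12)
    t_end <- -log(max(1 - run$stop_conversion, 1e-4)) * sum(M0) / rate0 * 4
    times <- seq(0, t_end, length.out = 400)
  }
  sol <- deSolve::lsoda(y0, times, deriv, parms = NULL, rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0) abort("ODE solver failed")
  out <- as_tibble(as.data.frame(sol))
  out$conversion_m1 <- if (M0[1] > 0) 1 - out$M1 / M0[1] else 0
  out$conversion_m2 <- if (M0[2] > 0) 1 - out$M2 / M0[2] else 0
  out$conversion <- 1 - (out$M1 + out$M2) / sum(M0)
  out
}

#' Closed-form chain-length distribution of the ideal case
#'
#' With instantaneous initiation, equal propagation coefficients and no
#' side reactions, every chain holds one initial unit plus a Poisson number
#' of growth units: `P(CL = 1 + k) = dpois(k, target_dp - 1)`, giving mean
#' chain length exactly `target_dp` at full conversion.
#'
#' @param target_dp Target degree of polymerization (>= 1).
#' @param cl_max Truncation length (default covers +10 standard deviations).
#' @return Tibble `cl`, `fraction` (renormalized on `1..cl_max`).
#' @export
ideal_cld <- function(target_dp, cl_max = NULL) {
  if (target_dp < 1) abort("`target_dp` must be >= 1")
  lambda <- target_dp - 1
  if (is.null(cl_max)) cl_max <- ceiling(target_dp + 10 * sqrt(lambda + 1)) + 1
  cl <- seq_len(cl_max)
  p <- dpois(cl - 1, lambda)
  tibble(cl = cl, fraction = p / sum(p))
}

#' Closed-form functionality distribution of the ideal case
#'
#' In the drift-free case (equal reactivities, `r1 = r2 = 1`) functional
#' units land on chains independently with probability `f2_0` per unit, so
#' the FUNCD is the Poisson-binomial mixture
#' `P(FUNC = F) = sum_CL P(CL) * dbinom(F, CL, f2_0)` over the ideal CLD.
#'
#' @inheritParams ideal_cld
#' @param f2_0 Functional-comonomer feed fraction.
#' @return Tibble `func`, `fraction`.
#' @export
ideal_funcd <- function(target_dp, f2_0, cl_max = NULL) {
  cld <- ideal_cld(target_dp, cl_max)
  func <- 0:max(cld$cl)
  mix <- vapply(func, function(f) {
    sum(cld$fraction * dbinom(f, cld$cl, f2_0))
  }, 0)
  tibble(func = func, fraction = mix / sum(mix))
}

#' Closed-form non-functionalized fraction of the ideal case
#'
#' `f_nonfunctionalized = sum_CL P(CL) (1 - f2_0)^CL` over the ideal CLD.
#'
#' @inheritParams ideal_funcd
#' @return A single number.
#' @export
ideal_fraction_nonfunctionalized <- function(target_dp, f2_0, cl_max = NULL) {
  cld <- ideal_cld(target_dp, cl_max)
  sum(cld$fraction * (1 - f2_0)^cld$cl)
}
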
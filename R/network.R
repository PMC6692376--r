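#' Enumerate the reaction channels of a kinetic model
#'
#' Expands a [kinetic_model()] into the ordered table of elementary reaction
#' channels consumed by the stochastic engine, with every rate coefficient
#' evaluated at the run temperature via [arrhenius_rate()]. Channels whose
#' rate coefficient is exactly zero are omitted. The enumeration order is
#' fixed (initiation, propagation, transfer, macropropagation, quench, ATRP
#' exchange, ATRP termination; within each block terminal-major), so the
#' channel table is byte-identical across runs for a fixed model.
#'
#' For a two-monomer CROP chemistry with all side reactions present this
#' yields 2 initiation + 4 propagation + 4 transfer + 2 macropropagation
#' channels (plus one quench channel when a kinetic terminator is
#' configured). An ATRP chemistry additionally carries initiator
#' activation/deactivation, chain activation/deactivation per terminal unit,
#' and radical termination.
#'
#' @param model A [kinetic_model()].
#' @param temperature Absolute temperature, K.
#' @param quench_kinetic Include the kinetic terminator channel (requires
#'   `model$k_t`); by default quenching is an instantaneous scheduled event,
#'   not a kinetic channel.
#' @return A tibble with columns `kind`, `terminal`, `monomer`, `rate`
#'   (`terminal`/`monomer` are `NA` where not applicable; rates in
#'   L mol^-1 s^-1 for bimolecular channels).
#' @export
build_network <- function(model, temperature, quench_kinetic = FALSE) {
  if (!inherits(model, "kinetic_model")) abort("`model` must be a kinetic_model")
  rows <- list()
  add <- function(kind, terminal, monomer, rate) {
    if (rate > 0) {
      rows[[length(rows) + 1L]] <<- list(kind = kind, terminal = terminal,
                                         monomer = monomer, rate = rate)
    }
  }
  atrp <- !is.null(model$atrp)

  if (!atrp) {
    for (j in 1:2) add("initiation", NA_integer_, j, .rate0(model$k_i[[j]], temperature))
  }
  for (i in 1:2) for (j in 1:2) {
    add("propagation", i, j, .rate0(model$k_p[[i]][[j]], temperature))
  }
  for (i in 1:2) for (j in 1:2) {
    add("transfer_to_monomer", i, j, .rate0(model$k_trM[[i]][[j]], temperature))
  }
  for (i in 1:2) add("macropropagation", i, NA_integer_, .rate0(model$k_pm[[i]], temperature))
  if (quench_kinetic) {
    if (is.null(model$k_t)) abort("quench_kinetic = TRUE but the model has no k_t")
    add("quench", NA_integer_, NA_integer_, .rate0(model$k_t, temperature))
  }
  if (atrp) {
    add("atrp_activation_initiator", NA_integer_, NA_integer_,
        .rate0(model$atrp$k_a_i, temperature))
    add("atrp_deactivation_initiator", NA_integer_, NA_integer_,
        .rate0(model$atrp$k_da_i, temperature))
    for (j in 1:2) add("atrp_initiation", NA_integer_, j, .rate0(model$k_i[[j]], temperature))
    for (i in 1:2) add("atrp_activation", i, NA_integer_, .rate0(model$atrp$k_a, temperature))
    for (i in 1:2) add("atrp_deactivation", i, NA_integer_, .rate0(model$atrp$k_da, temperature))
    add("atrp_termination", NA_integer_, NA_integer_, .rate0(model$atrp$k_t_rad, temperature))
  }
  if (!length(rows)) {
    return(tibble(kind = character(), terminal = integer(),
                  monomer = integer(), rate = double()))
  }
  dplyr::bind_rows(lapply(rows, tibble::as_tibble_row))
}

.kind_code <- function(kind) match(kind, .KIND_LEVELS)

#' Stochastic propensity of each reaction channel
#'
#' Standard SSA propensities from molecule/chain counts: unimolecular
#' channels have `a = k * X`; bimolecular channels `a = k / (N_A V) * X_A *
#' X_B`, where the chain-side count is the number of records matching the
#' channel's status and terminal-unit selector (e.g. a propagation channel
#' `(terminal = i, monomer = j)` counts active chains with terminal unit `i`
#' times free molecules of monomer `j`). ATRP termination between two active
#' radicals uses `a = k / (N_A V) * n * (n - 1)`.
#'
#' @param state A named list (or one-row data frame) of counts:
#'   `n_initiator`, `n_m1`, `n_m2`, `n_active_1`, `n_active_2`,
#'   `n_dormant_1`, `n_dormant_2`, `n_macromonomer`, `n_terminator`,
#'   `n_activator`, `n_deactivator`, `n_r0`. Missing entries default to 0.
#' @param network Channel table from [build_network()].
#' @param bimol_scale `1 / (N_A V)` in mol L^-1 per molecule; see
#'   [run_config()] (it equals `[I]_0 / N_I`).
#' @return The `network` tibble with an added `propensity` column (s^-1).
#' @export
channel_propensities <- function(state, network, bimol_scale) {
  g <- function(nm) {
    v <- state[[nm]]
    if (is.null(v)) 0 else as.numeric(v)
  }
  if (any(vapply(names(state), function(nm) g(nm) < 0, TRUE))) {
    abort("internal consistency error: negative counts in state")
  }
  nact <- c(g("n_active_1"), g("n_active_2"))
  ndorm <- c(g("n_dormant_1"), g("n_dormant_2"))
  nm <- c(g("n_m1"), g("n_m2"))
  a <- vapply(seq_len(nrow(network)), function(r) {
    k <- network$rate[r]
    i <- network$terminal[r]
    j <- network$monomer[r]
    switch(network$kind[r],
      initiation = k * bimol_scale * g("n_initiator") * nm[j],
      propagation = k * bimol_scale * nact[i] * nm[j],
      transfer_to_monomer = k * bimol_scale * nact[i] * nm[j],
      macropropagation = k * bimol_scale * nact[i] * g("n_macromonomer"),
      quench = k * bimol_scale * sum(nact) * g("n_terminator"),
      atrp_activation_initiator = k * bimol_scale * g("n_initiator") * g("n_activator"),
      atrp_deactivation_initiator = k * bimol_scale * g("n_r0") * g("n_deactivator"),
      atrp_initiation = k * bimol_scale * g("n_r0") * nm[j],
      atrp_activation = k * bimol_scale * ndorm[i] * g("n_activator"),
      atrp_deactivation = k * bimol_scale * nact[i] * g("n_deactivator"),
      atrp_termination = k * bimol_scale * sum(nact) * (sum(nact) - 1),
      abort("unknown channel kind")
    )
  }, 0)
  dplyr::mutate(network, propensity = a)
}
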
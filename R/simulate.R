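#' Batch/semi-batch run conditions for the stochastic engine
#'
#' Describes a simulated polymerization batch. Molecule counts follow from
#' the number of simulated initiator molecules `n_chains` (= N_I): the
#' initiator concentration is `[I]_0 = total_monomer_conc / target_dp`, the
#' control volume `V = N_I / (N_A [I]_0)`, and monomer molecule counts are
#' `round(target_dp * N_I)` split by `f2_0`.
#'
#' @param temperature Polymerization temperature, degrees Celsius.
#' @param total_monomer_conc Total initial monomer concentration, mol L^-1.
#' @param target_dp Target degree of polymerization, `[M]_0 / [I]_0`.
#' @param f2_0 Initial mole fraction of the functional comonomer (monomer 2)
#'   in the feed, in `[0, 1]`.
#' @param n_chains Number of simulated initiator molecules N_I (>= 10).
#' @param stop_conversion Overall-conversion stop criterion (complete
#'   monomer conversion is operationalized as >= 0.99 by default; the run
#'   also stops on monomer exhaustion).
#' @param max_time Maximum simulated time, s.
#' @param snapshot_grid Overall conversions at which summary snapshots are
#'   recorded (default every 1 %).
#' @param record_populations_at Overall conversions at which a full copy of
#'   the chain population is stored (the final population is always kept).
#' @param feed_events Tibble/data frame of instantaneous additions with
#'   columns `species` (`"m1"`, `"m2"`, `"initiator"`, `"activator"`),
#'   `amount_eq` (molar equivalents relative to initial initiator),
#'   `trigger` (`"conversion"`, `"conversion_m1"`, `"conversion_m2"`,
#'   `"time"`) and `at` (trigger value). Volume is held constant.
#' @param quench_at Optional scheduled quench (all active/dormant chains ->
#'   dead): a list `list(trigger =, at =)` like a feed event.
#' @param quench_at_end Convert surviving active/dormant chains to dead
#'   chains when the stop criterion is met (terminator added at the end of
#'   the batch). Does not change lengths or functionality.
#' @param ideal_mode Replace kinetic initiation by instantaneous initiation
#'   of all `n_chains` chains at t = 0 and disable all side reactions;
#'   combine with [ideal_model()] for the perfect statistical reference.
#' @param disable_transfer Ablation: drop chain-transfer channels.
#' @param disable_reinitiation_after_transfer Ablation: transfer still forms
#'   the macromonomer, but the monomer-derived fragment does not start a new
#'   chain.
#' @param disable_macropropagation Ablation: drop macropropagation channels.
#' @param activator_eq,deactivator_eq ATRP activator/deactivator charge in
#'   equivalents of initiator.
#' @param record_sequences Record the full ordered monomer sequence of every
#'   chain (memory-heavy; off by default).
#' @param max_events Safety cap on the number of SSA events.
#' @return An object of class `run_config`.
#' @export
run_config <- function(temperature,
                       total_monomer_conc = 3,
                       target_dp = 100,
                       f2_0 = 0.5,
                       n_chains = 1e4,
                       stop_conversion = 0.99,
                       max_time = Inf,
                       snapshot_grid = seq(0.01, 1, by = 0.01),
                       record_populations_at = numeric(),
                       feed_events = NULL,
                       quench_at = NULL,
                       quench_at_end = TRUE,
                       ideal_mode = FALSE,
                       disable_transfer = FALSE,
                       disable_reinitiation_after_transfer = FALSE,
                       disable_macropropagation = FALSE,
                       activator_eq = 1,
                       deactivator_eq = 0,
                       record_sequences = FALSE,
                       max_events = 5e8) {
  if (f2_0 < 0 || f2_0 > 1) abort("`f2_0` must be in [0, 1]")
  if (target_dp < 1) abort("`target_dp` must be >= 1")
  if (n_chains < 10) abort("`n_chains` must be >= 10")
  if (total_monomer_conc <= 0) abort("`total_monomer_conc` must be positive")
  if (!is.null(feed_events)) {
    feed_events <- as_tibble(feed_events)
    need <- c("species", "amount_eq", "trigger", "at")
    if (!all(need %in% names(feed_events))) {
      abort("`feed_events` needs columns species, amount_eq, trigger, at")
    }
    bad <- setdiff(feed_events$species, c("m1", "m2", "initiator", "activator"))
    if (length(bad)) abort(paste("unknown feed species:", paste(bad, collapse = ", ")))
    if (any(feed_events$amount_eq <= 0)) abort("feed amounts must be positive")
  }
  structure(list(
    temperature = temperature, total_monomer_conc = total_monomer_conc,
    target_dp = target_dp, f2_0 = f2_0, n_chains = as.integer(n_chains),
    stop_conversion = stop_conversion, max_time = max_time,
    snapshot_grid = sort(unique(snapshot_grid)),
    record_populations_at = sort(unique(record_populations_at)),
    feed_events = feed_events, quench_at = quench_at,
    quench_at_end = isTRUE(quench_at_end), ideal_mode = isTRUE(ideal_mode),
    disable_transfer = isTRUE(disable_transfer),
    disable_reinitiation_after_transfer = isTRUE(disable_reinitiation_after_transfer),
    disable_macropropagation = isTRUE(disable_macropropagation),
    activator_eq = activator_eq, deactivator_eq = deactivator_eq,
    record_sequences = isTRUE(record_sequences), max_events = max_events
  ), class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf(paste0("<run_config> %g degC, [M]0 = %g mol/L, target DP = %g, ",
                     "f2_0 = %g, N_I = %d\n"),
              x$temperature, x$total_monomer_conc, x$target_dp, x$f2_0, x$n_chains))
  if (x$ideal_mode) cat("  ideal mode (instantaneous initiation, no side reactions)\n")
  invisible(x)
}

.event_type_code <- function(species) {
  match(species, c("m1", "m2", "initiator", "activator", "quench"))
}
.trigger_code <- function(trigger) {
  match(trigger, c("conversion", "conversion_m1", "conversion_m2", "time"))
}

.compile_events <- function(run) {
  evs <- list()
  if (!is.null(run$feed_events)) {
    for (r in seq_len(nrow(run$feed_events))) {
      fe <- run$feed_events[r, ]
      tk <- .trigger_code(fe$trigger)
      if (is.na(tk)) abort(sprintf("invalid feed trigger '%s'", fe$trigger))
      evs[[length(evs) + 1L]] <- list(
        type = .event_type_code(fe$species), trigger_kind = tk,
        trigger = as.numeric(fe$at),
        amount = round(fe$amount_eq * run$n_chains))
    }
  }
  if (!is.null(run$quench_at)) {
    tk <- .trigger_code(run$quench_at$trigger %||% "conversion")
    if (is.na(tk)) abort("invalid quench trigger")
    evs[[length(evs) + 1L]] <- list(type = 5L, trigger_kind = tk,
                                    trigger = as.numeric(run$quench_at$at),
                                    amount = 0)
  }
  evs
}

.SNAPSHOT_COLS <- c("time", "conversion", "conversion_m1", "conversion_m2",
                    "n_initiator", "n_m1", "n_m2", "n_chains", "n_active",
                    "n_dormant", "n_macromonomer", "n_dead", "units_m1",
                    "units_m2", "x_n", "x_w", "dispersity",
                    "macromonomer_fraction", "branched_fraction",
                    "n_activator", "n_deactivator", "n_r0", "events")

.pop_tibble <- function(p) {
  out <- tibble(
    chain_id = seq_along(p$n1),
    cl = p$n1 + p$n2,
    n1 = p$n1, n2 = p$n2, func = p$n2,
    terminal = p$terminal,
    status = factor(.STATUS_LEVELS[p$status + 1L], levels = .STATUS_LEVELS),
    branch_count = p$branch
  )
  if (!is.null(p$sequence)) out$sequence <- p$sequence
  out
}

#' Run a kinetic Monte Carlo polymerization simulation
#'
#' Exact (Gillespie direct-method) stochastic simulation of the reaction
#' network of `model` under the conditions of `run`, with explicit
#' per-chain records (length, per-monomer unit counts, terminal unit,
#' status, branch count). Scheduled feed and quench events are applied
#' instantaneously at their trigger; summary snapshots are taken on the
#' overall-conversion grid.
#'
#' @param model A [kinetic_model()].
#' @param run A [run_config()].
#' @param seed Integer seed; identical `model`, `run` and `seed` give an
#'   identical trajectory.
#' @return A `kmc_trajectory` object: list with `snapshots` (tibble, one row
#'   per snapshot), `population` (tibble, one row per chain at the end of
#'   the run), `populations` (list of population tibbles at the conversions
#'   requested in `run$record_populations_at`), `tallies` (events per
#'   channel kind), and bookkeeping fields (`added_monomer`, `incorporated`,
#'   `free_monomer`, `aborted_reinitiations`, `conversion`, `time`, `seed`).
#' @examples
#' run <- run_config(temperature = 140, target_dp = 20, n_chains = 200,
#'                   ideal_mode = TRUE, stop_conversion = 1)
#' traj <- kmc_simulate(ideal_model(), run, seed = 1)
#' glance(traj)
#' @export
kmc_simulate <- function(model, run, seed = 1L) {
  if (!inherits(model, "kinetic_model")) abort("`model` must be a kinetic_model")
  if (!inherits(run, "run_config")) abort("`run` must be a run_config")

  temperature_K <- celsius_to_kelvin(run$temperature)
  eff_model <- model
  if (run$ideal_mode || run$disable_transfer) {
    eff_model$k_trM <- .entry_matrix(NULL, "k_trM")
  }
  if (run$ideal_mode || run$disable_macropropagation) {
    eff_model$k_pm <- list(NULL, NULL)
  }
  network <- build_network(eff_model, temperature_K,
                           quench_kinetic = !is.null(eff_model$k_t) &&
                             !run$ideal_mode)
  if (run$ideal_mode) {
    network <- dplyr::filter(network, .data$kind != "initiation")
    if (!nrow(network)) abort("ideal_mode requires propagation channels")
  }
  if (!nrow(network)) abort("the reaction network is empty")

  n_mono_total <- round(run$target_dp * run$n_chains)
  n_m2 <- round(run$f2_0 * n_mono_total)
  conc_I <- run$total_monomer_conc / run$target_dp
  bimol_scale <- conc_I / run$n_chains  # = 1 / (N_A V)

  atrp <- !is.null(model$atrp)
  init <- list(
    n_initiator = run$n_chains,
    n_monomer = c(n_mono_total - n_m2, n_m2),
    n_activator = if (atrp) round(run$activator_eq * run$n_chains) else 0,
    n_deactivator = if (atrp) round(run$deactivator_eq * run$n_chains) else 0,
    n_terminator = 0
  )

  chan <- list(kind = .kind_code(network$kind),
               terminal = ifelse(is.na(network$terminal), 0L, network$terminal),
               monomer = ifelse(is.na(network$monomer), 0L, network$monomer),
               rate = network$rate)

  ctrl <- list(
    seed = as.numeric(seed),
    bimol_scale = bimol_scale,
    disable_reinitiation = run$disable_reinitiation_after_transfer,
    termination_mode = if (atrp && identical(model$atrp$termination_mode,
                                             "disproportionation")) 2L else 1L,
    record_sequences = run$record_sequences,
    instant_init = run$ideal_mode,
    stop_conversion = run$stop_conversion,
    max_time = run$max_time,
    max_events = run$max_events,
    quench_at_end = run$quench_at_end,
    snapshot_grid = run$snapshot_grid,
    record_populations_at = run$record_populations_at,
    events = .compile_events(run)
  )

  res <- .kmc_run(chan, init, ctrl)
  if (isTRUE(res$stalled)) {
    abort(sprintf(paste0("simulation stalled: total propensity reached zero at ",
                         "overall conversion %.4f (< stop criterion %.4f)"),
                  res$conversion[1], run$stop_conversion))
  }

  snapshots <- as_tibble(setNames(as.data.frame(res$snapshots), .SNAPSHOT_COLS))
  pops <- lapply(res$populations, .pop_tibble)
  names(pops) <- sprintf("conversion_%g", res$population_conversions)

  structure(list(
    snapshots = snapshots,
    population = .pop_tibble(res$population),
    populations = pops,
    tallies = setNames(as.numeric(res$tallies), .KIND_LEVELS),
    network = network,
    model_name = model$name,
    run = run,
    seed = seed,
    bimol_scale = bimol_scale,
    time = res$time,
    n_events = res$n_events,
    quenched = res$quenched,
    added_monomer = res$added_monomer,
    free_monomer = res$free_monomer,
    incorporated = res$incorporated,
    aborted_reinitiations = res$aborted_reinitiations,
    conversion = setNames(res$conversion, c("overall", "m1", "m2"))
  ), class = "kmc_trajectory")
}

#' @export
print.kmc_trajectory <- function(x, ...) {
  cat(sprintf("<kmc_trajectory> %s: %d chains, %.0f events, t = %.4g s\n",
              x$model_name, nrow(x$population), x$n_events, x$time))
  cat(sprintf("  conversion: overall %.3f (M1 %.3f, M2 %.3f)\n",
              x$conversion[1], x$conversion[2], x$conversion[3]))
  fin <- x$snapshots[nrow(x$snapshots), ]
  cat(sprintf("  x_n = %.2f, dispersity = %.3f, macromonomer %.3f, branched %.3f\n",
              fin$x_n, fin$dispersity, fin$macromonomer_fraction,
              fin$branched_fraction))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname kmc_simulate
#' @param x A `kmc_trajectory`.
#' @param ... Unused.
#' @export
tidy.kmc_trajectory <- function(x, ...) x$snapshots

#' @rdname kmc_simulate
#' @export
glance.kmc_trajectory <- function(x, ...) {
  fin <- x$snapshots[nrow(x$snapshots), ]
  tibble(conversion = x$conversion[["overall"]],
         conversion_m1 = x$conversion[["m1"]],
         conversion_m2 = x$conversion[["m2"]],
         time = x$time, n_chains = nrow(x$population),
         x_n = fin$x_n, x_w = fin$x_w, dispersity = fin$dispersity,
         macromonomer_fraction = fin$macromonomer_fraction,
         branched_fraction = fin$branched_fraction,
         n_events = x$n_events, seed = x$seed)
}

#' Extract a chain population from a trajectory
#'
#' @param traj A `kmc_trajectory`.
#' @param at `NULL` for the final population, or an overall conversion that
#'   was requested in `record_populations_at`.
#' @return Population tibble (one row per macromolecule).
#' @export
chain_population <- function(traj, at = NULL) {
  if (is.null(at)) return(traj$population)
  nm <- sprintf("conversion_%g", at)
  if (!nm %in% names(traj$populations)) {
    abort(sprintf("no population was recorded at conversion %g", at))
  }
  traj$populations[[nm]]
}
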
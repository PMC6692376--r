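test_that("channel propensities match the hand-evaluated counting rules", {
  m <- toy_model(kp11 = 0.145, kp12 = 0.145, kp21 = 0.145, kp22 = 0.145,
                 ki = 0.02)
  net <- build_network(m, 400)
  # N_I = 1000, target DP = 100, [M] = 3 M equimolar => [I]0 = 0.03 M,
  # bimolecular scale [I]0 / N_I = 3e-5
  state <- list(n_initiator = 0, n_m1 = 50000, n_m2 = 0,
                n_active_1 = 1000, n_active_2 = 0)
  a <- channel_propensities(state, net, bimol_scale = 0.03 / 1000)
  prop11 <- dplyr::filter(a, kind == "propagation", terminal == 1, monomer == 1)
  expect_equal(prop11$propensity, 217.5)  # 0.145 * 3e-5 * 1000 * 50000
  # channels with an empty reactant pool have zero propensity
  expect_true(all(a$propensity[a$monomer %in% 2 | a$kind == "initiation"] == 0))
  # doubling the volume halves every bimolecular propensity
  a2 <- channel_propensities(state, net, bimol_scale = 0.03 / 2000)
  expect_equal(a2$propensity, a$propensity / 2)
  expect_error(channel_propensities(list(n_m1 = -1), net, 1e-5), "negative")
})

test_that("first-event channel-selection frequencies match a/sum(a)", {
  # from a frozen instantly-initiated state, two propagation channels per
  # terminal compete with rates 0.1 (monomer 1) and 0.3 (monomer 2) on
  # near-equal monomer pools: the first added unit is monomer 2 with
  # probability ~0.75; compare the empirical frequency over independent
  # single-event runs against a 4-sigma binomial bound
  m <- toy_model(kp11 = 0.1, kp12 = 0.3, kp21 = 0.1, kp22 = 0.3)
  run <- run_config(temperature = 140, target_dp = 100, f2_0 = 0.5,
                    n_chains = 50, ideal_mode = TRUE, max_events = 1,
                    snapshot_grid = numeric(), quench_at_end = FALSE)
  n_rep <- 400
  added <- vapply(seq_len(n_rep), function(s) {
    pop <- kmc_simulate(m, run, seed = s)$population
    grown <- pop[pop$cl == 2, ]
    stopifnot(nrow(grown) == 1)
    grown$terminal
  }, 0L)
  p2_hat <- mean(added == 2L)
  expect_lt(abs(p2_hat - 0.75), 4 * sqrt(0.75 * 0.25 / n_rep) + 0.005)
})

test_that("identical config and seed give identical trajectories", {
  m <- toy_model(ktr = 2e-3, kpm = 1e-2)
  run <- toy_run(n_chains = 300, record_populations_at = c(0.5))
  t1 <- kmc_simulate(m, run, seed = 42)
  t2 <- kmc_simulate(m, run, seed = 42)
  expect_identical(t1$snapshots, t2$snapshots)
  expect_identical(t1$population, t2$population)
  expect_identical(t1$populations, t2$populations)
  t3 <- kmc_simulate(m, run, seed = 43)
  expect_false(identical(t1$population, t3$population))
})

test_that("mass balance, chain ledger and FUNC <= CL hold with all side reactions", {
  m <- toy_model(ktr = 3e-3, kpm = 2e-2)
  traj <- kmc_simulate(m, toy_run(n_chains = 400), seed = 7)
  expect_mass_balance(traj)
  pop <- traj$population
  expect_true(all(pop$func <= pop$cl))
  expect_true(all(pop$cl >= 1))
  # chain-count ledger: records = initiations + transfer re-initiations
  # - macropropagation absorptions
  tal <- traj$tallies
  expect_identical(nrow(pop),
                   as.integer(tal[["initiation"]] + tal[["transfer_to_monomer"]] -
                              tal[["macropropagation"]]))
  # branch bookkeeping: branches = absorptions
  expect_identical(sum(pop$branch_count), as.integer(tal[["macropropagation"]]))
  # conversions non-decreasing along the trajectory
  expect_true(all(diff(traj$snapshots$conversion) >= 0))
  expect_true(all(diff(traj$snapshots$conversion_m1) >= 0))
})

test_that("transfer bookkeeping: macromonomers keep counts, carriers restart at CL 1", {
  m <- toy_model(ktr = 5e-3)
  run <- toy_run(n_chains = 300, record_populations_at = 0.6,
                 quench_at_end = FALSE)
  traj <- kmc_simulate(m, run, seed = 11)
  pop <- traj$population
  macs <- dplyr::filter(pop, status == "macromonomer")
  expect_gt(nrow(macs), 0)
  expect_true(all(macs$branch_count == 0))
  # transfer-born actives exist and the active-chain count matches the ledger
  expect_identical(sum(pop$status == "active"),
                   as.integer(traj$tallies[["initiation"]] +
                              traj$tallies[["transfer_to_monomer"]] -
                              nrow(macs)))
})

test_that("ablations remove their side products", {
  m <- toy_model(ktr = 5e-3, kpm = 5e-2)
  base <- toy_run(n_chains = 300)

  no_tr <- base; no_tr$disable_transfer <- TRUE
  t1 <- kmc_simulate(m, no_tr, seed = 3)
  sf <- species_fractions(t1)
  expect_identical(sf$macromonomer_fraction, 0)
  expect_identical(sf$branched_fraction, 0)
  expect_identical(unname(t1$tallies[["transfer_to_monomer"]]), 0)

  no_mp <- base; no_mp$disable_macropropagation <- TRUE
  t2 <- kmc_simulate(m, no_mp, seed = 3)
  expect_identical(unname(t2$tallies[["macropropagation"]]), 0)
  expect_true(all(t2$population$branch_count == 0))

  # milder transfer so the active population survives without re-initiation
  m_mild <- toy_model(ktr = 1e-3, kpm = 5e-2)
  no_re <- base; no_re$disable_reinitiation_after_transfer <- TRUE
  t3 <- kmc_simulate(m_mild, no_re, seed = 3)
  expect_gt(sum(t3$aborted_reinitiations), 0)
  expect_mass_balance(t3)
  # no transfer-born carriers: chains = initiations - absorptions
  expect_identical(nrow(t3$population),
                   as.integer(t3$tallies[["initiation"]] -
                              t3$tallies[["macropropagation"]]))
})

test_that("ideal mode initiates every chain at t = 0 and stays side-reaction-free", {
  run <- toy_run(target_dp = 30, n_chains = 500, ideal_mode = TRUE,
                 stop_conversion = 1)
  traj <- kmc_simulate(ideal_model(), run, seed = 9)
  expect_identical(nrow(traj$population), 500L)
  expect_identical(unname(traj$tallies[["transfer_to_monomer"]]), 0)
  expect_identical(traj$conversion[["overall"]], 1)
  expect_equal(mean(traj$population$cl), 30)  # exact: all monomer consumed
  expect_mass_balance(traj)
})

test_that("feed events add monomer at their trigger and quench kills active chains", {
  m <- toy_model()
  feed <- tibble::tibble(species = "m2", amount_eq = 10,
                         trigger = "conversion_m1", at = 0.5)
  run <- toy_run(target_dp = 20, f2_0 = 0, n_chains = 300, feed_events = feed,
                 stop_conversion = 0.95)
  traj <- kmc_simulate(m, run, seed = 5)
  expect_identical(unname(traj$added_monomer), c(20 * 300, 10 * 300))
  expect_gt(sum(traj$population$n2), 0)
  expect_mass_balance(traj)

  runq <- toy_run(n_chains = 200, quench_at = list(trigger = "conversion", at = 0.5))
  trajq <- kmc_simulate(m, runq, seed = 5)
  expect_true(all(trajq$population$status == "dead"))
  expect_lt(trajq$conversion[["overall"]], 0.6)
})

test_that("recorded monomer sequences agree with the per-chain unit counts", {
  m <- toy_model(ktr = 2e-3)  # no macropropagation: sequences stay linear
  run <- toy_run(n_chains = 200, record_sequences = TRUE)
  pop <- kmc_simulate(m, run, seed = 19)$population
  expect_true("sequence" %in% names(pop))
  expect_identical(nchar(pop$sequence), pop$cl)
  n2_from_seq <- vapply(strsplit(pop$sequence, ""),
                        function(s) sum(s == "2"), 0L)
  expect_identical(n2_from_seq, pop$n2)
  # terminal unit is the last symbol of the sequence
  expect_identical(as.integer(substr(pop$sequence, pop$cl, pop$cl)),
                   pop$terminal)
})

test_that("a network that cannot reach the stop criterion stalls with an error", {
  run <- toy_run(n_chains = 50, stop_conversion = 0.99, quench_at_end = FALSE)
  # no initiation channels: zero total propensity with the criterion unmet
  m0 <- kinetic_model(monomer_set(c("A", "B")),
                      k_i = list(NULL, NULL),
                      k_p = list(list(arrhenius_params(1), arrhenius_params(1)),
                                 list(arrhenius_params(1), arrhenius_params(1))))
  expect_error(kmc_simulate(m0, run, seed = 1), "stall")
})

test_that("ATRP termination modes conserve units and merge or keep chains", {
  cfg <- read_config(preset_path("atrp_ehac_gma"))
  run <- cfg$run; run$n_chains <- 400L
  traj <- kmc_simulate(cfg$model, run, seed = 2)
  expect_mass_balance(traj)
  tal <- traj$tallies
  # combination: every termination merges two chains into one record
  expect_identical(nrow(traj$population),
                   as.integer(tal[["atrp_initiation"]] - tal[["atrp_termination"]]))
  expect_gt(sum(traj$population$status == "dead"), 0)

  m_disp <- cfg$model
  m_disp$atrp$termination_mode <- "disproportionation"
  traj2 <- kmc_simulate(m_disp, run, seed = 2)
  expect_identical(nrow(traj2$population),
                   as.integer(traj2$tallies[["atrp_initiation"]]))
  expect_mass_balance(traj2)
})
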
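test_that("ideal closed forms have the stated moments and modes", {
  cld <- ideal_cld(100)
  expect_equal(sum(cld$fraction), 1, tolerance = 1e-12)
  expect_equal(sum(cld$cl * cld$fraction), 100, tolerance = 1e-9)  # mean = DP
  # exact tie p(CL = 99) = p(CL = 100) for the unit-shifted Poisson with
  # integer mean: both are modes
  expect_true(cld$cl[which.max(cld$fraction)] %in% c(99L, 100L))
  expect_equal(cld$fraction[cld$cl == 99], cld$fraction[cld$cl == 100],
               tolerance = 1e-12)

  one <- ideal_cld(1)  # lambda = 0: every chain has length 1
  expect_equal(one$fraction[one$cl == 1], 1)

  fd <- ideal_funcd(100, 0.5)
  expect_identical(fd$func[which.max(fd$fraction)], 50L)
  expect_equal(sum(fd$fraction), 1, tolerance = 1e-12)

  # f2_0 = 1: the FUNCD is the CLD
  fd1 <- ideal_funcd(40, 1)
  cld1 <- ideal_cld(40)
  expect_equal(fd1$fraction[match(cld1$cl, fd1$func)], cld1$fraction,
               tolerance = 1e-12)

  expect_lt(ideal_fraction_nonfunctionalized(100, 0.5), 1e-6)
  expect_equal(ideal_fraction_nonfunctionalized(1, 0.25), 0.75, tolerance = 1e-9)
})

test_that("the mean-field ODE reproduces the closed-form exponential decay", {
  m <- ideal_model(arrhenius_params(0.15))
  run <- run_config(140, target_dp = 50, f2_0 = 0, n_chains = 1000,
                    ideal_mode = TRUE)
  prof <- ode_conversion(m, run)
  cI <- 3 / 50
  expect_equal(prof$conversion_m1, 1 - exp(-0.15 * cI * prof$time),
               tolerance = 1e-6)
  expect_true(all(diff(prof$M1) <= 1e-12))
})

test_that("an all-zero network yields a constant ODE profile", {
  m <- kinetic_model(monomer_set(c("A", "B")),
                     k_i = list(NULL, NULL),
                     k_p = list(list(arrhenius_params(1e-30), arrhenius_params(1e-30)),
                                list(arrhenius_params(1e-30), arrhenius_params(1e-30))))
  run <- run_config(100, target_dp = 10, n_chains = 100)
  prof <- ode_conversion(m, run, times = seq(0, 10, length.out = 20))
  expect_equal(max(prof$conversion), 0, tolerance = 1e-12)
})

test_that("stochastic conversion tracks the mean-field ODE within replicate error", {
  # single-monomer CROP with kinetic initiation and transfer off
  m <- toy_model(ki = 0.05)
  run <- run_config(140, target_dp = 40, f2_0 = 0, n_chains = 2000,
                    quench_at_end = FALSE)
  prof <- ode_conversion(m, run)
  ode_at <- stats::approxfun(prof$time, prof$conversion, rule = 2)
  probe <- c(0.2, 0.5, 0.8, 0.95)
  reps <- sapply(1:5, function(s) {
    traj <- kmc_simulate(m, run, seed = 100 + s)
    st <- traj$snapshots
    sapply(probe, function(x) {
      i <- which(st$conversion >= x)[1]
      st$time[i]
    })
  })
  # compare the mean kMC time-to-conversion with the ODE's, within 3 SEM
  for (k in seq_along(probe)) {
    t_ode <- stats::approx(prof$conversion, prof$time, xout = probe[k])$y
    sem <- stats::sd(reps[k, ]) / sqrt(ncol(reps))
    expect_lt(abs(mean(reps[k, ]) - t_ode), 3 * sem + 0.02 * t_ode)
  }
})

test_that("ideal-mode empirical distributions converge to the closed forms", {
  run <- run_config(140, target_dp = 60, f2_0 = 0.5, n_chains = 20000,
                    ideal_mode = TRUE, stop_conversion = 1)
  traj <- kmc_simulate(ideal_model(), run, seed = 17)
  fc <- build_func_cld(traj)
  cld_emp <- marginal_cld(fc)

  ref <- ideal_cld(60, cl_max = max(cld_emp$cl) + 30)
  F_ref <- cumsum(ref$fraction)
  F_emp <- cumsum(tidyr::replace_na(cld_emp$fraction[match(ref$cl, cld_emp$cl)], 0))
  ks <- max(abs(F_emp - F_ref))
  expect_lt(ks, 1.63 / sqrt(20000))  # alpha = 0.01 KS bound, conservative

  fd_emp <- marginal_funcd(fc)
  fref <- ideal_funcd(60, 0.5, cl_max = max(cld_emp$cl) + 30)
  Ff_ref <- cumsum(fref$fraction)
  Ff_emp <- cumsum(tidyr::replace_na(fd_emp$fraction[match(fref$func, fd_emp$func)], 0))
  expect_lt(max(abs(Ff_emp - Ff_ref)), 1.63 / sqrt(20000))
})
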
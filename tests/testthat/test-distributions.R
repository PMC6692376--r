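test_that("build_func_cld counts chains into unit-width (CL, FUNC) bins", {
  point <- manual_population(cl = rep(5, 10), func = rep(2, 10))
  fc <- build_func_cld(point)
  expect_identical(nrow(fc), 1L)
  expect_identical(fc$fraction, 1)
  expect_identical(c(fc$cl, fc$func), c(5L, 2L))

  two <- build_func_cld(manual_population(cl = c(2, 3), func = c(0, 1)))
  expect_equal(two$fraction, c(0.5, 0.5))
  expect_equal(sum(two$fraction), 1)

  m <- as.matrix(two)
  expect_equal(m["2", "0"], 0.5)
  expect_equal(sum(m), 1)

  expect_error(build_func_cld(manual_population(integer(), integer())), "empty")
  # filtering to an absent status also errors
  expect_error(build_func_cld(point, statuses = "macromonomer"), "empty")
})

test_that("marginals integrate the bivariate distribution and stay normalized", {
  fc <- build_func_cld(manual_population(cl = c(5, 5, 5), func = c(2, 2, 2)))
  mg <- marginals(fc)
  expect_identical(mg$cld$cl, 5L)
  expect_identical(mg$funcd$func, 2L)
  expect_equal(mg$cld$fraction, 1)

  fc2 <- build_func_cld(manual_population(cl = c(2, 3), func = c(0, 1)))
  expect_equal(marginal_funcd(fc2)$fraction, c(0.5, 0.5))

  # property: both marginals of any simulated distribution sum to one
  traj <- kmc_simulate(toy_model(ktr = 3e-3), toy_run(n_chains = 300), seed = 2)
  fc3 <- build_func_cld(traj)
  expect_equal(sum(marginal_cld(fc3)$fraction), 1, tolerance = 1e-12)
  expect_equal(sum(marginal_funcd(fc3)$fraction), 1, tolerance = 1e-12)
})

test_that("moments reproduce hand-evaluated values", {
  cld <- tibble::tibble(cl = c(50, 150), fraction = c(0.5, 0.5))
  cm <- cld_moments(cld)
  expect_equal(cm$x_n, 100)
  expect_equal(cm$x_w, 125)
  expect_equal(cm$dispersity, 1.25)

  mono <- cld_moments(tibble::tibble(cl = 40, fraction = 1))
  expect_equal(mono$dispersity, 1)

  bern <- funcd_moments(tibble::tibble(func = c(0, 1), fraction = c(0.9, 0.1)))
  expect_equal(bern$mu, 0.1)
  expect_equal(bern$sigma, 0.3)
})

test_that("moments from the FUNC-CLD equal moments from the raw population", {
  traj <- kmc_simulate(toy_model(ktr = 2e-3, kpm = 1e-2),
                       toy_run(n_chains = 400), seed = 5)
  pop <- traj$population
  fc <- build_func_cld(pop)
  cm <- cld_moments(marginal_cld(fc))
  expect_equal(cm$x_n, mean(pop$cl), tolerance = 1e-12)
  expect_equal(cm$x_w, sum(pop$cl^2) / sum(pop$cl), tolerance = 1e-12)
  # engine x_n equals total incorporated units / total chains exactly
  fin <- traj$snapshots[nrow(traj$snapshots), ]
  expect_equal(fin$x_n, sum(traj$incorporated) / nrow(pop), tolerance = 1e-12)
  fm <- funcd_moments(marginal_funcd(fc))
  expect_equal(fm$mu, mean(pop$func), tolerance = 1e-12)
})

test_that("C_v and f_nonfunctionalized follow their definitions", {
  same <- tibble::tibble(func = 3, fraction = 1)
  expect_equal(coefficient_of_variation(same), 0)

  two <- tibble::tibble(func = c(0, 2), fraction = c(0.5, 0.5))
  expect_equal(coefficient_of_variation(two), 1)  # mu = 1, sigma = 1

  allzero <- tibble::tibble(func = 0, fraction = 1)
  expect_error(coefficient_of_variation(allzero), "undefined")

  expect_equal(fraction_nonfunctionalized(
    tibble::tibble(func = c(0, 1, 2), fraction = c(0.25, 0.5, 0.25))), 0.25)
  expect_equal(fraction_nonfunctionalized(
    tibble::tibble(func = 1:3, fraction = rep(1 / 3, 3))), 0)

  # C_v is invariant under scaling all chain counts by a constant
  f1 <- tibble::tibble(func = c(0, 1, 4), fraction = c(10, 30, 20))
  f2 <- tibble::tibble(func = c(0, 1, 4), fraction = c(10, 30, 20) * 7)
  expect_equal(coefficient_of_variation(f1), coefficient_of_variation(f2))
})

test_that("species fractions count macromonomers and branched chains", {
  pop <- manual_population(cl = rep(10, 10), func = rep(1, 10),
                           status = c(rep("macromonomer", 3), rep("dead", 7)),
                           branch = c(rep(0, 3), 1, rep(0, 6)))
  sf <- species_fractions(pop)
  expect_equal(sf$macromonomer_fraction, 0.3)
  expect_equal(sf$branched_fraction, 0.1)
})

test_that("poisson_reference matches the closed-form pmf", {
  # lambda = 0: point mass at zero
  p0 <- poisson_reference(tibble::tibble(func = c(0, 1), fraction = c(1, 0)))
  expect_equal(p0$fraction[p0$func == 0], 1)

  # lambda = 1: p(0) = p(1) = exp(-1), up to truncation renormalization
  f <- tibble::tibble(func = c(0, 2), fraction = c(0.5, 0.5))  # mu = 1
  pr <- poisson_reference(f)
  expect_equal(pr$fraction[pr$func == 0],
               dpois(0, 1) / sum(dpois(0:2, 1)))
  expect_equal(pr$fraction[pr$func == 0], pr$fraction[pr$func == 1])
})

test_that("cld_mode returns the argmax cell with the documented tie-break", {
  pop <- manual_population(cl = c(7, 7, 9), func = c(3, 3, 1))
  expect_identical(as.integer(cld_mode(build_func_cld(pop))[1, 1:2]), c(7L, 3L))
  # tie between (2,0) and (3,1): smallest CL wins
  tie <- build_func_cld(manual_population(cl = c(2, 3), func = c(0, 1)))
  expect_identical(as.integer(cld_mode(tie)[1, 1:2]), c(2L, 0L))
})
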
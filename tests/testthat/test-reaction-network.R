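test_that("arrhenius_rate evaluates A exp(-Ea/RT) and validates input", {
  expect_equal(arrhenius_rate(arrhenius_params(5), 300), 5)
  expect_equal(arrhenius_rate(arrhenius_params(5), 700), 5)  # Ea = 0: constant
  expect_equal(arrhenius_rate(arrhenius_params(1e8, 7e4), 413.15),
               0.14111263, tolerance = 1e-7)
  expect_error(arrhenius_rate(arrhenius_params(1), -10), "positive")
  expect_error(arrhenius_params(-1, 0), "positive")
  expect_error(arrhenius_params(1, -5), "non-negative")
})

test_that("arrhenius_rate is strictly increasing in T when Ea > 0", {
  p <- arrhenius_params(2e7, 5e4)
  temps <- seq(280, 500, by = 20)
  expect_true(all(diff(arrhenius_rate(p, temps)) > 0))
})

test_that("CROP presets reproduce the literature homo-propagation values at 140 C", {
  Tk <- celsius_to_kelvin(140)
  m <- preset_model("crop_meox_c2mestox")
  expect_equal(arrhenius_rate(m$k_p[[1]][[1]], Tk), 1.45e-1, tolerance = 5e-4)
  expect_equal(arrhenius_rate(m$k_p[[2]][[2]], Tk), 1.66e-1, tolerance = 5e-4)
})

test_that("reactivity ratios follow the functional-monomer convention", {
  m <- toy_model(kp11 = 0.3, kp12 = 0.3, kp21 = 0.1, kp22 = 0.2)
  rr <- reactivity_ratios(m, 400)
  expect_equal(rr$r1, 2.0)
  expect_equal(rr$r2, 1.0)

  sym <- toy_model(kp11 = 0.2, kp12 = 0.2, kp21 = 0.2, kp22 = 0.2)
  expect_equal(as.numeric(reactivity_ratios(sym, 350)), c(1, 1))

  # relabeling the monomers (transposing the matrix through the swap) swaps r1/r2
  swapped <- toy_model(kp11 = 0.2, kp12 = 0.1, kp21 = 0.3, kp22 = 0.3)
  rs <- reactivity_ratios(swapped, 400)
  expect_equal(c(rs$r1, rs$r2), c(rr$r2, rr$r1))
})

test_that("zero cross-propagation makes reactivity ratios error out", {
  k <- arrhenius_params(0.2)
  expect_error(
    kinetic_model(monomer_set(c("A", "B")), k_i = list(k, k),
                  k_p = list(list(k, NULL), list(k, k))),
    "propagation")
})

test_that("build_network enumerates, omits zero channels, and is order-stable", {
  full <- toy_model(ktr = 1e-3, kpm = 1e-2)
  net <- build_network(full, 400)
  expect_identical(nrow(net), 12L)  # 2 init + 4 prop + 4 transfer + 2 macroprop
  expect_identical(as.character(unique(net$kind)),
                   c("initiation", "propagation", "transfer_to_monomer",
                     "macropropagation"))

  bare <- toy_model()  # no side reactions configured
  expect_identical(nrow(build_network(bare, 400)), 6L)

  # deterministic, byte-identical across calls
  expect_identical(build_network(full, 400), build_network(full, 400))

  # every channel rate equals the Arrhenius evaluation of its model entry
  Tk <- 377.7
  m <- preset_model("crop_meox_c2mestox")
  net2 <- build_network(m, Tk)
  prop <- dplyr::filter(net2, kind == "propagation")
  for (r in seq_len(nrow(prop))) {
    expect_identical(prop$rate[r],
                     arrhenius_rate(m$k_p[[prop$terminal[r]]][[prop$monomer[r]]], Tk))
  }
})

test_that("ATRP networks carry exchange and termination channels", {
  net <- build_network(preset_model("atrp_styrene_npmi"), celsius_to_kelvin(110))
  expect_setequal(unique(as.character(net$kind)),
                  c("propagation", "atrp_activation_initiator",
                    "atrp_deactivation_initiator", "atrp_initiation",
                    "atrp_activation", "atrp_deactivation", "atrp_termination"))
  expect_true(all(net$rate >= 0))
})
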
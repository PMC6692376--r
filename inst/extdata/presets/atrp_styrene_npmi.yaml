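# ATRP of styrene (non-functional M1) with N-propylmaleimide (NPMI,
# functional M2), 1-bromoethylbenzene initiator, CuBr / 4,4'-dinonyl-
# 2,2'-bipyridine catalyst, 110 C. Semi-batch: 1 equivalent of NPMI
# (relative to the ATRP initiator) is added at 35 % styrene conversion.
#
# PLACEHOLDER parameter set: styrene propagation from the radical-
# polymerization benchmark Arrhenius pair; the strongly alternating
# styrene/maleimide cross-propagation preference (r1, r2 ~ 0.05) and the
# Cu-mediated activation/deactivation and termination coefficients are
# literature-guided placeholders (see the package vignette).
# Units: A in L mol^-1 s^-1, Ea in J mol^-1.
name: atrp_styrene_npmi
chemistry: atrp
monomers:
  - id: styrene
    name: styrene
    functional: false
  - id: NPMI
    name: N-propylmaleimide
    functional: true
initiation:                 # addition of the activated initiator radical
  styrene: {A: 4.270e+07, Ea: 3.251e+04}
  NPMI:    {A: 8.527e+08, Ea: 3.251e+04}
propagation:
  styrene:
    styrene: {A: 4.270e+07, Ea: 3.251e+04}   # k_p(110 C) = 1.58e+03
    NPMI:    {A: 8.527e+08, Ea: 3.251e+04}   # r_styrene = 0.05
  NPMI:
    styrene: {A: 1.230e+06, Ea: 3.00e+04}    # r_NPMI = 0.05
    NPMI:    {A: 6.152e+04, Ea: 3.00e+04}    # slow maleimide homo-propagation
atrp:
  k_a_i:   {A: 1.278e+05, Ea: 4.00e+04}      # k_a(110 C) ~ 0.45
  k_da_i:  {A: 2.539e+08, Ea: 1.00e+04}      # k_da(110 C) ~ 1.1e+07
  k_a:     {A: 1.278e+05, Ea: 4.00e+04}
  k_da:    {A: 2.539e+08, Ea: 1.00e+04}
  k_t_rad: {A: 1.232e+09, Ea: 8.00e+03}      # k_t(110 C) ~ 1e+08
  termination_mode: combination
conditions:
  temperature_C: 110
  total_monomer_conc_M: 3
  target_dp: 100
  f2_0: 0
  n_chains: 10000
  stop_conversion: 0.9
  activator_eq: 1
  events:
    - type: feed
      species: m2
      amount_eq: 1
      trigger: conversion_m1
      at: 0.35
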
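# ATRP of 2-ethylhexyl acrylate (EHA, non-functional M1) with glycidyl
# methacrylate (GMA, functional M2, 10 mol % initially), methyl
# 2-bromopropionate initiator, CuCl / 2,2'-bipyridine catalyst, toluene,
# 70 C, run to 90 % monomer conversion.
#
# PLACEHOLDER parameter set: acrylate/methacrylate propagation from the
# radical-polymerization benchmark families; cross-propagation toward the
# methacrylate preferred (r_EHA ~ 0.3, r_GMA ~ 2, tertiary methacrylate
# radical more stable than the secondary acrylate radical); Cu-mediated
# exchange and termination are literature-guided placeholders (see the
# package vignette).
# Units: A in L mol^-1 s^-1, Ea in J mol^-1.
name: atrp_ehac_gma
chemistry: atrp
monomers:
  - id: EHA
    name: 2-ethylhexyl acrylate
    functional: false
  - id: GMA
    name: glycidyl methacrylate
    functional: true
initiation:                 # addition of the activated initiator radical
  EHA: {A: 2.210e+07, Ea: 1.79e+04}
  GMA: {A: 7.367e+07, Ea: 1.79e+04}
propagation:
  EHA:
    EHA: {A: 2.210e+07, Ea: 1.79e+04}        # k_p(70 C) = 4.2e+04
    GMA: {A: 7.367e+07, Ea: 1.79e+04}        # r_EHA = 0.3
  GMA:
    EHA: {A: 1.337e+06, Ea: 2.10e+04}        # r_GMA = 2.0
    GMA: {A: 2.674e+06, Ea: 2.10e+04}        # k_p(70 C) = 1.7e+03
atrp:
  k_a_i:   {A: 2.455e+05, Ea: 4.00e+04}      # k_a(70 C) ~ 0.2
  k_da_i:  {A: 3.329e+08, Ea: 1.00e+04}      # k_da(70 C) ~ 1e+07
  k_a:     {A: 2.455e+05, Ea: 4.00e+04}
  k_da:    {A: 3.329e+08, Ea: 1.00e+04}
  k_t_rad: {A: 8.191e+08, Ea: 6.00e+03}      # k_t(70 C) ~ 1e+08
  termination_mode: combination
conditions:
  temperature_C: 70
  total_monomer_conc_M: 3
  target_dp: 100
  f2_0: 0.1
  n_chains: 10000
  stop_conversion: 0.9
  activator_eq: 1
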
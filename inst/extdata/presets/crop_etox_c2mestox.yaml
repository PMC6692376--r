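# CROP of 2-ethyl-2-oxazoline (EtOx, non-functional M1) with C2MestOx
# (functional M2) in acetonitrile. PLACEHOLDER parameter set: EtOx
# homo-propagation slightly below MeOx, somewhat less favorable
# cross-propagation (r_EtOx ~ 2.3, r_C2MestOx ~ 0.45) and more chain
# transfer than the MeOx pair, consistent with its poorer reported
# functionalization quality. Construction notes: see
# crop_meox_c2mestox.yaml and the package vignette.
# Units: A in L mol^-1 s^-1, Ea in J mol^-1.
name: crop_etox_c2mestox
chemistry: crop
monomers:
  - id: EtOx
    name: 2-ethyl-2-oxazoline
    functional: false
  - id: C2MestOx
    name: methyl 3-(2-oxazolin-2-yl)propanoate
    functional: true
initiation:
  EtOx:     {A: 3.543e+07, Ea: 7.00e+04}
  C2MestOx: {A: 3.543e+07, Ea: 7.00e+04}
propagation:
  EtOx:
    EtOx:     {A: 3.160e+07, Ea: 6.66e+04}   # k_p(140 C) = 1.20e-1
    C2MestOx: {A: 1.375e+07, Ea: 6.66e+04}   # r_EtOx = 2.3
  C2MestOx:
    EtOx:     {A: 9.718e+07, Ea: 6.66e+04}   # r_C2MestOx = 0.45
    C2MestOx: {A: 4.372e+07, Ea: 6.66e+04}   # k_p(140 C) = 1.66e-1
transfer:
  EtOx:
    EtOx:     {A: 1.144e+08, Ea: 9.16e+04}
    C2MestOx: {A: 1.144e+08, Ea: 9.16e+04}
  C2MestOx:
    EtOx:     {A: 1.144e+08, Ea: 9.16e+04}
    C2MestOx: {A: 1.144e+08, Ea: 9.16e+04}
macropropagation:
  EtOx:     {A: 5.268e+05, Ea: 6.66e+04}
  C2MestOx: {A: 5.268e+05, Ea: 6.66e+04}
conditions:
  temperature_C: 140
  total_monomer_conc_M: 3
  target_dp: 100
  f2_0: 0.5
  n_chains: 10000
  stop_conversion: 0.999
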
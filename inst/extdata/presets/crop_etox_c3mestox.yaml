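# CROP of EtOx (non-functional M1) with C3MestOx (functional M2) in
# acetonitrile. PLACEHOLDER parameter set, constructed as for
# crop_meox_c2mestox.yaml (see that file and the package vignette); the
# least favorable of the four 2-oxazoline pairs.
# Units: A in L mol^-1 s^-1, Ea in J mol^-1.
name: crop_etox_c3mestox
chemistry: crop
monomers:
  - id: EtOx
    name: 2-ethyl-2-oxazoline
    functional: false
  - id: C3MestOx
    name: methyl 4-(2-oxazolin-2-yl)butanoate
    functional: true
initiation:
  EtOx:     {A: 3.543e+07, Ea: 7.00e+04}
  C3MestOx: {A: 3.543e+07, Ea: 7.00e+04}
propagation:
  EtOx:
    EtOx:     {A: 3.160e+07, Ea: 6.66e+04}   # k_p(140 C) = 1.20e-1
    C3MestOx: {A: 1.264e+07, Ea: 6.66e+04}   # r_EtOx = 2.5
  C3MestOx:
    EtOx:     {A: 9.876e+07, Ea: 6.66e+04}   # r_C3MestOx = 0.4
    C3MestOx: {A: 3.950e+07, Ea: 6.66e+04}   # k_p(140 C) = 1.50e-1
transfer:
  EtOx:
    EtOx:     {A: 1.297e+08, Ea: 9.16e+04}
    C3MestOx: {A: 1.297e+08, Ea: 9.16e+04}
  C3MestOx:
    EtOx:     {A: 1.297e+08, Ea: 9.16e+04}
    C3MestOx: {A: 1.297e+08, Ea: 9.16e+04}
macropropagation:
  EtOx:     {A: 5.268e+05, Ea: 6.66e+04}
  C3MestOx: {A: 5.268e+05, Ea: 6.66e+04}
conditions:
  temperature_C: 140
  total_monomer_conc_M: 3
  target_dp: 100
  f2_0: 0.5
  n_chains: 10000
  stop_conversion: 0.999
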
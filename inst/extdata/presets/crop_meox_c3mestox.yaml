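# CROP of MeOx (non-functional M1) with methyl 4-(2-oxazolin-2-yl)butanoate
# (C3MestOx, functional M2) in acetonitrile. PLACEHOLDER parameter set,
# constructed as for crop_meox_c2mestox.yaml (see that file and the package
# vignette); C3MestOx slightly less reactive than C2MestOx and the pair
# carries somewhat more chain transfer, consistent with its poorer reported
# functionalization quality.
# Units: A in L mol^-1 s^-1, Ea in J mol^-1.
name: crop_meox_c3mestox
chemistry: crop
monomers:
  - id: MeOx
    name: 2-methyl-2-oxazoline
    functional: false
  - id: C3MestOx
    name: methyl 4-(2-oxazolin-2-yl)butanoate
    functional: true
initiation:
  MeOx:     {A: 3.543e+07, Ea: 7.00e+04}
  C3MestOx: {A: 3.543e+07, Ea: 7.00e+04}
propagation:
  MeOx:
    MeOx:     {A: 3.819e+07, Ea: 6.66e+04}   # k_p(140 C) = 1.45e-1
    C3MestOx: {A: 1.736e+07, Ea: 6.66e+04}   # r_MeOx = 2.2
  C3MestOx:
    MeOx:     {A: 8.770e+07, Ea: 6.66e+04}   # r_C3MestOx = 0.45
    C3MestOx: {A: 3.950e+07, Ea: 6.66e+04}   # k_p(140 C) = 1.50e-1
transfer:
  MeOx:
    MeOx:     {A: 1.068e+08, Ea: 9.16e+04}
    C3MestOx: {A: 1.068e+08, Ea: 9.16e+04}
  C3MestOx:
    MeOx:     {A: 1.068e+08, Ea: 9.16e+04}
    C3MestOx: {A: 1.068e+08, Ea: 9.16e+04}
macropropagation:
  MeOx:     {A: 5.268e+05, Ea: 6.66e+04}
  C3MestOx: {A: 5.268e+05, Ea: 6.66e+04}
conditions:
  temperature_C: 140
  total_monomer_conc_M: 3
  target_dp: 100
  f2_0: 0.5
  n_chains: 10000
  stop_conversion: 0.999
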
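# CROP of 2-methyl-2-oxazoline (MeOx, non-functional M1) with methyl
# 3-(2-oxazolin-2-yl)propanoate (C2MestOx, functional M2) in acetonitrile.
#
# Provenance of the rate coefficients (see also the package vignette):
#   * homo-propagation at 140 C: 1.45e-1 (MeOx) and 1.66e-1 (C2MestOx)
#     L mol^-1 s^-1 — literature values.
#   * everything else is a PLACEHOLDER pair constructed as follows:
#     Ea(propagation) = 66.6 kJ/mol back-calculated from the reported batch
#     times to complete conversion (~0.5 h at 140 C vs ~4 h at 100 C,
#     target DP 100); cross-propagation set by reactivity ratios r_MeOx ~ 2,
#     r_C2MestOx ~ 0.5 reproducing the slower C2MestOx incorporation and
#     feed enrichment; chain transfer (beta-elimination) ~25 kJ/mol more
#     activated than propagation, magnitude calibrated once against the
#     reported high-target-DP plateau of the non-functionalized fraction;
#     macropropagation of the same order as cross-propagation.
# Units: A in L mol^-1 s^-1 (all channels here are bimolecular), Ea in J mol^-1.
name: crop_meox_c2mestox
chemistry: crop
monomers:
  - id: MeOx
    name: 2-methyl-2-oxazoline
    functional: false
  - id: C2MestOx
    name: methyl 3-(2-oxazolin-2-yl)propanoate
    functional: true
initiation:
  MeOx:     {A: 3.543e+07, Ea: 7.00e+04}
  C2MestOx: {A: 3.543e+07, Ea: 7.00e+04}
propagation:
  MeOx:
    MeOx:     {A: 3.819e+07, Ea: 6.66e+04}   # k_p(140 C) = 1.45e-1
    C2MestOx: {A: 1.909e+07, Ea: 6.66e+04}   # r_MeOx = 2.0
  C2MestOx:
    MeOx:     {A: 8.744e+07, Ea: 6.66e+04}   # r_C2MestOx = 0.5
    C2MestOx: {A: 4.372e+07, Ea: 6.66e+04}   # k_p(140 C) = 1.66e-1
transfer:
  MeOx:
    MeOx:     {A: 7.627e+07, Ea: 9.16e+04}
    C2MestOx: {A: 7.627e+07, Ea: 9.16e+04}
  C2MestOx:
    MeOx:     {A: 7.627e+07, Ea: 9.16e+04}
    C2MestOx: {A: 7.627e+07, Ea: 9.16e+04}
macropropagation:
  MeOx:     {A: 5.268e+05, Ea: 6.66e+04}
  C2MestOx: {A: 5.268e+05, Ea: 6.66e+04}
conditions:
  temperature_C: 140
  total_monomer_conc_M: 3
  target_dp: 100
  f2_0: 0.5
  n_chains: 10000
  stop_conversion: 0.999
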
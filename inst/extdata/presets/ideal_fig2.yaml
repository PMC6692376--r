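# Theoretical reference: perfect statistical copolymerization with
# quasi-instantaneous chain growth — all chains initiated at t = 0, all four
# propagation coefficients equal, no side reactions. Equimolar feed,
# target DP 100, run to complete monomer conversion. The propagation
# coefficient only sets the time scale, not the distribution.
name: ideal_statistical
chemistry: crop
monomers:
  - id: M1
    name: non-functional comonomer
    functional: false
  - id: M2
    name: functional comonomer
    functional: true
initiation:
  M1: {A: 0.15, Ea: 0}
  M2: {A: 0.15, Ea: 0}
propagation:
  M1:
    M1: {A: 0.15, Ea: 0}
    M2: {A: 0.15, Ea: 0}
  M2:
    M1: {A: 0.15, Ea: 0}
    M2: {A: 0.15, Ea: 0}
conditions:
  temperature_C: 140
  total_monomer_conc_M: 3
  target_dp: 100
  f2_0: 0.5
  n_chains: 10000
  stop_conversion: 1.0
  ablations:
    ideal_mode: true
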
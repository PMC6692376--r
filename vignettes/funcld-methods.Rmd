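---
title: "Simulating functionality-chain-length distributions: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating functionality-chain-length distributions: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(funcld)
```

## The problem

Functional copolymers used in polymer therapeutics and hydrogels carry a
small amount (typically up to 20 mol %) of a functional comonomer
statistically distributed over the chains. The average composition hides
the question that matters for conjugation chemistry: *how are the
functional groups spread over the individual chains?* Even a perfectly
statistical, side-reaction-free chain growth leaves a distribution of both
chain length (CL) and the number of functional units per chain (FUNC), and
real chemistries add composition drift and chain transfer on top.

`funcld` answers this with an explicit-chain kinetic Monte Carlo (kMC)
simulation of chain-growth copolymerization: every macromolecule in a small
control volume is tracked individually, so the bivariate number-fraction
distribution over (CL, FUNC) — the FUNC-CLD — and everything derivable from
it (marginal CLD and FUNCD, $x_n$, $x_w$, dispersity, the FUNCD mean
$\mu$ and standard deviation $\sigma$) are direct observables rather than
moment reconstructions.

## Reaction scheme and assumptions

Two chemistries are covered, both under the **terminal model** (the
reactivity of an active chain depends only on its last monomer unit;
penultimate effects are out of scope) and with chain-length-independent
rate coefficients (diffusional limitations ignored — dilute solution, low
intrinsic reactivities).

**Living cationic ring-opening polymerization (CROP) of 2-oxazolines:**

* chain initiation: $I + M_j \to P_1$, coefficient $k_{i,j}$;
* propagation: $P_n(i) + M_j \to P_{n+1}(j)$, matrix $k_{p,ij}$;
* chain transfer to monomer (β-elimination): $P_n(i) + M_j \to D_n + P_1(j)$,
  matrix $k_{trM,ij}$ — the chain becomes a **macromonomer** $D_n$ with a
  polymerizable enamine end group, and the protonated monomer acts as a new
  unit-length chain carrier;
* macropropagation: $P_n(i) + D_m \to P_{n+m}(i)$ with one extra branch
  point, coefficient $k_{pm,i}$ (macromonomer reactivity is assumed
  independent of its length and composition, since the scheme carries a
  single coefficient);
* termination by a nucleophilic quench. By default quenching is an
  *instantaneous scheduled event* (the terminator is added at the end of
  the batch), not a kinetic channel; a kinetic terminator channel exists
  but is off by default.

**ATRP of vinyl monomers:** reversible halide exchange
($R_0X$/dormant chains + activator $\rightleftharpoons$ radicals +
deactivator, coefficients $k_{a(,i)}$, $k_{da(,i)}$), propagation as above,
and radical-radical termination $k_t$ (combination by default — one merged
dead chain; disproportionation — two dead chains — by a model switch).
The counter-ion (CROP) and solvent have no kinetic role and are not
simulated.

Index convention throughout: **monomer 1 is the non-functional comonomer,
monomer 2 the functional one**; FUNC of a chain is its monomer-2 unit
count.

## Stochastic simulation

The engine is an exact Gillespie direct-method SSA over molecule counts.
The control volume follows from the simulated initiator count:
$[I]_0 = [M]_0/\mathrm{DP_{target}}$ and $V = N_I/(N_A [I]_0)$, so
bimolecular channels have propensity $a = k/(N_A V)\,X_A X_B$. Chains are
held in per-(status, terminal) index groups; a channel fires against a
uniformly chosen member of its group, which keeps every step $O(\#$
channels$)$ — about 2.5 million events per second in the compiled engine,
or a few seconds for the headline $N_I = 10^5$, target DP 100 runs
($10^7$ events).

Per-chain records carry $(n_1, n_2)$ unit counts, the terminal unit,
status (active / dormant / macromonomer / dead) and a branch counter;
optionally the full monomer sequence. Exact integer bookkeeping gives
assertable invariants at every step: per-monomer mass balance (units in
chains + free monomer = monomer charged), the chain-count ledger
(records = initiations + transfer re-initiations − macropropagation
absorptions − combinations), FUNC ≤ CL, and non-decreasing conversions.
A single 64-bit Mersenne Twister seed makes trajectories bit-reproducible.

Scheduled events (semi-batch feeds, quench) are applied instantaneously at
their conversion or time trigger with the volume held constant; a feed of
a monomer restarts that monomer's conversion denominator, which is the one
documented exception to conversion monotonicity. Snapshots are taken every
1 % overall conversion by default. "Complete monomer conversion" is
operationalized as ≥ 99 % overall (configurable; the shipped CROP
scenarios use 99.9 %), and the run also stops on monomer exhaustion.

`ideal_mode` reproduces the theoretical reference case of a perfect
statistical copolymerization: all $N_I$ chains are initiated at $t = 0$
and all side-reaction channels are dropped; with equal propagation
coefficients the final CLD is the unit-shifted Poisson with mean
$\mathrm{DP_{target}}$ and the FUNCD its binomial mixture.

## Rate coefficients and their provenance

Every channel is parameterized as an Arrhenius pair $(A, E_a)$ evaluated
at the run temperature. The shipped CROP presets anchor the two
homo-propagation coefficients to literature values at 140 °C
(MeOx 1.45·10⁻¹, C2MestOx 1.66·10⁻¹ L mol⁻¹ s⁻¹). All other entries are
**clearly labeled placeholders**, constructed once and frozen:

* $E_a$(propagation) = 66.6 kJ mol⁻¹, back-calculated from the reported
  batch times to complete conversion at target DP 100 (≈ 0.5 h at 140 °C
  vs ≈ 4 h at 100 °C);
* cross-propagation from reactivity ratios $r_{\mathrm{MeOx}} \approx 2$,
  $r_{\mathrm{C2MestOx}} \approx 0.5$, chosen to reproduce the observed
  drift pattern (the functional monomer incorporates more slowly despite
  its higher homo-propagation coefficient, and the feed enriches in it);
* chain transfer 25 kJ mol⁻¹ more activated than propagation (transfer
  gains relevance with temperature), with its 140 °C magnitude
  (2·10⁻⁴ L mol⁻¹ s⁻¹) calibrated in a single pass against the reported
  high-target-DP plateau of the non-functionalized chain fraction —
  transfer coefficients are conventionally fitted to such
  high-conversion observables — and then frozen;
* macropropagation of the order of 10⁻² × propagation, consistent with a
  branched-chain fraction well below 3 mol %.

The ATRP presets (styrene/N-propylmaleimide with a maleimide feed at 35 %
styrene conversion; 2-ethylhexyl acrylate/glycidyl methacrylate at 10 mol %
loading) use the radical-polymerization benchmark Arrhenius families for
propagation, strongly alternating (r ≈ 0.05) respectively
methacrylate-preferring (r ≈ 0.3/2) cross-propagation, and
literature-guided Cu exchange/termination magnitudes
($k_{da} \sim 10^7$, $k_t \sim 10^8$ L mol⁻¹ s⁻¹). They demonstrate the
generality of the bookkeeping (dormant states, the persistent-radical
start-up, semi-batch feeds), not a quantitative parameterization.

Because the side-reaction and cross coefficients are placeholders,
quantities that depend on them (dispersity at full conversion, the exact
non-functionalized tail at high loading) carry parameterization
uncertainty; the package's tests therefore anchor on the quantities the
placeholders were *not* tuned to where possible, and on structural
invariants everywhere.

## Derived distributions and quality metrics

`build_func_cld()` bins chains into unit-width integer (CL, FUNC) cells
and normalizes to number fractions — no smoothing, and number (not weight)
fractions throughout, matching the definition of the FUNCD as the number
fraction of chains with a given functional-unit count. Macromonomers,
dead and branched chains are included by default (the product contains
them); a status filter supports ablation studies. Marginals, moments, the
FUNCD coefficient of variation $C_{v} = \sigma/\mu$, the
non-functionalized fraction $f_0 = p(\mathrm{FUNC}=0)$, and a Poisson
reference pmf with rate $\mu$ are one call each. The bivariate mode uses
argmax with ties broken toward the smallest CL then the smallest FUNC.

A note on the ideal-case mode: the closed-form CLD ties exactly at
CL 99/100 for target DP 100 (and CL 98 is under 1 % lower), and odd-CL
binomials tie at FUNC 49/50, so the top of the bivariate surface is a
near-degenerate set of cells differing by a fraction of a percent. A
single-run empirical argmax therefore scatters over that set at any
practical chain count; the package's headline measurement averages the
FUNC-CLD over 20 replicate runs of $10^5$ chains, whose marginal modes
localize to ±1 while the bivariate argmax ranges over the tie set.

**Quality label.** The two metrics map to a five-band color label
(dark_green, light_green, yellow, orange, dark_red) by per-metric band
edges, the overall label being the worse band — either metric exceeding
its key value disqualifies the product, so the label is monotone in both
metrics. The light-green upper edges are the conventional key values
**0.5 for $C_v$ and 0.05 for $f_0$**. The intermediate edges are a
presentation convention, not a physical constant; the defaults
($C_v$: 0.38, 0.5, 0.65, 0.8; $f_0$: 0.01, 0.05, 0.10, 0.25) were chosen
so that the label series reproduces the expected qualitative colorings
under the shipped parameterization — in particular the dark-green edge
sits at 0.38 because the drift-plus-sampling floor of $C_v$ for the
best conditions (50 mol % loading at 140 °C, or 13 mol % at 100 °C) is
≈ 0.35–0.36, which an edge at exactly 0.35 would misclassify. Both edge
sets are fully configurable via `quality_thresholds()`.

`design_scan()` runs the full simulate–score pipeline over a condition
grid (comonomer pair, target DP, loading, temperature) with replicate
seeds (`seed + replicate index`), averages the metrics, and labels the
replicate means; failed conditions produce error rows without aborting
the scan.

## Verification oracles

Two independent routes check the engine:

* **Mean-field ODE twin** (`ode_conversion()`): the same network as
  concentration ODEs (terminal-type-resolved active-chain balances,
  macromonomer balance, the ATRP exchange equilibrium), integrated with
  `deSolve::lsoda` at rtol 10⁻⁸. Single-monomer instant-initiation decay
  matches the closed-form exponential to 10⁻⁶; stochastic conversions are
  required to track the ODE within three replicate standard errors.
* **Closed forms for the ideal case** (`ideal_cld()`, `ideal_funcd()`,
  `ideal_fraction_nonfunctionalized()`): unit-shifted Poisson CLD, its
  binomial mixture FUNCD, and $\sum_{CL} p(CL)(1-f_{2,0})^{CL}$. The
  drift-free binomial mixture is only asserted for equal reactivities;
  with unequal reactivities only the ODE route applies. Empirical
  distributions from `ideal_mode` must pass a Kolmogorov–Smirnov
  comparison (α = 0.01, conservative on discrete support) against these
  forms at $10^5$ chains.

## Numerical and design choices

* Direct SSA with full propensity recomputation per step: at ≤ 25
  channels this is cheaper than dependency-graph bookkeeping at desk
  scale.
* Default $N_I$: $10^5$ chains for headline runs, $10^4$ for routine
  scans and the quantitative checks, smaller for unit tests; these are
  statistical-precision choices, not physical ones. A $10^4$-chain CROP
  batch to 99.9 % conversion runs in well under a second.
* Transfer-born carriers are active unit-length chains (the terminal
  model makes them kinetically equivalent to initiation products) and
  count as incorporated units in composition bookkeeping.
* The branch representation merges the absorbed macromonomer into the
  absorbing record (counts summed, branch counter incremented); each
  active record carries exactly one active center.
* $F_{2,\mathrm{inst}}$ is computed by finite differences of incorporated
  unit counts on the 1 %-conversion snapshot grid (grid width
  configurable); snapshot intervals with no net incorporation are
  skipped with a notice.
* Degenerate inputs are errors, not guesses: empty populations, undefined
  $C_v$ on an entirely non-functional population (labelled dark_red with
  a flag where a label is still needed), zero cross-propagation in
  reactivity ratios, stalled networks (zero total propensity with the
  stop criterion unmet).

## What the tests do and do not show

The simulated populations emulate finite-batch statistical
copolymerization with the side reactions of the scheme above. They do not
emulate SEC band broadening or calibration offsets (no
hydrodynamic-volume rescaling), penultimate-unit effects,
depropagation, temperature programming, volume change on feeds, or
diffusion-controlled kinetics. Agreement of the checks therefore
validates the stochastic chemistry and its bookkeeping — not the absolute
accuracy of the placeholder coefficients, which should be replaced with
fitted values (the configuration schema takes any Arrhenius pair) before
quantitative use on a specific system.

## A worked example

```{r example, fig.width = 6, fig.height = 4}
model <- preset_model("crop_meox_c2mestox")
run <- preset_run("crop_meox_c2mestox")
run$f2_0 <- 0.1
run$n_chains <- 4000L
traj <- kmc_simulate(model, run, seed = 1)
glance(traj)
analyze_population(traj)
autoplot(build_func_cld(traj))
```
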
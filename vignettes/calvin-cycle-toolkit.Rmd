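---
title: "Kinetic modeling of the Calvin-Benson cycle with CalvinSim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetic modeling of the Calvin-Benson cycle with CalvinSim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(CalvinSim)
```

## The model

CalvinSim treats a kinetic model of the Calvin-Benson cycle as a reaction
network: species with carbon and phosphate counts, reactions with real-valued
stoichiometric coefficients, a named parameter set with unit tags, and an
append-only lineage recording how the model was derived from a base variant.
The governing equations are mass balances,

$$\frac{d\mathbf{X}}{dt} = N\,\mathbf{v}(\mathbf{X}),$$

with $N$ the stoichiometry matrix and $\mathbf{v}$ the vector of rate laws.
Clamped (boundary) species keep their rows in $N$ for flux accounting but
have their time derivative forced to zero — the SBML `boundaryCondition`
convention. Concentrations are mM, time is s; fluxes quoted in
mmol s$^{-1}$ convert through a declared compartment volume (default 1 l)
recorded in the model metadata.

Non-integer stoichiometry is first-class because the central lumping device
needs it: photorespiration can be encoded inside the carboxylation reaction
as

$$\mathrm{RuBP} + \mathrm{CO_2} \rightarrow A\cdot\mathrm{PGA} +
  B\cdot\mathrm{PGCA}, \qquad B = 2f,\; A = 2 - 2f,$$

where $f$ is the oxygenation flux fraction. Each RuBP turnover yields two
three-carbon-equivalent products, which forces the factor 2: at $f = 4.2\%$
the pair is $(A, B) = (1.916, 0.084)$. An alternative reading — $f$ as the
fraction of turnover events, $B = f$ — is selectable
(`rule = "per_event"`) but not the default, because only $B = 2f$ reproduces
the printed pair. `elementBalance()` reports that the lumped reaction is not
exactly carbon-closed ($3A + 2B - 6 = -0.084$ carbons per event); the
toolkit reports this honestly rather than renormalizing it away.

## Rate-law families

Beyond mass action and irreversible Michaelis-Menten with competitive
modifiers, the families that carry the scientific weight are:

* **Transketolase** (both cycle reactions,
  $\mathrm{F6P}+\mathrm{GAP}=\mathrm{E4P}+\mathrm{X5P}$ and
  $\mathrm{S7P}+\mathrm{GAP}=\mathrm{Ri5P}+\mathrm{X5P}$):
  $$v = \frac{V_m\,k_E\,(S_1 S_2 - P_1 P_2 / k_E)}
            {(S_1 + K_{m1}\,T)(S_2 + K_{m2})},$$
  where $T$ is the E4P/Ri5P modifier saturation term. The numerator
  prefactor $k_E$ makes the forward rate scale with the equilibrium
  constant, which is what turns the historical $k_{E7} = 10$ (instead of
  0.076) into a roughly hundredfold forward-rate error; the rate still
  vanishes exactly at the equilibrium composition. $T$ combines the two
  modifier terms additively by default; the `multiplicative_modifiers`
  variant reproduces the documented dimensional defect, whose numerical
  effect is below 1 % but which `validateModel()` flags. Two denominator
  conventions exist because the two published encodings of these reactions
  are genuinely different models: the `appendix` form carries $T$ inside
  the first substrate's Michaelis term, the `supplement` form carries no
  modifier saturation at all — which is also why only the appendix form
  destabilizes when the modifier constant `kM103` drops below 0.06 mM.
  `kM103` is bound as the E4P-modifier constant shared by both reactions
  (the saturation term is shared in the source encodings); raising it from
  0.06 toward the transaldolase-derived 0.46 relieves both reactions and
  lowers steady F6P and S7P.
* **Phosphate translocator** ($V_{PGAout}$): with stromal saturation sum
  $T_s = \mathrm{OP}/K_{mOP} + \mathrm{PGA}/K_{mPGA} +
  (\mathrm{GAP}+\mathrm{DHAP})/K_{mT3P}$ and cytosolic sum $T_c$ defined
  analogously,
  $$v = V_{m11}\,\frac{T_c\,(\mathrm{PGA}/K_{mPGA}) -
        T_s\,(\mathrm{PGA_c}/K_{mPGAc})}{T_s + T_c + T_s T_c}.$$
  The denominator is used exactly as printed, with no additive
  idle-carrier "1" term (the typesetting of the source admits both
  readings; we follow the literal one). Consequence worth knowing: export
  into a completely empty cytosol is exactly zero — the law is an
  antiporter and needs a counter-substrate. The law is antisymmetric under
  exchange of the two compositions and linear in $V_{m11}$, yet the
  steady-state export is set by the production flux, not by $V_{m11}$:
  the package verifies this across two orders of magnitude.
* **RuBisCO oxygenase** (for the split encoding):
  $$v = \frac{\mathrm{RuBP}\,V_o\,\mathrm{O_2}/(\mathrm{O_2} +
        K_o(1+\mathrm{CO_2}/K_c))}{\mathrm{RuBP} + K_r\,(1 + \sum_j I_j/K_{Ij})}$$
  with PGA, FBP, SBP, Pi and NADPH as the five inhibitors.
* **Starch phosphorylase**: the corrected form is
  $V_M\,\mathrm{starch}/(\mathrm{starch} + K_m(1 +
  \mathrm{G1P}/K_{iG1P}))$; the `original` variant carries free phosphate
  in both substrate positions and therefore keeps degrading starch at zero
  starch — the defect that drives starch to negative concentrations.
  Models flagged `diagnostic_reproduction` evaluate rates on raw (possibly
  negative) states so this pathology can be reproduced on demand; the
  default mode clips negative concentrations to zero and counts every clip
  (`negativeClipCount()`), so nothing fails silently.
* **Generic expressions**: arbitrary arithmetic trees (operators, powers,
  min/max) cover imported SBML kinetic laws; evaluation is cross-checked
  against an independent tree-walking oracle in the test suite.

## The variant library

`buildModel()` constructs one compartment with fixed CO2, O2 and inorganic
phosphate, every hexose/pentose and GAP/DHAP as separate species, 13 cycle
reactions, 3 starch-synthesis reactions, Michaelis-Menten kinetics
throughout, and Michaelis-Menten (MMcb) export sinks:

* `zhu_A` / `zhu_S` — the two transketolase encodings (appendix vs
  supplement form, default `kM103` 0.46 vs 0.015). Neither is presented as
  canonical: which encoding produced the published simulations is unknown.
* `cyano_C1` / `cyano_C2` — no oxygenation; the PGCA drain is folded into
  the PGA sink with the printed factor 1.66. C1 also folds the minor
  DHAP/E4P/Ri5P sinks (fractions 0.32 %, 0.31 %, 0.7 %, q factors 1, 4/3,
  5/3); C2 declares them explicitly.
* `cyano_D1` / `cyano_D2` — photorespiration as O2 fixation, lumped into
  the carboxylation stoichiometry by default; `split_oxygenation` converts
  to the two-reaction encoding with maximal rates $(1-2f)V$ and $2fV$,
  which leaves all steady-state fluxes identical (verified as a property).
* `hahn` — the same topology under pure mass action with dynamic
  adenylates and a finite external phosphate pool: the behavior class of
  the earliest models, whose stability test shows phosphate depletion, ATP
  collapse and suspension of the cycle unless external phosphate is
  clamped.

**Adenylates are dynamic.** The cyanobacterial variants carry ATP/ADP as
state variables with an explicit photophosphorylation reaction
(`L_atpsyn`, capacity `V_L`). This was a deliberate design choice after
exploring an all-clamped-cofactor design: with every cofactor fixed, the
steady flux pins at the carboxylation capacity and the regeneration-side
pools become near-neutral integrators of tiny flux imbalances —
equilibration becomes pathologically slow and parameter corrections show up
as artifacts rather than as the documented directional effects. A
capacity-bounded ATP supply is the soft global feedback that the published
models all contain, and with it every variant relaxes to a steady state
from the default initial conditions. The energy-charge scan still clamps
ATP and ADP at $ec\cdot T$ and $(1-ec)\cdot T$, removing them from the ODE
state — which reproduces the scan axis exactly and avoids stiffness.

**Parameters are fixture values.** The original parameterizations live in
literature this package does not reconstruct; every built variant is
tainted `non-archival` in its lineage. The numeric defaults were chosen
once to be physiologically shaped (Michaelis constants 0.1–1 mM,
maximal rates of order 1–10 mM s$^{-1}$, transketolase near its
thermodynamic displacement, sink capacities about three times their target
fractions of a nominal 0.9 mM s$^{-1}$ reference flux, a 0.5 mM adenylate
pool) and so that the documented qualitative behaviors — all six variants
stable, `kE7` and `kM103` corrections moving F6P/S7P in the documented
directions, instability below `kM103` = 0.06 — emerge from the model
structure. Importing the supplementary SBML files replaces these values
and clears the taint.

## Analyses

* `stabilityTest()` sets every state variable to its steady-state value
  except a knockout species (default RuBP) at zero, runs 80 minutes of
  simulated time, and reports suspension (RuBP-synthesis flux below 1 % of
  its steady value at the end) and the ATP-collapse time (energy charge
  below 1 %). Both thresholds are package definitions, reported with every
  result.
* `energyChargeScan()` clamps $ATP\cdot(ADP+ATP)^{-1}$ over a grid and
  reports steady observables, flagging non-convergent points and steady
  PGA outside the reported physiological range (2.15–11.7 mM) without
  aborting the scan.
* `sinkOutputAnalysis()` switches sink pools and starch from fixed to
  variable and reports the pool multiplication factor
  $(\mathrm{pool}_0 + \text{sink accumulation})/\mathrm{pool}_0$ (a closed
  system gives exactly 1), the starch excursion in the same units (the
  defective starch law makes it negative), and the mass-production rate,
  defined as the sink-accumulation rate — the quantity the spurious starch
  degradation inflates.
* `sinkComparisonTable()` crosses the two transketolase encodings with
  three PGA-sink kinetics (mass action; translocator-style MM regulated by
  phosphate, GAP and DHAP; simplest MM) and accumulates PGA sink, starch,
  Calvin-Benson pool and total mass over three simulated hours, normalized
  to the supplement-encoding + MM cell = 100. "Total mass" is
  carbon-weighted (carbon atoms exported plus carbon stored in starch):
  carbon weighting is the only convention consistent with the use of
  carbon-ratio q factors; a molar alternative is selectable. The
  parenthesized second values printed alongside the historical table have
  no stated meaning, so the package deliberately produces only the
  unparenthesized convention.
* `pairedModelRatio()` runs two flux-matched variants from one initial
  state and reports ratio series with a $10^{-12}$ mM floor; transient
  excursions appear in ratios even when each raw series is monotone, which
  is the point of the paired protocol.

`matchFlux()` implements the pairing: a common scale factor on chosen knob
parameters is bisected (on a log scale, bracket grown outward from 1) until
the steady-state reference flux of the second model matches the first
within `delta_flux` — $5\times10^{-6}$ for the C pair and $3\times10^{-4}$
for the D pair in the shipped configurations. Every evaluation starts cold
from the model's initial state so the matched flux is exactly reproducible
afterwards.

## Numerical choices

* Integration: `deSolve` `lsodar`, relative tolerance $10^{-8}$, absolute
  $10^{-12}$ mM, with a root function that stops integration when any
  species passes the divergence cap ($10^6$ mM, configurable) — the
  expected outcome for a sink-less cycle, reported as "unbounded
  accumulation" naming the species.
* Steady-state criterion: $\max_i |\dot X_i| / \max(|X_i|, 10^{-9}\,
  \mathrm{mM}) < \varepsilon$, default $\varepsilon = 10^{-6}$ s$^{-1}$.
  The published equilibration times presuppose an unstated criterion, so
  `timeToSteadyState()` accepts a vector of $\varepsilon$ and returns the
  sensitivity band; ties break to the first grid time, on a log grid of
  1000 points per decade by default.
* `findSteadyState()` integrates in growing chunks (cap $10^5$ s
  simulated), restarting each chunk projected back onto the conserved-
  moiety manifold of the initial state (integrator round-off otherwise
  drifts conserved totals), then refines by damped Newton iteration using
  a truncated-SVD step so that near-null directions — conserved moieties —
  are never moved. Converged states leave residuals near machine
  precision; the contract tested is residual $< 10\varepsilon$.
* Serialization: the native structured-text form writes numerics with 17
  significant digits and R data as deparsed literals, making
  write–read–write bit-stable; SBML export embeds the rate-law family,
  bindings, lineage and metadata as annotations, so a round trip is
  structurally exact. Imported SBML without unit definitions is assumed
  mM/s with a loud warning.

## What the fixtures do and do not show

The synthetic fixtures (`linearChainFixture`, `toyCycleFixture`,
`calvinMiniFixture`) have known answers — analytic steady states, exact
carbon/phosphate conservation, a phosphate pool whose exhaustion is forced
by construction, a starch branch whose defective variant goes negative on
demand. They establish that the machinery is correct, not that any
particular published parameterization is reproduced: the quantitative
reproduction targets (equilibration at 0.6 s, 61-fold pool multiplication,
the normalized product table) require the original SBML files, which are
third-party artifacts; the corresponding checks activate when those files
are placed under `tests/testthat/external/`. Problem sizes in the shipped
tests were chosen for sharpness per CPU-second: networks of 3–30 species,
horizons of 10–300 s for unit tests and one 3-hour-equivalent comparison in
the acceptance suite, 100 random starts for the brute-force oracle, 1000
random expression trees for the evaluator cross-check.

## Known limitations

* No temperature or pH dependence, no enzyme-activation dynamics (RuBisCO
  activation on the 120–600 s scale is out of scope), no stochastic or
  delay dynamics, no bifurcation continuation, no metabolic control
  analysis.
* SBML support is Level 2 only; events, algebraic rules and constraints
  are rejected on import.
* The `hahn` and `zhu` variants are behavior classes under fixture
  parameters, not reconstructions of the original parameterizations —
  those remain import targets.
* Thermodynamic consistency is enforced only through declared equilibrium
  constants; there is no charge balancing.
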
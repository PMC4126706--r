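---
title: "Reducing unbalanced metabolism to a kinetic macroscopic model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reducing unbalanced metabolism to a kinetic macroscopic model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drumr)
```

## The modeling problem

Constraint-based metabolic models almost always assume balanced growth:
every internal metabolite is produced exactly as fast as it is consumed
(the quasi-steady-state approximation, QSSA), so substrate uptake maps
instantaneously to growth and excretion. Photoautotrophic microalgae under
day/night cycles violate this assumption in an essential way — they fix
carbon into carbohydrate and lipid pools during the day and burn those
pools at night to keep growing. Any model that forces `K v = 0` on the
whole network cannot represent that storage dynamic.

The DRUM (Dynamic Reduction of Unbalanced Metabolism) approach implemented
here relaxes the QSSA *locally*:

1. the reaction network is partitioned into **sub-networks** — groups of
   reactions that share a compartment, a regulatory unit or a metabolic
   function, and can credibly be assumed internally synchronous (a
   reaction may belong to several sub-networks; the shared column is
   duplicated);
2. each sub-network is assumed at quasi-steady state *on its own internal
   species* and reduced to its **elementary flux modes** (EFMs): the
   support-minimal flux distributions `e` with `K_internal e = 0` and
   irreversibility respected. Each mode collapses to one **macroscopic
   reaction** `K_SN e` over the sub-network's boundary species;
3. the metabolites `A` linking sub-networks (pathway branch points and
   storage end-products) are exempt from the QSSA and **accumulate**;
4. each macroscopic reaction gets a simple proportional kinetic rate, and
   the whole system becomes a low-dimensional chemostat ODE

   $$\frac{dM'}{dt} = K'\,\alpha(M', I)\,B \;-\; D\,M' \;+\; D\,M_{in},$$

   where functional biomass $B$ multiplies every rate (the catalytic
   machinery scales the whole metabolism), $D$ is the dilution rate and
   $I$ the irradiance.

The packaged worked example is a carbon-storage model of the microalga
*Tisochrysis lutea*: six sub-networks (photosynthesis, upper and lower
glycolysis, carbohydrate synthesis, lipid synthesis, biomass synthesis)
reduced to eight macroscopic reactions MR1–MR8 over fifteen metabolite
rows, with accumulating set `A = {GAP, G6P, PEP, CARB, PA}` and functional
biomass `B`. Counting each reversible macroscopic reaction as two directed
modes, the reduced system represents 11 elementary modes — compared with
tens of thousands for a whole-network QSSA — and carries only 10 kinetic
parameters.

```{r}
tiso <- build_tisochrysis_model()
tiso$model
```

## The elementary flux mode engine

`enumerate_efms()` is a Schuster-style nullspace tableau (double
description): reversible reactions are split into opposed irreversible
columns, the steady-state constraints are processed one internal species
at a time by combining sign-opposed candidate rows, and support-minimality
is maintained with the classical zero-set inclusion test. Two numerical
choices matter:

* **Exact integer arithmetic.** Each constraint row is rescaled to
  integers (stoichiometric tables carry at most a few decimals — the
  engine refuses coefficients it cannot scale exactly) and every combined
  row is reduced by its gcd. No tolerance ever discards a mode; floats
  appear only on output. An overflow guard aborts above $2^{52}$, which
  sub-network-scale problems never approach.
* **Two-cycle removal.** Splitting a reversible reaction creates a
  spurious forward+backward cycle; these are removed by support pattern.
  Genuine futile cycles spanning two or more distinct reactions — such as
  the ATP-dissipating mode MR2 of the worked example — are kept, because
  they are real elementary behaviours of the network.

Mode columns are normalized by their smallest-magnitude nonzero
coefficient and ordered lexicographically by support, which makes the
reduction deterministic and independent of reaction declaration order.
The engine is validated in the test suite against an independent
brute-force oracle (enumerate every support subset; keep those whose
restricted nullspace is one-dimensional with a strictly signed generator)
on a seeded corpus of random networks of up to ten reactions. Enumeration
is deliberately targeted at sub-network scale; above 10,000 candidate
modes the engine warns and suggests a finer partition rather than
attempting genome-scale enumeration.

When a sub-network yields many modes, `reduce_subnetwork()` can keep a
single representative via the yield-space projection: each biomass-forming
mode is normalized to unit flux through a reference reaction and the mode
with the lowest substrate consumption per by-product formed (here, the
best PEP/CO~2~ yield) is selected — the mode that wastes the least carbon
to respiration.

Reversible macroscopic reactions can arise two ways, and the package
supports both: `merge_reverse_pairs()` fuses modes whose stoichiometries
are exact negatives (opposite orientations of one reversible pathway),
while a reaction table may simply declare reversibility with `<->`. The
packaged fixture takes the second route — its reversible entries (MR5,
MR6, MR7) are declared, mirroring how the reduced model is usually
communicated — whereas reductions computed from sub-networks produce
directed modes that `merge_reverse_pairs()` can then fuse. The two G6P
reactions MR3/MR4 illustrate why merging is stoichiometric, not cosmetic:
they are *not* negatives of each other (their ATP terms differ), so they
rightly stay separate irreversible reactions.

## Elemental bookkeeping and lumped species

Lumped species (an "average" lipid, the functional-biomass unit) have no
tabulated formula; their carbon and nitrogen contents are inferred by
**closure**: the atom count that zeroes the elemental residual of the
reaction forming them, given the known counts of every other material
participant (`infer_composition_by_closure()`). For the packaged model
this gives C~PA~ = 36.22 from the lipid-synthesis reaction, then
C~B~ = 8.5442 and N~B~ = 1.31 from biomass synthesis. Untracked energy
cofactors (ATP/ADP, NAD(P)H/NAD(P)) are excluded from all balances — the
model deliberately does not describe their fate — and photons, written as
a reactant of photosynthesis, are a non-material pseudo-species.

Because the table's coefficients are printed to two decimals, exact
closure is impossible; the default balance tolerance is 0.05 atoms per
reaction (H and O are not checked at all: water and proton bookkeeping in
lumped reactions is unreliable). Total particulate carbon and nitrogen
are then element balances over the pools,
$X_C = \sum_A C_A A(t) + C_B B(t)$, and chlorophyll is reported as a
fixed fraction of functional biomass (default 0.05 mol/mol; the actual
ratio is a free fixture parameter, as only its constancy matters).

## Kinetics, units and the default environment

Each macroscopic reaction uses the simplest proportional law compatible
with its role (one or two rate constants — a parsimony choice):

| reaction | law | constants (calibrated) |
|---|---|---|
| MR1 photosynthesis | $k I$ | $k = 11.07\times10^{-3}$ |
| MR2 futile ATP cycle | $0$ | — |
| MR3 G6P formation | $k\,\mathrm{GAP}$ | 223.53 |
| MR4 G6P consumption | $k\,\mathrm{G6P}$ | 10.30 |
| MR5 lower glycolysis | $k\,\mathrm{GAP} - k'\,\mathrm{PEP}$ | 436.95, 5.00 |
| MR6 carbohydrate storage | $k\,\mathrm{G6P} - k'\,\mathrm{CARB}$ | 70.00, 6.50 |
| MR7 lipid storage | $k\,\mathrm{PEP}\cdot\mathrm{GAP} - k'\,\mathrm{PA}$ | $4.50\times10^{3}$, 0.60 |
| MR8 biomass synthesis | $k\,\mathrm{PEP}\cdot\mathrm{G6P}\cdot\mathrm{NO_3}$ | $2.18\times10^{4}$ |

Concentrations are in mM (functional biomass in mM of biomass units),
time in hours, irradiance in µE m^-2^ s^-1^; the constants are expressed
per mM of functional biomass so that $\alpha B$ has units mM h^-1^. MR2
is carried with identically zero rate: it exists so the reduced
stoichiometry remains a faithful image of the sub-network's elementary
modes, not because it moves mass.

The default environment is a chemostat at $D = 1\,\mathrm{d^{-1}}$ fed
with 4.018 mg N L^-1^ of nitrate (0.287 mM, taking atomic nitrogen at
14.007 g mol^-1^ — the conversion basis is a documented interpretation)
under a 12 h:12 h light cycle. The light profile is a truncated sine with
sunrise at $t = 12$ h (so midday falls at clock time 18 h) — a synthetic
stand-in for the measured irradiance of the original experiment, which is
not available. Its peak defaults to 500 µE m^-2^ s^-1^ in the packaged
fixture: with the calibrated constants, peaks much below ~200 µE m^-2^
s^-1^ cannot offset dilution at $D = 1\,\mathrm{d^{-1}}$ and the culture
washes out, whereas at a few hundred µE m^-2^ s^-1^ — a typical peak for
day/night culture experiments — the model settles into the
nitrogen-limited periodic regime (functional biomass near
$S_{in}/1.31$ mM) with the expected storage dynamics: carbohydrates and
lipids dip shortly after sunrise, peak one to three hours before sunset,
and are consumed through the night. The generic `light_signal()` utility
keeps a neutral default of 100 µE m^-2^ s^-1^.

Dissolved gases and minerals (CO~2~, O~2~, H~2~O, H, Pi, SO~4~, Mg) and
the photon pseudo-species are **clamped**: they remain rows of `K'` for
bookkeeping (the photosynthetic quotient is read off the O~2~ and CO~2~
rows) but are held constant during simulation, reflecting a pH- and
CO~2~-controlled culture where they are non-limiting. Nitrate is dynamic —
it is the limiting nutrient.

## Numerical integration

`simulate_model()` integrates with `deSolve::lsoda` (relative tolerance
$10^{-8}$ by default). A right-hand side compiled in C is used for the
square and truncated-sine light forms and is checked against the pure-R
reference `ode_rhs()` in the test suite; tabulated light falls back to
the R path. Rate evaluation clamps tiny negative concentrations to zero;
after integration, excursions above $-10^{-6}$ mM are clipped to zero
(reversible mass-action laws arrest depletion on their own, so clipping
is a safety net) and anything below that aborts with the failure time.
Initial conditions are not part of the model definition; the fixture
default starts every accumulating pool at 0.01 mM with 0.1 mM functional
biomass and nitrate at the feed concentration, and analyses discard a
ten-cycle transient, by which point the cycle-to-cycle state difference
at lights-on has fallen below $10^{-5}$ mM.

Two structural identities double as integration checks: with $D = 0$ and
CO~2~ tracked as a dynamic species, total carbon
$X_C + \mathrm{CO_2}$ is conserved along trajectories (only coefficient
rounding, bounded by the closure construction, can break it — observed
drift is at floating-point level); and with $B = 0$ every species follows
the analytic washout exponential.

## Calibration

`fit_kinetics()` minimizes the weighted squared error between simulated
and observed series. The weighting is $w_o = 1/\max(\mathrm{obs}_o)^2$,
normalizing each mixed-unit observable to unit scale — the original
objective's weighting is not recoverable, so this is a documented
interpretation. Optimization is multistart Nelder–Mead in log-parameter
space (positivity by construction; the calibrated constants span seven
orders of magnitude, which log-space handles naturally): starts are drawn
log-uniformly within bounds from a seeded generator, each is polished
with Nelder–Mead (simplex tolerance $10^{-8}$, at most 2000 iterations),
and the best point receives restart polishing — re-launching the simplex
from its own endpoint until the objective stops improving — because a
single Nelder–Mead run reliably stalls in ten dimensions. A failed
simulation scores a large finite penalty so the simplex can retreat.
Duplicate-culture averaging is a preprocessing utility
(`average_duplicates()`), not part of the objective.

On noiseless synthetic data generated from the calibrated constants, the
fit recovers seven of the ten parameters to within a few percent. The
remaining three (k~MR3~, k~MR5~, k~MR7~ — the constants consuming GAP)
are structurally non-identifiable *as a triple*: GAP equilibrates within
minutes and contributes negligibly to every observable, so scaling all
three by a common factor while GAP rescales inversely leaves the
trajectories unchanged. Their ratios are recovered accurately, and
per-parameter flat directions at the optimum are reported by the fitter
rather than hidden. This is a property of the data, not of the
optimizer: dynamic measurements of the fast pools would be needed to pin
the scale.

## What the synthetic data do and do not emulate

`generate_synthetic_observations()` stands in for a day/night chemostat
experiment: it forward-simulates past the transient, samples the
quantities such an experiment measures (particulate C and N, chlorophyll,
carbohydrates, neutral lipids, functional biomass, nitrate — by default
every 4 h over five days) and adds independent Gaussian noise scaled to a
fraction of each observable's range. It reproduces the *structure* of
such a dataset, not its reality: real measurements have correlated and
heteroscedastic errors, duplicate cultures, irregular sampling, and an
irradiance profile that is neither sinusoidal nor identical across days.
Passing the recovery tests therefore demonstrates the correctness and
identifiability structure of the fitting machinery under the model's own
dynamics — not that the packaged constants would be recovered from a real
culture.

## Problem sizes and runtimes

The shipped analyses are sized for interactive use: simulations run 20
day/night cycles at 0.25–0.5 h output resolution (well past the
transient), the EFM oracle corpus uses 25 seeded networks of at most ten
reactions, and the full parameter-recovery exercise uses 20 starts on a
five-day, 31-point observation window (a few minutes on one core, thanks
to the compiled right-hand side).

## Known limitations

* The partition into sub-networks is user-supplied. Automated splitting
  (flux-coupling clusters, topology, information criteria over candidate
  decompositions) is out of scope.
* Enumeration is exact but exponential; it is meant for sub-networks, not
  genome-scale matrices.
* The kinetic library covers the proportional forms used by the packaged
  model; saturating (Michaelis–Menten, Hill) or regulatory kinetics would
  need new forms.
* Light attenuation in dense cultures, temperature and pH dependence, and
  the night-time arrest of nitrate uptake during cell division are not
  modelled; the last is a documented discrepancy of this model family
  with observations (measured nitrogen uptake stops at dusk, the model's
  does not).
* The photosynthetic quotient is a ratio of net gas fluxes and diverges
  where net CO~2~ fixation crosses zero (just after dawn and just before
  dusk under a smooth light ramp); it is meaningful only over the
  net-photosynthesis phase of the cycle, which is how the package's
  checks evaluate it.
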
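---
title: "Models and methods: BCSC state transitions, niche kinetics, and therapy screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the models it
implements, the assumptions they carry, the parameters that matter, how the
unpublished constants were calibrated, and what the shipped tests do and do
not establish.

## The two-state plasticity model

Breast cancer stem cells are modeled as a two-state continuous-time Markov
chain: state 1 is the mesenchymal, quiescent, invasive EMT-like state
(CD44+/CD24−), state 2 the epithelial, proliferative MET-like state
(ALDH+). Throughout the package `lambda_met` is the rate *of* the
mesenchymal-to-epithelial transition (leaving state 1) and `lambda_emt` the
rate of the reverse transition; with that convention the stationary flux
balance is `pi_emt * lambda_met = pi_met * lambda_emt` and the epithelial
occupancy is `pi_met = lambda_met / (lambda_emt + lambda_met)`. Marker
frequencies map to occupancies as a simple ratio,
`pi_emt = f_mes / (f_mes + f_epi)`; the package implements both published
mappings (a tumor-initiating fraction as the mesenchymal numerator in one
cell line, CD44+CD24− frequency in the other) exactly as stated, without
reconciling their different marker-to-state conventions.

Rate estimation uses an exponential fit to a marker time course (vimentin
decay after induced MET). The default fit is ordinary least squares of
`log(value)` on time: it is deterministic, has a closed-form standard
error, and is exactly the maximum-likelihood fit under the multiplicative
log-normal noise that positive expression data carry. A
Levenberg–Marquardt refit on the natural scale is available behind
`nonlinear = TRUE`. The decay rate of the marker is an upper bound on the
transition rate it proxies; the package reports it as the estimate, as the
source analysis does, with two-significant-figure rounding for display
only (`report_rate()`).

A stored benchmark, `ips_dedifferentiation_rate = 0.0036` per cell per
day, is the published comparison value for fibroblast reprogramming. The
printed number is kept verbatim even though 1% over 28 days works out to
0.00036; the constant is used only for the qualitative contrast that state
transitions (0.02–0.08 / day) are far more frequent than dedifferentiation,
which holds under either reading.

## Mass-action reaction networks

A network is species plus channels with mass-action propensities:
`a_j` for a zero-order source, `a_j x_k` for unimolecular,
`a_j x_k x_m` for bimolecular with distinct reactants, and
`a_j x_k (x_k − 1)/2` for homodimerization (implemented for generality;
the shipped models contain none). Catalytic channels carry the catalyst on
both sides so its net stoichiometry is zero. `conserved_moieties()`
extracts integer left-null vectors of the stoichiometry matrix by rational
row reduction; it is used as a structural test instrument (e.g. every
receptor's free + bound pool is invariant, while the IL-6 pool is not,
because NF-κB transcribes it).

The niche model has 32 species and 37 channels: four ligand–receptor
binding/dissociation pairs; Stat3 and Akt activation by receptor
complexes; NF-κB activation (release of p50·RelA from IκB·p50·RelA) by
active Stat3 and Akt, with rebinding; β-catenin activation by Lin-28 and
HER2·EGFR; Lin-28/Let-7, Let-7/IL-6, mir-93/TGF-β and Lin-28/HER2-mRNA
sequestration; five cell-state transition channels; symmetric self-renewal
of epithelial BCSCs driven by active β-catenin; epithelial BCSC death; and
three transcription channels (HER2, IL-6, Lin-28). Two literal readings
are implemented as printed rather than "fixed": no cytokine degradation
channels exist, and free TGF-β (not the receptor complex) drives the
MET→EMT channel.

## Simulation: SSA, SAL, and the hybrid

`ssa_exact()` is the Gillespie direct method. `simulate_network()` is
step-anticipation τ-leaping: each channel's firing count over a leap τ is
Poisson with mean `ω_j = r_j τ + ½ (dr_j/dt) τ²`, where the drift
`dr_j/dt` comes from the chain rule over the reaction-rate-equation mean
field `dμ/dt = Σ_j r_j(μ) ν^j`. The anticipated mean is clamped at zero,
and τ is capped so no active channel's mean goes negative.

Leap selection combines three criteria:

- **Drift control** (the SAL criterion): `|dr_j/dt| τ ≤ ε max(r_j, a_j)`,
  default `ε = 0.03`. This is the documented semantics of `select_tau()`.
- **Fluctuation control** (engine refinement): per species, the leap's mean
  shift and standard deviation from the non-critical channels are both held
  below `max(ε x_k, 1)`. The drift criterion alone is blind at
  quasi-equilibria (where `dr/dt ≈ 0` but fluxes are large), and without
  this bound stationary variances inflate by roughly the relaxation rate
  times τ. The bound is what brings the leaping engine within Monte-Carlo
  error of exact SSA in the oracle tests.
- **Grid alignment**: leaps never straddle a recording time, so recorded
  states are exact leap endpoints rather than stale pre-leap states (which
  would bias growing trajectories low by ~half a leap).

**Critical channels.** Any channel that consumes a species whose count is
below `ssa_threshold` (default 10) is fired one event at a time from an
exponential clock while the remaining channels leap over the same
interval; when every channel is critical this reduces to exact SSA. This
partitioned hybrid replaces a coarser whole-step rule (switch the entire
step to SSA whenever any active channel's reactant is low) because several
niche species sit permanently near zero, which would force whole-run SSA
and make the prescribed screen sizes infeasible; the partition preserves
exactness where it matters — small counts and extinction — at a fraction
of the cost.

**Negative counts** are handled by reject-and-halve (up to 40 halvings)
with a final fallback to a single exact event, so no trajectory ever
contains a negative count (asserted across the whole test suite).

**Randomness.** The engine uses R's RNG, so `set.seed()` gives
bit-identical trajectories. Ensembles derive per-replicate seeds from the
root seed by a fixed counter scheme (`seed + 1000003 · i`, mod 2³¹-ish), so
replicate *i* is the same regardless of how many replicates run — this is
also what gives the screens common random numbers across conditions.

The deterministic companion `rre_trajectory()` integrates the RRE with
`deSolve::lsoda`; it is used for parameter calibration and is clearly a
mean-field object, not a stochastic simulation.

## Niche rate constants: the calibration

The niche model's per-channel rate constants are not published. The
defaults in `niche_rate_defaults()` were chosen in two steps and then
frozen:

1. **Scale structure.** Binding and dissociation propensities are of
   similar magnitude at the default counts; transcription is an order of
   magnitude rarer; signaling sits between. IL-6's per-particle binding
   constant is ten-fold weaker than the other ligands' because IL-6 is
   ten-fold more abundant (1000 vs 100 particles), keeping channel
   propensities comparable. Stat3/Akt activation through IL-8·CXCR1 is a
   weak auxiliary route relative to gp130 and HER2·EGFR, reflecting the
   wiring in which IL-6/gp130 is the dominant Stat3 input.
2. **Qualitative anchoring.** With the scale structure fixed, a small
   number of constants (the Lin-28 transcription rate, the
   β-catenin-activation constants, the renewal and death rates, and the
   EMT/MET transition constants) were tuned against the deterministic RRE
   trajectories until the model's documented behaviours held
   simultaneously: the untreated niche grows; IL-6 blockade shifts cells
   into the proliferative state and accelerates growth; mir-93 + BMP
   blockade shrinks the total pool while raising the quiescent fraction;
   HER2-containing blockades dip but recover through NF-κB-driven Lin-28
   unless IL-6 signaling is also removed; and only HER2 + IL-6 blockade
   eliminates both populations. The stochastic screens were run after the
   constants were frozen.

The mechanism behind the screen's discrimination is worth stating plainly.
Self-renewal needs active β-catenin, which has two activation routes:
HER2·EGFR (strong, constitutive while HER2 dimerizes) and free Lin-28
(NF-κB-driven). Blocking HER2 alone removes the first route, but the
IL-6→Stat3→NF-κB loop keeps transcribing Lin-28, which first saturates its
sequestration pools (Let-7, HER2 mRNA) and then accumulates free, restoring
renewal within a few hundred days — the population dips and regrows.
Blocking IL-6 alone leaves the HER2 route intact. Blocking both starves
β-catenin activation for longer than the death rate needs to exhaust the
population; IL-6 removal additionally keeps cells out of the death-free
quiescent state (IL-6·gp130 is the dominant MET→EMT drive), which is why
HER2+IL-6 beats HER2+Stat3 — the latter silences NF-κB equally but leaves
IL-6 free to park cells in quiescence.

The reversible subsystems (binding/dissociation, activation/deactivation,
sequestration) relax within days to weeks — fast against the 1000-day cell
dynamics — and only their equilibrium ratios couple to the cells, so those
ratios, not the absolute kinetic constants, are the calibrated quantities.
Every constant is overridable per run.

## Carcinogenesis hierarchy and Gompertz growth

Only epithelial (MET-like) BCSCs divide: symmetric self-renewal β
(→ 2 MET), asymmetric self-renewal α (→ MET + BPP, held at 0.027 per cell
per day), symmetric differentiation ρ (→ 2 BPP). The symmetric-division
fraction `f = (β+ρ)/(α+β+ρ)` steps yearly from 20% to 80% over six years
(year = 365 days, switches exactly at day 365k), with `β = 5ρ` in years
1–4 and `β = ρ` afterwards; `schedule_rates()` solves those two equations
exactly, and the healthy baseline `β = ρ ≈ 0.0034` (one symmetric event
per ~42 weeks) emerges as the `f = 0.2`, ratio-1 case. State transitions
use the niche-independent estimates (0.02, 0.08 / day), so the quiescent
fraction stays near 20%. BCSC death defaults to zero in these runs (a
config knob exists); mesenchymal cells carry no division or death
channels.

Progenitor and differentiated-cell rates are not published. They were
calibrated by `calibrate_progenitor_rates()`: a grid search over BPP
division, total BPP differentiation (split evenly between luminal and
basal fates) and differentiated-cell death, minimizing the squared
distance between the deterministic 12-year total-population trajectory and
the target Gompertz curve with the published fit (`A0 = 0.0193`,
`c = 0.00133`, `N0 = 625`, asymptote ≈ 1.2 × 10⁹ — note those three are
mutually consistent, since `625·e^{A0/c} ≈ 1.26 × 10⁹`). The grid optimum —
division 0.02, differentiation 0.06, death 8.5 × 10⁻⁴ per day — is frozen
as the default. The resulting stochastic ensembles fit the Gompertz law
with `c ≈ 0.00139` per day, R² ≈ 0.9996 on counts, and asymptote
≈ 1.3 × 10⁹ cells.

**Gompertz fitting.** `fit_gompertz()` fits `(A0, c, N0)` (or `(A0, c)`
with N0 fixed) by Levenberg–Marquardt with multi-start over the explored
grid `A0 ∈ [0.02, 0.04]`, `c ∈ [0.001, 0.002]` plus a data-driven start.
The default objective is least squares on the counts themselves — the
scale on which simulated trajectories are compared with tumor growth
curves, and the only scale on which this model's trajectory is
Gompertz-like (its early log-scale growth is convex, since the division
schedule ramps up, while the Gompertz log-curve is concave everywhere).
`scale = "log"` is the matched error model for multiplicative log-normal
noise and is what the coverage experiments use; under it the asymptotic
t-based confidence intervals achieve their nominal coverage. R² is always
reported on untransformed counts. N0 is a free prefactor and may fit below
one cell; the asymptote `K = N0 e^{A0/c}` is the physical quantity.
Confidence intervals are computed on the mean trajectory (not
per-replicate), an explicit convention.

## Therapy screens

Inhibition multiplies the rate constants of a target's affected channels
by 10⁻¹⁰, leaving initial conditions untouched. The nine-element default
target set (IL-6, IL-8, TGF-β, BMP, mir-93, HER2, Akt, Stat3, Lin-28) and
the target→channel map are documented package conventions
(`niche_inhibition_map()`), fully user-editable: a ligand blockade scales
its binding, production and any free-ligand transition channel; a receptor
blockade its dimerization and production; a microRNA knockdown the
channels in which the microRNA acts; a signaling-node inhibitor the node's
activation channels.

Screens simulate baseline plus each condition with common random numbers
(same per-replicate seeds), 100 replicates and a 1000-day horizon by
default (1000 replicates for extinction histograms). Extinction frequency
is first-passage — the fraction of replicates whose selected population
has hit zero by the evaluation day on the recording grid — which is
monotone in time by construction and matches the absorbing character of
total-BCSC extinction. Ranking uses total-BCSC extinction frequency at the
horizon (descending), then mean total BCSC at the horizon (ascending),
then the condition label; the screen's starting point is the standard
initial counts (not a grown tumor state), with an override available.

## Synthetic data

All estimator inputs are generated, never downloaded: exponential marker
series with multiplicative log-normal noise (default σ = 0.05, n = 20,
grid spanning ≥ 3 e-foldings), exact per-cell two-state CTMC occupancy
data, noisy Gompertz observations, and four analytic fixture networks
(pure death, linear birth–death, reversible dimerization, two-state
switch) that carry their closed-form moments. Generators are pure
functions of their spec (same spec → identical bytes) and each dataset is
written with a JSON spec sidecar that regenerates it exactly. The noise
model is a deliberate simplification: it does not mimic qPCR or
flow-cytometry error structure, plate effects, or censoring, so passing
recovery tests demonstrates estimator correctness under the declared noise
model, not robustness to real measurement pathology.

## Problem sizes and tolerances

The shipped tests use: oracle-equivalence ensembles of 1000 replicates per
method per fixture, compared within three combined standard errors for
means and variances; a τ→0 distributional check on the two-state switch at
ε = 0.005 (proportion test, α = 0.01); 24-replicate (≥ 20) 12-year
carcinogenesis ensembles for the Gompertz fit; 100-replicate screens at a
1000-day horizon for the qualitative orderings, with 1000 replicates for
the winning pair's extinction histogram; 100 seeded repetitions for the
confidence-interval coverage experiment; and 50–60 replicates per value
for the sensitivity sweeps. These sizes put Monte-Carlo error comfortably
below the effect sizes being asserted while keeping the whole suite in the
minutes range on one core.

## Known limitations

- Mass-action, well-stirred kinetics with particle counts of similar
  magnitude for cells and molecules — a declared simplification; real
  cytokine copy numbers would dwarf cell counts.
- No spatial structure, delays, resource limitation, mutation, or
  dose–response (inhibition is the single 10⁻¹⁰ factor); no scheduling of
  therapies.
- The niche rate constants are calibrated, not measured; conclusions
  should be read as properties of the calibrated wiring, with the
  sensitivity sweeps probing the two parameters the screen conclusions
  depend on most.
- Exact replication of any particular published stochastic trace is not
  attempted (leap parameters are not published); agreement is statistical.
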
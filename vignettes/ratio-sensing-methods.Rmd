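---
title: "Models and methods: ratio-sensing in GAL signal integration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: ratio-sensing in GAL signal integration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ratiosense)
```

`ratiosense` asks a single question of several small circuits: when a
cell reads two competing nutrient signals, under what conditions does
the induction decision depend on their *ratio* rather than on either
absolute level? The package answers it with closed-form steady states,
decision-front geometry, and numerical censuses, each cross-checked
against an independent dynamic (ODE) oracle in the test suite.

All concentrations are in arbitrary units on log10 axes; the package
never claims physical units. Axis convention throughout: x = log10
galactose, y = log10 glucose, slope = dy/dx.

## The uptake layer

Sugar import is a two-step process: extracellular sugar loads a free
transporter (association `kf`, dissociation `kr`), and loaded
transporters unload into the cytoplasm at `k_trans`; intracellular sugar
is consumed at turn-over rate `gamma`. With a conserved transporter pool
`T_total` shared by both sugars, mass action gives a five-species system
(`transporter_rhs()`), and its steady state has the closed form
implemented in `transporter_steady_state()`:

$$\mathrm{gal_{in}} = \psi \cdot
\frac{1}{1 + (K_{gal}/\mathrm{gal_{ex}})^{n_{gal}}
\left(1 + (\mathrm{gluc_{ex}}/K_{gluc})^{n_{gluc}}\right)}$$

with $K_{gal} = (kr_{gal} + k_{trans})/kf_{gal}$ (glucose mirrored) and
$\psi = k_{trans} T_{total} / \gamma$, the transport capacity — the
ceiling of intracellular sugar. Induction of the pathway is taken
proportional to intracellular galactose, so iso-induction contours are
iso-`gal_in` contours.

**Cooperativity.** The Hill exponents enter through the lumped occupancy
ratio: $s/K$ becomes $(s/K)^n$, applied to the whole lumped constant
rather than to the association step alone. At steady state the two
choices are indistinguishable — the front slope $n_{gal}/n_{gluc}$ and
intercept $\tfrac{1}{n_{gluc}}\log_{10}(K_{gluc}^{n_{gluc}}/K_{gal}^{n_{gal}})$
are invariant to where the exponent is attached — so the package uses
the lumped form, and the dynamic oracle applies the same generalization
to the association flux so that both routes share one steady state.

**Regimes.** When glucose saturates the transporters
($\mathrm{gluc_{ex}} \gg K_{gluc}$, checked at 100× margins by the
preset loader), the half-maximal contour is straight over the whole
window: full-range ratio sensing. When $K_{gluc}$ falls inside the
titration window, the low-glucose half of the window is unsaturated and
the circuit degrades into a galactose threshold sensor there — the
compound mode. The two shipped uptake presets place $K_{gluc}$ at
$10^5$ (window $10^7..10^{13}$) and $10^7$ (window $10^5..10^{10}$) to
realize each regime.

## The transcription layer

Intracellular galactose and glucose bind internal sensors, forming an
active activator and repressor (quasi-equilibrium, since sugar–sensor
binding is much faster than transcription):
$A^* = \mathrm{gal_{in}}/(K_G + \mathrm{gal_{in}}) \cdot A_{total}$,
mirrored for the repressor with $K_M$. Both compete for the GAL1
cis-regulatory element (CRE), whose copies are conserved across free,
active and repressed states. At equilibrium the actively transcribed
fraction is

$$f = \frac{1}{1 + \frac{1}{\phi_A}\left(\frac{K_G}{\mathrm{gal_{in}}} + 1\right)
\left(1 + \frac{\phi_R}{K_M/\mathrm{gluc_{in}} + 1}\right)}$$

with activation and repression capacities $\phi_A = A_{total}/K_A$,
$\phi_R = R_{total}/K_R$. The induction readout is this active fraction
itself; no protein synthesis/decay layer is added. In the regime

$$\mathrm{gal_{in}} \ll K_G, \qquad K_M/\phi_R \ll \mathrm{gluc_{in}} \ll K_M,$$

the front is $\log \mathrm{gluc_{in}} = \log \mathrm{gal_{in}} +
\log(K_M/K_G) + \log(\phi_A/\phi_R) + \log(1/\ell - 1)$: slope exactly
1, intercept set by relative sensor affinity and relative regulatory
capacity.

**Operationalizing "≪".** The models' inequalities are asymptotic; the
package makes them checkable with a configurable multiplicative factor,
default 100× ($a \ll b$ iff $100a \le b$). `check_ratio_regime()`
reports the raw margins alongside the booleans so downstream code (and
the tests) can tighten or relax the factor explicitly. Each of the
three inequalities has a shipped preset that deliberately violates it;
the violation converts one end of the front into a threshold segment,
and `classify_pattern()` is required (by the tests) to recover the
resulting compound patterns.

## Concatenation

`concatenated_response()` composes the two layers exactly:
the uptake steady state supplies $\mathrm{gal_{in}}, \mathrm{gluc_{in}}$
to the CRE occupancy form. A useful exact identity:
$\mathrm{gal_{in}}/\mathrm{gluc_{in}} =
(\mathrm{gal_{ex}}/K_{gal})/(\mathrm{gluc_{ex}}/K_{gluc})$ — the uptake
layer transmits the (affinity-scaled) external ratio undistorted, which
is why the combined system is so robustly ratiometric. Substituting the
uptake expressions into the transcriptional regime inequalities, and
using that both transporter saturation fractions are bounded by 1,
yields the sufficient conditions $K_G \gg \psi$, $K_M \gg \psi$ with
$\phi_R$ large, checked by `check_combined_conditions()`.

**Preset pairing.** The 2×4 combined design reuses the two uptake and
four transcription presets. Because the stand-alone transcription
presets are tuned for inputs spanning the identity window, they are
co-scaled before composition (`scale_for_combination()`): multiply
$K_G$ and $K_M$ by one common factor until both clear $100\psi$, then
multiply $\phi_A$ and $\phi_R$ by a second common factor until the
repression-capacity condition clears 100× at the grid's minimal glucose
saturation. Both rescalings leave the front position
$(\phi_A/\phi_R)(K_M/K_G)$ unchanged, so the scaling rule repositions
regimes without moving fronts. The factors applied to each pair are
recorded in the `combined_presets()` output.

## Network motifs

The generalized unit (`generalized_active_fraction()`) replaces the
constant pools with solved effective pools. Each node carries one of
five states: none, positive/negative auto-regulation, or a coherent
(inhibitory) / incoherent (promoting) feedforward edge from the other
node's active form. Regulation uses saturating first-order forms —
negative: $X_0/(1 + Z/K)$; positive: $X_0 (Z/K)/(1 + Z/K)$ — the
minimal mass-action-consistent choices. They are pinned by a required
reproduction test: in their deep-regulation regimes they must reproduce
the analytic front formulas of all eight single-motif circuits,
including the square-root intercept terms (negative auto-activator),
the squared terms (negative auto-repressor), and the shifted arguments
(positive auto-regulation, incoherent edges). The slope multipliers are
1/2 for negative auto-regulation at the activator and for the
repressor⊣activator coherent edge, 2 for their mirrors on the repressor
side, and 1 for all positive/incoherent variants.

**Solving the pools.** Auto-regulated nodes have exact scalar fixed
points (the stable root of a quadratic for the negative form; the
nonzero branch $X_0 - K/\mathrm{occ}$ of the positive form where it
exists, else extinction at 0). A single feedforward edge is an ordered
evaluation. Only configurations with feedforward edges on both nodes
couple the two pools; there the fixed point is found per grid point by
a bracketed monotone root solve on the active activator — unique
because all forms are first order (no cooperativity, hence no
bistability), with mutual activation's extinct state handled by an
onset check. A damped fixed-point iteration is kept internally as an
assumption-free cross-check and is compared against the direct solver
in the tests; the direct solver replaced it as the primary path because
the iteration slows critically near the positive-auto onset.

**The census.** `enumerate_configurations()` lists the 5×5 = 25 state
pairs. For the numerical census, per-node constants are fixed once from
a margin analysis (deep-regulation inequalities at roughly 100× along
in-window fronts): inhibitory motif constants sit where the regulating
active form exceeds them a hundredfold, and promoting-edge constants
are small so those edges are saturated on — a promoting edge starved by
its partner's suppression otherwise degenerates the front into a pure
glucose threshold. Each configuration's repressor baseline $R_0$ is
then rescaled by a one-dimensional root solve so that the normalized
half-maximal front passes through the centre of the titration window
(falling back to anchor points displaced toward the maximal-induction
corner for circuits whose working region excludes the centre, e.g.
extinction of a positively auto-regulated pool at low input). Centring
chooses where the front sits, not what slope it has; it was fixed as
part of preset construction, before any census outcome was read, and
the tests additionally require the resulting 6/13/6 partition to be
invariant under twofold perturbation of all motif constants.
`census_slope_multipliers()` bins fitted slopes to the nearest of
{0.5, 1, 2} within ±20% and flags (rather than bins) fits with RMS
residual above 0.15 log10 units or fronts shorter than 4 points.
Mixed configurations with opposing motifs on the two nodes have no
printed closed form and are handled numerically only; empirically they
cancel back to slope 1, completing the 13 neutral circuits.

## Decision fronts and classification

Model surfaces are monotone (increasing in galactose, decreasing in
glucose), so the level contour is extracted by per-glucose-row monotone
interpolation of log-induction against log10 galactose — one ordered
crossing per row, no marching squares. Interpolating in log-induction
matters: induction varies as a power of concentration near the front,
so log-linear interpolation is nearly exact there. Rows that do not
cross contribute no point; fronts with numerically constant galactose
coordinates are flagged `vertical` instead of reporting an infinite
slope. `fit_front()` is ordinary least squares of y on x with the RMS
residual reported.

Classification pools contour points from both scan directions (per
glucose row *and* per galactose column) because a near-horizontal
segment is sampled by only a handful of rows but by one point per
column, and vice versa. Sliding-window local slopes (window 5) are
binned: |slope| > 10 → galactose threshold, < 0.1 → glucose threshold,
else ratio; one class on ≥ 90% of points labels the surface, otherwise
it is compound with a per-segment breakdown. The numeric thresholds
(10, 0.1, 90%) are package constants exposed as arguments — the models
define the limiting geometries but no sharp criterion.

## Synthetic titration data

`make_log_grid()` builds the double-gradient layout: log10-uniform
axes, default 30 points per axis over $10^{-4}..10^{2}$ a.u. — wide
enough to straddle every transcription preset's constants; uptake
presets carry their own, wider windows. `normalize_surface()` divides
by the value at the (max galactose, min glucose) corner — in theory the
maximal-induction condition — and clips to [0, 1].
`add_measurement_noise()` applies seeded multiplicative log-normal
noise, $v \mapsto v\,e^{\varepsilon}$,
$\varepsilon \sim N(0, \log(1+\mathrm{cv}))$: induction values are
positive and fold-change-like, so multiplicative scatter is the natural
model. The generator emulates the *layout and scatter* of titration
induction maps, not their biology: no single-cell bimodality,
cell-to-cell variability, growth-history effects, or measurement
saturation. Passing tests therefore demonstrate correctness of the
models and of the front machinery under idealized monotone surfaces
with multiplicative noise — not agreement with any particular
experimental strain.

## Numerical choices

- **Steady-state oracles.** `deSolve::lsoda` (stiff-capable), rtol
  1e-11, chunked integration with the horizon set to ≥ 20 of the
  slowest relaxation times and stretched 1.5× per chunk. For the CRE
  system the slow mode is the active⇌repressed partition exchanging
  through a depleted free pool, whose rate is bounded below by
  min(krA, krR); those bare dissociation rates are included in the
  time-scale floor. Steady state is declared when the relative
  derivative norm falls below 1e-9, or when the state moves less than
  that over a full chunk — the second clause covers parameter sets
  where flux cancellation noise (rtol × flux magnitude) floors the
  derivative above the first criterion.
- **Zero inputs.** `gal_ex = 0` (and `gal_in = 0`) short-circuit to
  zero induction as exact limits, avoiding division by zero.
- **Problem sizes.** 30×30 grids for all headline fronts and the
  census; 240-point glucose axes for the extreme cooperativity ratios
  (a slope-1/20 front crosses only a handful of rows on a 30-row
  grid); 20 random parameter sets per oracle-equivalence property;
  50 seeded replicates for the noise benchmark. These sizes keep each
  check well resolved — front-fit discretization error is far below
  the asserted tolerances — while the whole suite runs in seconds.
- **Determinism.** All steady-state computations are deterministic;
  the only randomness is the noise generator, which takes an explicit
  seed and restores the session RNG state.

## Known limitations

- The communal transporter pool is a single lumped species; distinct
  hexose transporter isoforms or Gal2p-specific kinetics are out of
  scope, as is feedback from GAL gene expression to transporter
  abundance.
- The Gal3p/Gal80p/Gal4p sequestration cascade is abstracted into one
  activator species; Mig1 phosphorylation and shuttling into one
  repressor species.
- Time-resolved induction dynamics are internal oracle machinery, not
  a deliverable; all outputs are steady states, so dynamic motif
  properties (pulse filtering, delays) are not modelled.
- Parameter presets realize the qualitative regimes through their
  stated inequalities at documented margins; they are not fits to any
  experimental strain, and the robustness statements carried by the
  intercept formulas (e.g. square-root dependence on pool sizes) are
  structural, not quantitative claims about yeast.
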
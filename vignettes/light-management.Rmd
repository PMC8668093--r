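---
title: "Designing artificial light schedules with greenlight"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing artificial light schedules with greenlight}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Controlled-environment agriculture pays for every photon. A grow-room light
schedule is described here by six properties of a periodic waveform: the
period `Pr` (h), the photoperiod `Ph` (h of light per cycle), the phase of
dawn `Dw` (h), the twilight duration `Tw` (h, the width of the light/dark
transition), the relative amplitude `A` (1 = 100% intensity) and a constant
background offset `Δl`. greenlight asks: which schedules make *Arabidopsis*
flower early and stay compact, and what do they cost in LED energy?

The pipeline has four stages, each an exported function:

1. **Waveform** — `light_profile()` / `evaluate_light()` build the smooth
   periodic waveform
   \[
   L(t) = \Delta l
   + \tfrac{A}{2}\!\left[1+\tanh\tfrac{P_r\phi}{T_w}\right]
   - \tfrac{A}{2}\!\left[1+\tanh\tfrac{P_r\phi-P_h}{T_w}\right]
   + \tfrac{A}{2}\!\left[1+\tanh\tfrac{P_r\phi-P_r}{T_w}\right],
   \qquad \phi = \operatorname{frac}\!\big((t+D_w)/P_r\big),
   \]
   which plateaus at `Δl + A` during the photoperiod and `Δl` in the dark,
   with sigmoidal transitions of width about `Tw`. The fractional-part
   construction makes it exactly periodic; `Dw > 0` advances the waveform
   (phenotypes are invariant to `Dw`, so only the convention matters).

2. **Clock** — `simulate_entrained()` integrates a circadian gene-network
   model under the waveform until it settles on its entrained limit cycle
   and records one period.

3. **Phenotypes** — `phenotypes()` converts the trajectory: hypocotyl
   length is \(a_1 \int_0^{P_r}(\min(ATHB2(t),a_3)-a_2)\,dt\) mm and days
   to flower is the hyperbola \(d_0 + a_4/(1-\mathrm{FT}_{area}/a_5)\) of
   the FT period-integral, with the published calibration
   `d0 = 16.55, a1 = 0.9, a2 = 0.03103, a3 = 0.8, a4 = -2308.141,
   a5 = 0.02`. FT areas below `a5` put the hyperbola past its pole; the
   (negative) value is returned with `NEGATIVE_DAYS` and
   `FT_AREA_BELOW_A5` flags rather than suppressed, because it simply
   marks schedules outside the calibration range (near-zero photoperiods).
   Two derived schedule metrics follow: the *effective light duration for
   flowering* `days × 24 × Ph/Pr` (total light-ON hours until flowering)
   and the annual LED driver energy
   \(E_c = V_{out} I_{out} A (P_h/P_r)(N \times 24)/(\eta_{LED} 10^6)\)
   MWh/year for a 48 V, 10.5 A, 90.5%-efficient driver over 365 days.

4. **Search** — `sweep_single()` varies one property at a time;
   `collective_stage1()` (period × photoperiod) and `collective_stage2()`
   (amplitude × offset, with stage-1 fixed) perform the two-stage grid
   search; `summarize_influence()` tabulates per-property leverage.

## The clock models

The simulation driver is model-agnostic: a `clock_model()` bundles species
labels, a right-hand side `f(t, state, L(t), params)`, a documented initial
state and parameters, and anything satisfying that contract can be entrained
— including a user's transcription of a full published Arabidopsis
gene-network model. Two models ship with the package.

**`toy_clock_model()`** is the one-variable driven relaxation
`dx/dt = k(L(t) − x)`. Its periodic steady state is known in closed form
(for a square wave the cycle mean of `x` is the duty-cycle mean
`Δl + A·Ph/Pr`), so it anchors the test suite: quadrature, entrainment
bookkeeping, sweep mechanics and the monotone chain *more light → larger FT
area → fewer days* can all be checked against arithmetic.

**`coincidence_model()`** is the package's own 12-species reduction of the
clock-with-outputs architecture used in photoperiodism modelling:

* a *dark accumulator* `P` charges at night and discharges abruptly in
  light, so the product `light × P` fires an acute dawn pulse of a morning
  gene (`Mm`/`M`, LHY/CCA1-like);
* a two-stage kinetic *timer* low-passes `M`, placing a broad window
  roughly 8–16 h after dawn;
* the timer drives an *evening complex* `E` (light-destabilised, so it
  rises after dusk) that represses the morning gene, closing the loop;
* *CO* mRNA is transcribed when the timer is high and both `M` and `E` are
  low (a late-day window); CO protein is translated and stable only under
  a sharp strong-light gate (Hill exponent 8, threshold 0.8), so FT is
  produced only where the window coincides with bright light — the
  external-coincidence mechanism that makes FT area rise steeply with
  photoperiod;
* a *PIF-like* factor integrates darkness slowly (20 h turnover) and is
  destroyed by even faint light; it drives ATHB2 above a light-independent
  basal level, so hypocotyls lengthen with night length and plateau in
  long days.

### Calibration

The kinetic constants were fixed once, against canonical *Arabidopsis*
photoperiod physiology, before any comparison with a specific reference
dataset, and not revisited afterwards. The anchors were: days to flower
roughly 30–40 under 12 h light / 12 h dark, saturating near 20–25 under
16–21 h days and reaching 80–120 under 8 h days; hypocotyl length
decreasing with photoperiod from ~4–5 mm (short days) through ~3 mm
(12 h) to a ~1–1.3 mm long-day plateau; basal FT in darkness below the
`a5` pole so that continuous darkness yields flagged, non-physiological
flowering times. Three structural choices encode trends rather than
numbers: the strong-light CO gate makes long twilights shorten the
*effective* bright day (days to flower deteriorate at `Tw = 3 h`) and makes
sub-nominal amplitude costly; the offset benefit runs through night-light
suppression of the evening complex and saturates by ~5% background light;
and fast evening-complex turnover keeps the loop 1:1 entrained for periods
down to 16 h (slower turnover produced 2:1 subharmonic locking in short
T-cycles).

What the model does *not* emulate: it is a reduction, not a transcription
of any published 48-equation system, so its absolute phenotype values
differ from any particular published parameterisation (its nominal 12L:12D
schedule flowers at ~33 days where a specific published model may print a
different value); temperature input, light quality and stochastic gene
expression are out of scope. Passing the trend and property tests therefore
demonstrates the pipeline and the mechanism classes, not numerical
agreement with any one reference model — for that, plug a transcription of
that model into `clock_model()`.

## Entrainment protocol and numerics

`sim_settings()` defaults: integrate from the model's documented initial
state one cycle at a time with `deSolve::lsoda` (`rtol 1e-6`,
`atol 1e-9`); after each cycle compare consecutive cycle-start states with
the relative sup-norm `max |a−b|/(1+|a|)`; declare entrainment when at
least 12 cycles have run and the residual is below `1e-4` (extending to at
most 40 cycles — short-period schedules lock more slowly); then record one
period on a 0.05 h grid, which resolves the sharpest default twilight.
Species are floored at zero after each cycle to absorb solver undershoot
within the absolute tolerance. The internal step is capped at
`min(0.25, max(Tw, 0.01))` h so the solver can never leap over a light/dark
transition — without the cap, adaptive steps in the dark plateau can skip a
sharp dawn entirely. Two further conventions: `Tw = 0` is disallowed
(it divides the tanh argument); use `1e-4` h for an ideal square wave, and
a non-24 h period simply redefines one cycle as one `Pr`.

Halving the output grid changes the phenotype integrals by well under
0.1% (tested), so trapezoidal quadrature on the native grid is used with no
resampling.

## Sweeps, feasibility and the recommendation rule

Default single-property grids: photoperiod 0–24 h step 1; offset 0–5% step
1%; amplitude 0.90–1.10 step 0.02; dawn −6 to 6 h step 2 (any symmetric
range works — phenotypes are dawn-invariant); twilight 0.01–3 h on a
log-then-linear ladder; period 16–32 h step 2 with `Ph = Pr/2`. Stage 1
spans `Pr ∈ {18,…,32}` × `Ph ∈ {12,…,28}` (cells with `Ph > Pr` skipped and
counted); stage 2 spans `A ∈ {0.97,…,1.03}` × `Δl ∈ {0,…,0.05}`. All grids
are arguments or config entries. Failed cells are recorded per row and
never abort a sweep; a trajectory cache keyed by profile lets overlapping
grids re-use simulations.

A row is *feasible* if neither phenotype exceeds its threshold (by default
the nominal baseline values — "no worse than the standard schedule") and
days are non-negative. The recommendation rule then works on the feasible
set: the preferences for a natural 24 h period and for no constant
background light are *soft* — each is enforced only when some preferred row
lies within 1.5 days of the unconstrained optimum, so a practical schedule
is chosen over a marginally faster exotic one, but never over a decisively
faster one. Within the surviving pool, days to flower are minimised with
ties broken by lower energy, then lower effective light duration, then zero
offset. "Comparable" alternates (reported alongside the optimum, ranked by
effective light duration) are rows with shorter photoperiods within 1.5
days and 0.1 mm of the optimum. The margins are reporting conventions, not
fitted quantities.

## The synthetic generator

`make_trajectory()` produces trajectories whose period-integrals are known
in closed form (constant, sinusoid, triangle — area `mean × period`), with
optional seeded Gaussian noise clipped at zero, plus the toy-clock kind.
These exist so every converter and the whole sweep engine can be tested
without any gene-network model; they emulate the *interface* of entrained
expression data (periodic, non-negative, labelled FT/ATHB2 channels), not
the waveform shapes of real transcripts. Noise defaults to zero because the
pipeline itself is deterministic.

## Known limitations

* Days to flower versus twilight is non-monotone in the compact model: a
  shallow dip near `Tw ≈ 1 h` precedes the deterioration at `Tw = 3 h`,
  because moderate night-side twilight light behaves like a beneficial
  offset before the bright-day erosion dominates.
* Amplitude sensitivity below `A = 1` is strong but its magnitude is a
  model property, not a measured dose-response.
* The energy model is the driver rating equation: offset and twilight do
  not enter it, and `Ec` is linear in `A` and `Ph/Pr` by construction.
* Continuous-light cells (`Ph = Pr`) are legal inputs and can win the
  feasibility ranking; horticultural constraints beyond the two phenotypes
  are not modelled.

## Problem sizes

The test suite runs the compact model at a 0.1 h output grid and re-uses a
shared trajectory cache (about a dozen distinct entrainments); sweep
mechanics are exercised on the toy clock. The analysis script
(`scripts/acceptance.R`) runs the full 25-cell photoperiod sweep and the
individual cells it reports at the default 0.05 h grid. These sizes are the
package's standard working resolution; halving them is tested to change
integrals by <0.1%.
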
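---
title: "Models and methods: p53-Mdm2-MdmX network dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: p53-Mdm2-MdmX network dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(p53mdmx)
```

## The biological question and the model

p53 is held in check by two structurally related binders. Mdm2 is a
ubiquitin ligase that promotes p53 degradation and is itself a p53 target
gene, closing a delayed negative feedback loop that can make p53 pulse
after DNA damage. MdmX binds p53 and Mdm2 but has no ligase activity of
its own, so its regulatory role is not obvious: it only forms complexes.
This package implements a mass-action kinetic model built to ask what
those purely non-enzymatic interactions do to the dynamics of the loop.

The network comes in two variants built by `build_network()`:

* **simple** (14 species, 33 reactions): free and phosphorylated p53,
  Mdm2 and MdmX; the p53:Mdm2, Mdm2:MdmX, Mdm2:MdmXP and p53:MdmX
  complexes; the phospho-p53 dimer and tetramer; and a promoter that the
  tetramer occupies. The occupied promoter produces Mdm2 directly
  (rate symbol `k33`), standing in for transcription plus translation.
* **full** (16 species, 38 reactions): the promoter complex instead
  produces an explicit mRNA species which produces Mdm2, and
  unphosphorylated p53 can occupy the promoter to drive basal
  transcription. This variant is the one fitted to data-like targets.

Every reaction is elementary mass action of order at most two;
homodimerization fluxes use the deterministic convention `k x^2`. The
promoter moiety (`x13 + x14` and, in the full variant, `+ x16`) is
conserved exactly, which the stoichiometry tests verify, and which has a
numerical consequence used throughout: the Jacobian always has an exact
zero eigenvalue, so steady-state Newton solves replace the free-promoter
equation with the conservation constraint, and linear stability is read
from the conservation-reduced Jacobian.

`p53 activity` means promoter occupancy by tetramers (`x14`) in the
simple variant, read at a fixed early time `t = 55` AU, and the maximum
of the mRNA species (`x15`) over 0–180 min in the full variant.

## Parameters and protocols

Six published rate-constant columns are bundled
(`load_parameter_set("col4")` … `"col9"`): an initial exploratory set, two
oscillatory simple-model sets (one using a 50-time-unit delay on Mdm2
production instead of the positive feedback), a heterodimer-knockout
study set, and two full-model sets fitted from the two oscillatory
regions found by the parameter survey (labelled by their search origin,
OSC1P1- and OSC2P1-derived). Cells printed as scan ranges carry a
documented default (log-midpoint of the range, or the middle entry of a
printed list); every routine that scans them sets them explicitly, so the
defaults never silently decide a result.

DNA damage is a constant phosphorylation input `k3 = k8 = k17 > 0`
switched on at `t = 0`; the full-model sets additionally switch basal p53
production from 0.003 (pre-damage) to 0.01 (post-damage).
Early-response protocols start from the damage-free steady state
(`pre_equilibrate()`); late-response protocols start from the default
initial state (everything zero except the free promoter) without
pre-equilibration, matching how the long oscillatory runs were done.
Early simple-model studies cut the transcription feedback
(`k33 = k14 = 0`) to isolate the transient mechanism.

One modelling choice deserves emphasis: an MdmX production fold (the
`k15` scans at 1/100…100-fold) is treated as a property of the cell and
therefore applies during pre-equilibration too. The reservoirs of
p53:MdmX and Mdm2:MdmX that drive the switch-like early response are
built *before* damage; applying the fold only at damage onset would
change the mechanism being studied.

Two inputs the sources do not print numerically are fixed once and
documented rather than fitted: the total promoter concentration
(`promoter_total = 1` concentration unit, configurable) and the initial
condition of late-response runs (the default initial state). The
early-response percentage changes are sensitive to the promoter total
(see Limitations); all analyses keep the default.

## Numerical methods

* **Integration.** `deSolve::lsoda` with the analytic mass-action
  Jacobian supplied for stiff steps; `rtol = 1e-8`, `atol = 1e-10` by
  default, and protocols expose both so tolerance-refinement checks are
  one argument away. Output is sampled on a fixed grid (1 time unit by
  default) regardless of internal steps.
* **Delay variant.** `deSolve::dede()` with the lagged promoter
  occupancy entering the Mdm2-production flux and the constant initial
  history; `tau = 0` falls back to the plain ODE path and is tested to
  agree with it.
* **Damage-free steady states.** With the phosphorylation input at zero,
  every phosphorylated species (and everything downstream: dimer,
  tetramer, occupied promoter) vanishes at steady state, the MdmX balance
  collapses to `x5 = k15/k16`, and only free p53 and free Mdm2 remain
  coupled; these two are solved by a damped Newton iteration and the full
  state is reassembled and verified against the complete right-hand side
  (`max|rhs| < 1e-9 (1 + max|state|)`). This reduction matters in
  practice: at high Mdm2 production the Mdm2:MdmX reservoir equilibrates
  on ~1e9-minute timescales, far beyond any reasonable integration
  horizon. A long-integration + Newton fallback covers parameter regimes
  the reduction cannot certify. The reduction also exhibits a structural
  fact used as a test invariant: the damage-free steady levels of the
  non-MdmX species are independent of the MdmX production rate.
* **Steady-state Newton solves.** Damped (residual-monotone) Newton with
  the conservation-constrained Jacobian; the line search is
  unconstrained, because boundary steady states (species exactly zero)
  jam a positivity-projected search, and genuinely negative solutions
  are rejected after convergence instead. Convergence uses a
  state-scaled residual criterion, since branch continuation visits
  steady states whose components span many orders of magnitude.
* **Branch tracing.** Natural-parameter continuation along an ordered
  control grid (each solution seeding the next solve) with up to 8
  step-halvings between grid points; Hopf points are bisected on the
  leading real part of the reduced spectrum to a relative control
  tolerance of 1e-6.
* **Hopf criticality.** The first Lyapunov coefficient at the Hopf
  point, via the projection formula. Because mass action is at most
  quadratic, the bilinear form is *exact* — a difference of two
  Jacobians — so no higher-order derivative tensors are approximated and
  the classification is plain linear algebra. This was chosen over
  amplitude-scaling fits after measuring the near-onset eigenvalue
  scale of the oscillatory set (~1e-5 per AU at a few percent from
  onset): resolving asymptotic amplitudes there needs ~1e6-AU
  integrations per probe, and one of the three Hopf points is nearly
  degenerate (|l1| ~ 2e-7), where finite-time probes misclassify. The
  implementation is validated two independent ways in the tests: against
  the planar closed-form normal-form coefficient on random quadratic
  systems, and against shooting (a Floquet-unstable small orbit exists
  on the stable side of the one subcritical point).
* **Periodic orbits.** Single shooting: Newton on
  `phi_T(y0) = y0` with a Poincaré phase anchor (the monitored species'
  derivative vanishes at `t = 0`), finite-difference monodromy, and
  Floquet multipliers after discarding the trivial flow and
  promoter-conservation multipliers. Shooting is well-conditioned near
  onset (small, nearly sinusoidal cycles) and on the moderately
  relaxational full-model cycle; it is *not* used on the deeply
  relaxational simple-model cycles (period ~25,000 AU), where
  single shooting is ill-conditioned — long integration serves there.
* **Peak detection.** Local maxima above a prominence threshold of 5% of
  the post-transient range, after discarding the first 20% of the
  window; the period is the median peak-to-peak interval and is flagged
  undefined with fewer than three peaks.
* **Sensitivity.** Central finite differences with relative step
  `1e-3 k_j` (step-halving agreement is tested), normalized pointwise by
  `k_j / x15` with a 1e-12 floor on `x15`, trapezoid-integrated over
  0–180 min, ranked by absolute integral. The perturbation applies to
  the whole protocol including pre-equilibration.

## The parameter survey and its synthetic targets

The survey algorithm (`neighbor_search()`) draws candidates uniformly in
log10 space within a radius of the current center, promotes any
improvement to be the new center, and doubles the radius (default start
0.1 decade, cap 2 decades) after 200 stagnant evaluations. Stage 1
searches 15 oscillation-relevant constants with the ties
`k7 = k5 = k2`, `k14 = 0.2 k13`, `k8 = k3`, `k9 = k4 = 0.02 k3`; stage 2
searches the 11 data-fit constants with `k10 = k17 = k3`,
`k4 = k9 = k18 = 0.02 k3`. The stage-2 description mentions a
12-dimensional space but lists 11 symbols; the 11 listed symbols are
implemented. Stage-1 acceptance additionally requires the oscillation
floor (maximum promoter occupancy above 1e-4).

The external calibration data are not printed numerically anywhere, so
the package generates synthetic stand-ins (`target_bundle()`), and all
fitness machinery is exercised against those:

* an oscillation pattern built from raised-cosine pulses on a baseline
  (pulsatile rather than sinusoidal, as p53 dynamics are observed to
  be), default period 360 min = 6 h, six pulses, optional damping and
  seeded Gaussian noise;
* Nutlin fold-change curves `1 + (plateau - 1)(1 - exp(-rate t))` with
  default plateaus 3 (p53), 5 (Mdm2), 1.5 (MdmX) and rate 0.005/min —
  fold-increases of a few over ~24 h, the scale reported for
  Nutlin-treated cells;
* total-protein ratio targets Mdm2/p53 = 2 and MdmX/Mdm2 = 1, plausible
  for a p53-wild-type line with active Mdm2 feedback.

The exact composite fitness used originally is not published; here it is
the equal-weight mean of three [0, 1] sub-scores: the lag-maximized
cross-correlation mapped `(s + 1)/2`, `exp(-d)` of the mean RMS relative
deviation of the three Nutlin curves, and `exp(-d)` of the mean absolute
log-error of the two ratios. The mapping is monotone in each data fit,
so the 0.25 success threshold keeps its meaning as "all three components
at least moderately matched". The Nutlin protocol itself blocks only the
p53–Mdm2 association (`k11 = 0`) from a pre-equilibrated, damage-free
state.

Because these targets are synthetic, passing tests show that the
machinery — simulation, scoring, search, selection — behaves correctly
and that the fitted parameter sets are consistent with data of the
stated shape and scale; they cannot show that the model fits the actual
published measurements.

## Problem sizes

Analyses run at sizes chosen to resolve each effect cleanly on a single
CPU: early-response scans use 9–20 point log grids in `k6` with 180-min
simulations; late-response windows follow the stated 10,020–10,980-min
readout after simulation to 11,000 min; the oscillation period uses a
10,000-min run discarding the first 2,000; the heterodimer-knockout
control integrates to 2e5 AU (the original used 5e5; dampening at high
MdmX is ~80%, far above resolution); bifurcation branches use 20–26
points over `k1` in [0.005, 2.4] — the printed upper scan limit of 10 is
outside the tractable (and plotted) region, as the simple model has no
tetramer degradation and its steady state grows astronomically there;
survey demonstrations use 150 stage-1 and 8-evaluation stage-2 budgets
with 3 trials per center, versus the cluster-scale hundreds-to-thousands
of trials originally used, so only the direction of the success-rate
asymmetry (OSC2-derived centers succeed more easily) is asserted, never
counts.

## Known limitations

* The total promoter concentration and the original initial-condition
  table are not published. The oscillation period and all sign/threshold
  behaviors above are robust to the promoter total over 0.05–2, but the
  early-response *percentage* changes are not (the low-Mdm2 amplification
  ranges from −65% to +409% as the promoter total goes 2 → 0.5). With
  the documented default of 1.0 the low-Mdm2 amplification reaches ~26%,
  close to but short of the reported >30%.
* With the printed OSC1P1-derived constants the asymptotic total-p53
  period is 283 min (4.7 h), not the ~6 h of the published average
  pattern; the original fit aligned series by cross-correlation with a
  time shift and did not claim exact period reproduction, and the
  printed constants carry only four significant digits.
* The delay variant is simulation-only; no DDE bifurcation analysis.
* No stochastic (SSA) simulation, no ternary complexes, no explicit
  ubiquitination intermediates — all outside the network definition.

## Reproducing the analyses

The numbered scripts under `analysis/` are thin drivers over the exported
functions and `run_recipe()`; each prints what it found and writes its
tables under `results/`. `scripts/acceptance.R` recomputes the six
headline quantities from scratch (see the README).
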
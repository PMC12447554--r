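---
title: "Modelling four-way DNA strand exchange with bulged toeholds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling four-way DNA strand exchange with bulged toeholds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fourwaykinetics)
```

## The system

Four-way (Holliday-junction) strand exchange swaps strands between two
DNA duplexes: toeholds on an *input* duplex hybridize with toeholds on a
fluorophore/quencher-labelled *probe* duplex, the resulting four-way
junction migrates in a random walk, and complete displacement separates
the fluorophore from its quencher. Each migration step requires two
base pairs to open simultaneously, which makes four-way branch
migration orders of magnitude slower than the three-way reaction.
Engineering an unpaired base (a *bulge*) next to each toehold opens an
alternative pathway in which a single base pair opens at a time — a
*half-migration step* — which accelerates migration by about an order
of magnitude. This package provides the quantitative machinery around
that design: a kinetic model with global fitting, model-free completion
statistics, a lattice model of bulge diffusion, and a synthetic-data
generator so the whole pipeline is testable without instrument data.

## The two-step kinetic model

Five species are tracked: free input duplex, free probe duplex, the
toehold-bound four-stranded intermediate `t_only`, the fluorescent
product `F`, and the released quenched complex `Q`:

$$
\begin{aligned}
\frac{d[\mathrm{input}]}{dt} &= k_\mathrm{off}[t_\mathrm{only}] - k_\mathrm{on}[\mathrm{input}][\mathrm{probe}]
 = \frac{d[\mathrm{probe}]}{dt}\\
\frac{d[t_\mathrm{only}]}{dt} &= k_\mathrm{on}[\mathrm{input}][\mathrm{probe}] - (k_\mathrm{off}+k_\mathrm{bm})[t_\mathrm{only}]\\
\frac{d[F]}{dt} &= k_\mathrm{bm}[t_\mathrm{only}] = \frac{d[Q]}{dt}
\end{aligned}
$$

Binding through the toeholds is reversible
($k_\mathrm{on}$, M⁻¹s⁻¹; $k_\mathrm{off}$, s⁻¹); branch migration
plus resolution is approximated as a single irreversible step
($k_\mathrm{bm}$, s⁻¹). Two conservation laws follow
(probe + t_only + F and input − probe are constant) and $Q(t) = F(t)$
when both start at zero; the test suite checks both to 10⁻⁶ relative
on every simulated trace. The reported signal is $F(t)$ over the
limiting reagent's total, matching normalized fluorescence.

Numerics: `simulate_deterministic()` integrates the system with
`deSolve::lsoda` and an analytic Jacobian compiled in C, at relative
tolerance 10⁻⁸ and absolute tolerance 10⁻¹⁵ M. A stiff-capable method
is required because the fitted rate constants span five decades
(1.9×10⁻² to 1.1×10² s⁻¹). Internally all concentrations are molar;
files use nanomolar, the experimental convention. As an
integrator-independent oracle, `analytic_excess_input()` solves the
pseudo-first-order limit (input in large excess) in closed form from
the eigenvalues of the linear two-state system, with the repeated-root
limit handled explicitly; ODE and oracle agree to better than 10⁻³ on
the 1000 nM / 5 nM panel condition.

## Global fitting

All traces of a panel (one design, 5 nM probe, six input concentrations
20–1000 nM) are fitted simultaneously with a single parameter pair
$(k_\mathrm{off}, k_\mathrm{bm})$, pooled unweighted least squares, and
$k_\mathrm{on}$ fixed at the maximum hybridization rate 10⁷ M⁻¹s⁻¹.
Design choices:

* **Log-scale parameters.** Positivity plus a five-decade plausible
  range make $\log_{10}$ the natural fitting scale; box bounds are
  10⁻⁸–10⁸ s⁻¹.
* **Multi-start.** A deterministic log-uniform grid over
  [10⁻⁴, 10⁴] s⁻¹ (default 16 starts) with seeded jitter, refined by
  Levenberg–Marquardt (`minpack.lm::nls.lm`); ties break by lower
  objective, then lower $k_\mathrm{off}$. Weakly identified panels (the
  two-bulge design, where only the passage probability
  $k_\mathrm{bm}/(k_\mathrm{off}+k_\mathrm{bm})$ is well constrained)
  have genuine local minima, which is what the multi-start absorbs.
* **Fitting-path tolerances.** Residuals during optimization are
  integrated at rtol 10⁻⁶ / atol 10⁻¹³ — far below the 10⁻² measurement
  noise but much faster than the reporting tolerances; final fitted
  curves and objectives are recomputed at the strict tolerances.
  Parameter sets where the integrator fails (visited by early multistart
  iterations) contribute large finite penalty residuals instead of
  errors, so the optimizer retreats gracefully.
* **Confidence intervals.** The measurement-error model is unknown
  beyond "small and roughly homoscedastic", and the two free rates are
  strongly correlated, so CIs come from a residual bootstrap: pooled
  residuals are resampled onto the fitted curves and each replicate is
  refitted from the original optimum (default 500 replicates,
  percentile 2.5/97.5, widened if needed to bracket the point
  estimate). On noiseless data the intervals collapse to the estimate.

`kon_sensitivity()` refits the panel for each fixed $k_\mathrm{on}$
(default 10⁶, 10⁷, 10⁸ M⁻¹s⁻¹) and reports the maximum relative spread
of $\hat k_\mathrm{bm}$. One structural caveat the scan exposes: a
panel whose implied second-order rate
$k_\mathrm{on}k_\mathrm{bm}/(k_\mathrm{off}+k_\mathrm{bm})$ exceeds an
assumed $k_\mathrm{on}$ cannot be fitted under that assumption at all —
the low-concentration traces are then faster than any binding-limited
model, $\hat k_\mathrm{bm}$ diverges, and the scan flags the regime
instead of returning a small deviation. The single-bulge bulge-present
parameter set (implied second-order rate ≈ 8×10⁶ M⁻¹s⁻¹) hits exactly
this wall at $k_\mathrm{on} = 10^6$, while between 10⁷ and 10⁸ its
$\hat k_\mathrm{bm}$ moves by only a few percent; the bulge-absent set
(≈ 2×10⁵ M⁻¹s⁻¹) is insensitive across the whole range.

## Model-free completion metrics

`time_to_fraction()` reports the time to 90% completion referenced to
the trace's own plateau, estimated as the mean of the final 5% of
samples, with the crossing located by linear interpolation. Referencing
the plateau (not absolute 1.0) keeps the statistic defined for
incomplete or slowly tailing reactions; traces that never cross return
a flagged `NA` rather than an error so partial condition grids still
tabulate. `enhancement_table()` pairs panels without ($T_0$) and with
($T_b$) bulges by toehold length and concentration and reports
$T_0/T_b$. In the saturated regime this ratio converges to the ratio
of branch-migration rates; at lower concentrations it reflects the
per-binding passage probabilities, so with the fitted parameter sets
(where bulges also raise toehold instability in the two-bulge design
but lower it in the single-bulge fit) the trend with concentration can
go either way — the package asserts the limits, not a universal
monotone trend.

## The bulge-diffusion lattice walk

The walk is a deliberately coarse continuous-time Markov analogue of
the molecular picture, *not* a nucleotide-level simulation: rates are
free parameters with no claimed calibration to the fitted
$k_\mathrm{bm}$. The junction coordinate $j$ runs over $0..N$ migration
steps; each bulge has a displacement-domain coordinate $x \in 0..M$
(0 = at the junction; default $M$ = 20 for one bulge, 21 for two,
the rightmost point representing the bulge beyond the final domain
position). Rules, in `enumerate_moves()`:

* With a bulge at $x = 0$ the junction migrates through half-steps at
  `rate_half_step`: full state → intermediate (flagged `half_step`) →
  adjacent full state, two firings per migration step, the bulge
  returning to 0 on completion. The intermediate can also revert, so
  migration stays unbiased.
* With no bulge at the core the junction takes full steps at
  `rate_migration_nobulge`.
* Bulges hop $x \to x \pm 1$ at `rate_bulge_hop`, suspended while a
  half-step is in flight, with exclusion between two bulges. An
  optional per-position energy table $E(x)$ (kT) biases hops by the
  symmetric rule $r \propto e^{-(E_y - E_x)/2}$, which satisfies
  detailed balance with stationary weights $e^{-E}$; the default is
  unbiased, since the functional form behind the experimentally
  observed two-welled profile is not known. The two-bulge merged
  intermediate is represented as adjacent bulges with the half-step
  flag set.
* $j = N$ (complete displacement) is absorbing when `absorb_at_end`;
  there is no dissociation channel, because toehold unbinding already
  lives in the ODE model's $k_\mathrm{off}$.

Three estimators sit on top: `stationary_exact()` solves global balance
for the frozen-junction chain and applies the free-energy transform
$F(x)/kT = -\ln(P(x)/P(1))$ (pinned to 0 at $x = 1$; zero-occupancy
positions get an infinite flag); `occupancy_profile()` is the
dwell-weighted histogram of a `gillespie_run()` trajectory; and
`mean_first_passage()` solves the linear first-passage system exactly,
reporting 1/MFPT as an effective displacement rate. Cross-checks in the
test suite: hand-built transition tables, the birth–death MFPT formula
$\sum_{k<N}(k+1)/r$ (asymptotically $N^2/2r$), two-state detailed
balance, and agreement between sampled and exact solutions within three
standard errors. A characteristic prediction, mirrored from the
molecular observations: increasing bulge mobility *slows* displacement
whenever the assisted pathway is faster than the plain one, because
diffusion removes the bulge from the junction core.

One corner case is resolved by convention: a state with zero total
outgoing rate that is not the absorbing end *stalls* the trajectory
(it dwells until `t_max` and the result is flagged) rather than raising
an error, so degenerate all-zero-rate configurations still produce
well-defined runs.

`check_sequence_constraint()` encodes the design rule that a single
bulge forces the branch-migration domain to poly-A or poly-T (base $n$
must pair with base $n+1'$; poly-G is unsynthesizable), while two
bulges relax it to alternating GT/TG or CA/AC repeats.

## The synthetic-data generator

`generate_series()` emulates the fluorescence experiment: 5 nM probe,
inputs {20, 50, 100, 200, 500, 1000} nM, two replicates, deterministic
kinetics from a chosen truth plus additive iid Gaussian noise on the
normalized signal (default sd 0.01, matching the small replicate spread
of such plate-reader data), clipped below zero. An optional
per-replicate lognormal multiplier on the probe concentration (mean 1,
chosen CV, default off) emulates pipetting/truncated-strand errors; the
*recorded* probe concentration stays nominal, as it would for an
experimenter. Run durations default to 6 pseudo-first-order e-foldings
of the slowest trace, so every default trace reaches ≥ 95% completion
and the 90%-completion statistic is always defined; the sampling
interval defaults to 1/300 of the duration. Neither the instrument's
true sampling interval nor run length is published, so these are
declared package defaults, not inferred quantities.

What the generator does *not* emulate — photobleaching, baseline drift,
the blocker-strand leak reactions, heteroscedastic noise at the plateau
— bounds what passing tests mean: they validate the estimators against
the stated statistical model, not against every artefact of real
fluorimeter data.

`rate_parameter_presets()` carries the four fitted parameter sets
(single/two bulges × present/absent, all with
$k_\mathrm{on} = 10^7$ M⁻¹s⁻¹) used as generator truths throughout the
tests and the analysis scripts.

## Problem sizes and verification budget

The test suite regenerates everything it checks. The heavier
computations and their sizes, chosen to keep a full run in tens of
minutes on one core: parameter-recovery fits use noiseless panels at
the default 301 samples/trace; the bootstrap-coverage study uses 100
independent noisy panels of 41 samples/trace × 6 concentrations × 2
replicates with 500 bootstrap refits each; Gillespie-vs-exact occupancy
uses 40 independent runs of 400 time units on a 7-position biased
chain; the MFPT cross-check uses 10⁴ sampled passages on a
41-state chain. The `analysis/` scripts run the same machinery at
presentation sizes and write their tables under `results/`.

## Known limitations

* The ODE model treats branch migration as one irreversible step; it
  cannot resolve multi-step migration effects (e.g. the anomalous
  slow tail of fast two-bulge reactions) that a multi-state model
  would capture.
* The two-bulge-present condition is weakly identified by design:
  rates far above the binding scale leave only their ratio well
  constrained, and the bootstrap CIs honestly span that ridge.
* The lattice walk is qualitative; mapping its rates onto measured
  rate constants would require nucleotide-level input the package
  deliberately does not model.
* The bulge-position energy table defaults to flat; the two preferred
  locations seen in molecular simulation can be *imposed* via the
  table but are not predicted.
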
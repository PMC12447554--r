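# fourwaykinetics

Quantitative analysis of four-way DNA strand-exchange kinetics with
bulged toeholds, for DNA-nanotechnology researchers characterizing
toehold-mediated strand displacement.

Four-way strand exchange proceeds through a Holliday junction whose
branch migration requires two base pairs to open per step, making it
orders of magnitude slower than three-way displacement. Placing an
unpaired base (bulge) next to each toehold enables half-migration steps
that open one base pair at a time and accelerate the reaction. This
package implements the analysis machinery around that design:

* **Kinetic model** — the two-step model with rate constants k_on
  (toehold binding, M⁻¹s⁻¹), k_off (unbinding, s⁻¹) and k_bm (branch
  migration/resolution, s⁻¹) over five species (input, probe,
  toehold-bound intermediate, fluorescent product, quenched complex):

      d[input]/dt  = k_off·[t_only] − k_on·[input]·[probe] = d[probe]/dt
      d[t_only]/dt = k_on·[input]·[probe] − (k_off + k_bm)·[t_only]
      d[F]/dt      = k_bm·[t_only] = d[Q]/dt

  integrated stiffly (compiled RHS + analytic Jacobian) with a
  closed-form pseudo-first-order oracle for verification.
* **Global fitting** — one (k_off, k_bm) pair per concentration panel
  with k_on fixed at 10⁷ M⁻¹s⁻¹, log-scale multi-start
  Levenberg–Marquardt, residual-bootstrap 95% CIs, and a fixed-k_on
  sensitivity scan.
* **Model-free metrics** — plateau-referenced 90%-completion times and
  the reaction enhancement factor T0/Tb across toehold lengths and
  concentrations.
* **Bulge-diffusion lattice walk** — a continuous-time Markov model of
  junction migration with 0–2 diffusing bulges: exact stationary
  occupancy and free-energy profiles F(x)/kT = −ln(P(x)/P(1)),
  Gillespie sampling, exact mean first-passage times, and the
  poly-A/T / poly-GT/CA sequence-constraint checker.
* **Synthetic data** — panels emulating the fluorescence experiments
  (5 nM probe, 20–1000 nM input, Gaussian signal noise, optional
  probe-pipetting error) so everything is testable end to end.

## Worked example

Generate a noisy synthetic panel from the fitted single-bulge rates,
refit it, and bootstrap the uncertainty:

```r
library(fourwaykinetics)

truth <- rate_parameter_presets()[["1bulge_present"]]  # k_off 0.14, k_bm 0.56
panel <- generate_series(truth, experiment_design(replicates = 2),
                         noise_model(signal_sd = 0.01, seed = 1))
fit <- global_fit(panel, fixed_kon = 1e7, n_starts = 16, seed = 1)
fit <- bootstrap_ci(panel, fit, n_boot = 500, seed = 2)
fit
#> <fw_fit> k_off = 0.1418 s^-1, k_bm = 0.5614 s^-1 (k_on fixed at 1e+07 M^-1 s^-1)
#>   SSR = 0.3884 over 3612 points; 16 starts; converged: TRUE
#>   95% CI k_off [0.1382, 0.1451], k_bm [0.5589, 0.5643] (500 bootstrap replicates)
```

The recovered unbinding rate (0.1418 s⁻¹) and branch-migration rate
(0.5614 s⁻¹) bracket the generating truth within tight intervals: with
six concentrations up to saturation the panel identifies both rates.
The same machinery quantifies the acceleration mechanism model-free —
`enhancement_table()` on matched bulge-absent/bulge-present panels
gives T0/Tb ≈ 31–39 across 20–1000 nM for the single-bulge design —
and mechanistically: `mean_first_passage()` on the lattice walk shows
displacement slowing as the bulge's hop rate grows, because diffusion
strands the bulge away from the junction core.

The `analysis/` directory holds the full workflow as numbered scripts
(simulate panels → global fits → k_on sensitivity → enhancement →
bulge walk), each writing its tables under `results/`.

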
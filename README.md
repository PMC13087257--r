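# deerpop

Quantifying co-existing protein conformational states from pulse dipolar
EPR (DEER/PELDOR) data.

Dimeric K2P potassium channels carry an extracellular cap domain that packs
either against its own subunit (non-swapped, NS) or against the partner
subunit (swapped, S). With two spin labels on a single subunit, the
intra-subunit label distance is state-diagnostic (NS ≈ 3.3 nm, S ≈ 5.0 nm),
so a DEER distance distribution measures both states at once and the area
under each component is the state's population. deerpop is for EPR
spectroscopists and structural biologists who want that analysis as a
reproducible, testable pipeline rather than a GUI workflow.

The core is a global regularised inversion plus a parametric population
model:

- forward model `V(t) = V0 [(1 − λ) + λ F(t)] B(t)` with the powder-averaged
  dipolar kernel `K(t, r)` (`ν = D/r³`, `D = 52.04 MHz nm³`), form factor
  `F(t) = ∫ K(t, r) P(r) dr` and stretched-exponential background
  `B(t) = exp(−k t^(d/3))`;
- `deer_fit()`: one distribution `P(r) ≥ 0` shared by up to six traces,
  recovered by non-negative Tikhonov regularisation
  (`min Σᵢ ‖Vᵢ − model‖²/σᵢ² + α²‖L₂P‖²`) with per-trace nuisance
  parameters `(λᵢ, kᵢ, V0ᵢ)`, the regularisation parameter chosen by
  (strong robust) generalised cross-validation;
- `fit_two_gaussians()` + `populations()`: bimodal Gaussian fit of `P(r)`
  whose component weights are the NS/S populations, with 2σ (95%)
  confidence intervals from the fit covariance;
- robustness: leave-one-trace-out (`jackknife_traces()`) and distance-axis
  sensitivity (`axis_sensitivity()`) analyses, and trace-length reliability
  ranges (`reliability_ranges()`).

Around the core: seeded synthetic-data generators for every input
(`make_ground_truth()`, `simulate_trace_set()`, packaged study fixtures
`"exp19C"`/`"exp40C"`, `helix_dimer_fixture()`, `simulate_energy_series()`),
accessible-volume R1 rotamer modelling for in-silico distance prediction
(`attach_rotamers()`, `predict_pair()`), an exponential-averaging
interaction free-energy estimator with block-averaged errors
(`block_free_energy()`), a radial-distribution utility, and Nernst/fold
-activation helpers. See the vignette in `vignettes/` for the methods.

## Worked example

Simulate the standard four-trace set from the 19 °C fixture (ground truth:
NS 3.3 nm/SD 0.5 nm at 43%, S 5.0 nm/SD 0.3 nm at 57%; evolution windows
2/4/6/7.5 µs, modulation depth 0.3, noise 0.005), invert globally and
quantify:

```r
library(deerpop)

ts  <- simulate_fixture("exp19C", seed = 1)
fit <- deer_fit(ts)                          # global inversion, 9 nm axis
fit
#> Global regularised DEER fit: 4 trace(s), alpha = 0.316 (srgcv)
#>   P(r): mean 4.43 nm, sd 1.24 nm on [1.50, 9.00] nm
#>   label t_max   n lambda      k d    V0 sigma
#>    t2us  2.00 126  0.312 0.0445 3 0.998 0.005
#>    t4us  4.00 251  0.311 0.0464 3 0.998 0.005
#>    t6us  6.00 376  0.315 0.0459 3 1.002 0.005
#>  t7.5us  7.49 469  0.315 0.0468 3 1.004 0.005

tg <- fit_two_gaussians(fit$distribution, width_cap = 1.0,
                        cap_semantics = "sd")
tg
#> Two-Gaussian fit: mu = 3.31 / 5.01 nm, fwhm = 1.25 / 0.71 nm, p1 = 0.440 (se 0.009)
populations(tg)
#> State populations (95% CI): NS 44 +/- 2 %, S 56 +/- 2 %
```

The fit prints each trace's recovered modulation depth, background rate and
scale (all close to the generating values 0.3 / 0.05 / 1), the selected
regularisation parameter and criterion, and the moments of the recovered
distribution. The two-Gaussian fit resolves the components at 3.31 and
5.01 nm; their weights are the populations — here NS 44%, S 56% against the
fixture's 43/57 ground truth, with a 2σ interval of about ±2 points from
the fit covariance alone (axis sensitivity adds the `p1/10` heuristic; see
`axis_sensitivity()`). Averaged over 20 replicate seeds the pipeline
recovers the 19 °C and 40 °C S populations without material bias; that
average is what `scripts/acceptance.R` reports.

The same machinery runs end to end from a config:

```r
report <- run_pipeline(list(fixture = "exp19C", seed = 1))
```

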
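---
title: "Quantifying co-existing conformational states from pulse dipolar EPR data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying co-existing conformational states from pulse dipolar EPR data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deerpop)
```

## The problem

Dimeric two-pore-domain (K2P) potassium channels carry an extracellular cap
domain that can pack in two ways: *non-swapped* (NS), with the outer
transmembrane helix against its own subunit, and *swapped* (S), against the
partner subunit.  When exactly one subunit of the dimer carries two nitroxide
spin labels, the intra-subunit label distance differs strongly between the
states (short, near 3.3 nm, for NS; long, near 5.0 nm, for S), so pulse
dipolar EPR (DEER/PELDOR) sees the whole conformational ensemble at once and
the *area* under each component of the distance distribution measures the
population of the corresponding state.  deerpop implements that pipeline
end to end — forward physics, global regularised inversion, bimodal-Gaussian
quantification with uncertainty, and the companion analyses (in-silico label
modelling, MD interaction-energy post-processing, electrophysiology
arithmetic) — together with seeded generators for every input, so each stage
is testable without experimental raw data.

## Forward model

A 4-pulse DEER trace is modelled as

$$V(t) = V_0\,\bigl[(1-\lambda) + \lambda F(t)\bigr]\,B(t), \qquad
F(t) = \int K(t, r)\,P(r)\,\mathrm{d}r,$$

with modulation depth $\lambda$, stretched-exponential background
$B(t) = \exp(-k\,t^{d/3})$, and the powder-averaged dipolar kernel

$$K(t, r) = \int_0^1 \cos\!\bigl[2\pi\,\nu(r)\,(1 - 3u^2)\,t\bigr]\,
\mathrm{d}u, \qquad \nu(r) = D/r^3,$$

with $D = 52.04$ MHz nm$^3$ for a free-electron pair (exchange coupling is
neglected, safe beyond about 1.5 nm).  The kernel is evaluated through the
Fresnel-integral closed form by default; a Gauss–Legendre quadrature route
(5001 nodes) is kept as an independent cross-check and the two agree to
better than $10^{-6}$ over the working domain.  Times are microseconds and
distances nanometres throughout; unit conversion happens only at I/O
boundaries (`read_trace()` auto-detects ns time axes).

## Inversion

`deer_fit()` recovers one distance distribution shared by 1–6 traces of
different lengths by solving

$$\min_{P \ge 0,\ \theta}\ \sum_i \frac{\lVert V_i -
\mathrm{model}(P, \theta_i)\rVert^2}{\sigma_i^2}
\;+\; \alpha^2 \lVert L_2 P \rVert^2,$$

where $L_2$ is the second-difference operator, $\sigma_i$ is each trace's
noise level (estimated from the high-frequency residual of a Savitzky–Golay
fit when not supplied), and $\theta_i = (\lambda_i, k_i, V_{0,i})$ are
per-trace nuisance parameters.  Numerically the problem separates: for fixed
nuisance parameters the inner problem is a convex non-negative least-squares
solve (a compiled Lawson–Hanson active-set routine on the normal equations,
with a soft unit-integral row so $P$ stays a density), and the nuisance
parameters are refined per trace by bounded optimisation with the scale
profiled out.  The two steps alternate to a relative objective tolerance of
$10^{-4}$ (default, at most 40 rounds; beyond that point the alternation
crawls along a flat depth-width valley with no visible change in the
estimates); non-convergence is flagged in the result rather than silently
ignored.

Trace weights use relative noise levels ($\bar\sigma/\sigma_i$), so the
scale of the problem — and hence the meaning of $\alpha$ — does not depend
on the absolute noise level.  Noise estimates are floored at $10^{-4}$ of
the trace scale to keep clean synthetic traces well conditioned.

**Choosing $\alpha$.**  `select_alpha()` scans a log-spaced grid (25 points,
$10^{-4}$–$10^2$ by default) and minimises either generalised
cross-validation, $\mathrm{GCV}(\alpha) = m\lVert r\rVert^2 / (m -
\operatorname{tr} H)^2$, or its strong-robust variant (the default), which
multiplies GCV by the Lukas penalty $\gamma + (1-\gamma)\,
\operatorname{tr}(A_\alpha^{\dagger\top} A_\alpha^\dagger)/m$ with
$\gamma = 0.8$, made dimensionless by normalising with the mean squared row
norm of the design so the penalty is invariant to the data scale.  The
influence trace is computed on the passive (non-negative-active) set.
Before the scan, the nuisance parameters are warmed by a few alternation
rounds at a deliberately *small* $\alpha$ (0.01): with minimal smoothing
the distribution can absorb any shape, so the modulation depths converge
without the upward bias that an over-smoothed $P$ induces through the
depth–width degeneracy (warming at a large $\alpha$ measurably biases
$\lambda$ up and drags the short component's mean down).  The scan is
repeated once after the alternation converges.  Ties break toward larger
$\alpha$ (stronger smoothing).  The criterion actually used is recorded in
every fit.

**Reliability.**  The distance ranges in which the recovered shape, width
and mean can be trusted grow with the cube root of the evolution window:
$r_X = c_X\,(t_{\max}/2\,\mu s)^{1/3}$ with $c = 5.0/6.0/7.0$ nm.  The
constants are configurable; they approximate the colour-bar convention of
established DEER analysis software, whose exact values are not published.

**Robustness checks.**  `jackknife_traces()` refits all leave-one-trace-out
subsets — holding $\alpha$ at the full-set selection so the check isolates
the influence of the data from that of the processing — and reports the
maximum pairwise $L_1$ distance between the recovered distributions; `axis_sensitivity()` repeats the whole analysis on
8, 9 and 10 nm distance axes and combines the weight spread with the fit
covariance as $\max(\mathrm{ci}_{95},\ p_1/10)$ — the empirical rule that
processing-parameter variation contributes about a tenth of the weight.

## Quantification

`fit_two_gaussians()` fits a two-component Gaussian mixture to the recovered
$P(r)$ by multi-start least squares (eight seeded starts around the two
largest local maxima).  Because components are normalised, their weights
*are* the peak areas, i.e. the state populations; `populations()` reports
them with $2\sigma$ (95%) intervals from the fit covariance, and
`assign_states()` maps the short component to NS and the long to S, warning
when a mean strays more than 0.7 nm from the 3.3/5.0 nm references.

**Width cap.**  Component widths are capped at 1.0 nm, by default on the
FWHM scale — the convention of the published analysis tooling.  The cap's
scale matters: the packaged ground-truth fixtures generate the NS component
with SD 0.5 nm (FWHM 1.18 nm), and a *binding* FWHM cap makes the weight
estimator inconsistent by about +3 points on the S population (measured by
fitting the capped model to the exact mixture).  The packaged fixtures
therefore carry `cap_semantics: "sd"` (cap 1.0 nm SD, which never binds for
the known generating widths), and the general default remains `"fwhm"` for
data whose true widths are unknown.  When the cap binds, the reported
populations inherit that model bias; this is a property of the capped-model
convention, not of the inversion.

## Synthetic data: what it emulates, and what it does not

The generators produce every input the pipeline consumes:

* `make_ground_truth()` — Gaussian-mixture distance distributions; the
  packaged fixtures `"exp19C"`/`"exp40C"` fix the component means/SDs at the
  in-silico values (3.3/0.5 and 5.0/0.3 nm) and the weights at the fitted
  populations (S = 57% and 66%).
* `simulate_trace_set()` — up to six traces of different evolution windows
  (the fixture uses 2/4/6/7.5 µs at 16 ns steps, the longest window being
  the transverse-dephasing limit), modulation depth 0.3, homogeneous 3D
  background $k = 0.05$/µs, and white Gaussian noise of 0.005 of the trace
  scale on the real channel.  Modulation depth, background dimensionality
  and noise level are *simulation conventions* — the experimental values are
  not published — chosen to reproduce traces with strong visible
  oscillations; they are recorded in the fixture file and reported with any
  result.
* `helix_dimer_fixture()` — idealized poly-alanine helix pairs
  ($\phi=-57^\circ$, $\psi=-47^\circ$) for download-free spin-labelling
  tests.
* `simulate_energy_series()` — stationary AR(1) series with prescribed
  mean, SD and correlation time, standing in for MD interaction-energy
  output.

Passing the round-trip tests therefore shows the *estimator chain* is
unbiased and correctly calibrated under these conditions; it does not probe
experimental artefacts the generators omit (orientation selection, nuclear
modulation, phase drift, non-Gaussian noise, background model error), which
in real data are handled by end truncation (`truncate_end()`), the phase
rotation in `read_trace()`, and the robustness analyses.

## Spin labelling

`attach_rotamers()` performs an accessible-volume search of the R1
(nitroxide) side chain built from an internal-coordinate template with five
free dihedrals sampled uniformly; a conformer is accepted if its heavy atoms
make at most 5 contacts closer than 2.5 Å to protein heavy atoms ("loose";
"tight" is 0 contacts at 3.4 Å), stopping at 200 accepted conformers or a
30000-candidate budget ("thorough").  These thresholds mirror the published
semantics of the accessible-volume labelling tool whose mode names the
workflow uses; hydrogens are ignored, and disulfide-bonded cysteines
(SG–SG < 2.5 Å) are refused as sites.  The label position is the N–O bond
midpoint, and `pair_distance_distribution()` histograms all ensemble-pair
distances (default bin 0.05 nm — the tool's bin width is unpublished).

## MD energetics

`exp_avg_free_energy()` implements the exponential-average estimator
$\Delta G = -kT\ln\langle e^{-U/kT}\rangle$ (ideal-gas reference state,
$k_B = 0.0019872041$ kcal/(mol K)), evaluated by log-sum-exp so it cannot
overflow.  `block_free_energy()` applies the estimator per contiguous block
(default 5 blocks — the source block count is unpublished — over the last
half of the series) and reports the block mean and SD; applying the
estimator *per block* rather than to block-averaged energies is a
documented choice where the procedure was ambiguous.  `delta_delta_g()`
forms temperature differences with quadrature errors, refusing mismatched
state labels.  `pv_term()` converts 1 bar × volume to kJ/mol
(0.0602214 kJ/mol per bar nm³).  The trajectory-dependent published energy
differences are not reproduction targets; only the estimator's correctness
is tested.

## Numerical choices and degenerate inputs

* Distance axis: 1.5 nm to 9 nm (8/9/10 in sensitivity runs) at 0.05 nm —
  the lower bound is this package's convention.
* Inner NNLS tolerance scales with the normal-matrix norm; an empty passive
  set or singular influence matrix raises a diagnostic error.
* Traces with fitted modulation depth below 0.02 are flagged
  `"low modulation depth"` rather than rejected.
* A unimodal input to the two-Gaussian fit collapses one weight; results
  with a weight ≥ 0.99 carry the `"effectively unimodal"` flag.
* All generators and fits are pure functions of (parameters, seed); the
  pipeline report embeds its config so any run can be regenerated.

## Problem sizes used in the shipped checks

The population round-trip studies use 20 replicate seeds per condition with
the full four-trace fixture (about 1200 data points jointly inverted on a
151-point axis per replicate), which resolves the 57 → 66% shift cleanly;
smaller unit tests use shorter traces and coarser axes, sizes chosen so the
whole suite exercises every code path at desk scale.

## Known limitations

Orientation-selective DEER, multi-spin effects, exchange coupling,
Bayesian/neural inversion and mixtures with more than two components are out
of scope.  The srGCV penalty follows Lukas's strong-robust form as
implemented here; other software may use a slightly different expression, so
the criterion used is always recorded in the fit object.  Population
uncertainties are reported both as fit-covariance intervals and as the
axis-spread heuristic, since published uncertainty bands mix the two.
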
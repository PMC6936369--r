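---
title: "Connectome-based simulation of resting-state dynamics: models, surrogates and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Connectome-based simulation of resting-state dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(connsim)
```

## The scientific question

A structural connectome (SC) — the matrix of anatomical projection
strengths between brain regions — constrains, but does not equal, the
functional connectome (FC) measured as pairwise correlations of
resting-state BOLD signals.  Connectome-based modelling makes the link
causal: place an identical neural-mass model at every region, couple the
regions through the SC, simulate BOLD, and ask how well the simulated FC
predicts the empirically measured FC.  The Pearson correlation between the
(strictly upper-triangular) simulated and empirical FC is the *predictive
power* (PP) of the structural connectome under the model.

With that machinery, structural hypotheses become experiments on the SC
matrix itself.  This package implements the full loop: connectome
containers and I/O, the surrogate constructions that remove or restore
specific structural features (directionality, weak long-range connections,
individual weights, hemispheric asymmetry), the forward model from SC to
BOLD, the functional metrics, the statistical battery, and a synthetic
cohort generator that stands in for a real tracer + diffusion-MRI + fMRI
mouse data set so that the entire analysis is reproducible from a seed.

## The forward model

### Neural dynamics

Each region is a reduced Wong–Wang population with one slow gating
variable \(S_i \in [0, 1]\):

\[
\dot S_i = -\frac{S_i}{\tau_s} + (1 - S_i)\,\gamma\,H(x_i), \qquad
x_i = w J_N S_i + G J_N \sum_j C_{ji} S_j + I_0,
\]

with the current-to-rate transfer
\(H(x) = (a x - b) / (1 - e^{-d (a x - b)})\) (the removable singularity at
\(a x = b\) is evaluated analytically).  `C` is the max-normalized weight
matrix with the source-to-target convention: `C[j, i]` couples region `j`
into region `i`, so directionality matters dynamically.  Parameters live in
`dmf_params()` with the canonical values
\(a = 270\,\mathrm{nA^{-1}}, b = 108\,\mathrm{Hz}, d = 0.154\,\mathrm{s},
\gamma = 0.641\,\mathrm{s^{-1}}, \tau_s = 100\,\mathrm{ms},
J_N = 0.2609\,\mathrm{nA}, I_0 = 0.32\,\mathrm{nA}\).

The local recurrence `w` selects the node's regime.  At the default
\(w = 1.0\) the isolated node is bistable — a low and a high stable firing
state separated by an unstable root, verifiable with
`find_fixed_points()`:

```{r}
find_fixed_points(dmf_params())
```

Integration is Euler–Maruyama (C++ core) at `dt = 0.1` ms by default.
Noise deserves three remarks.  First, the diffusion uses the
seconds-convention scaling (a Wiener kick of SD
\(\sigma\sqrt{\Delta t\,[\mathrm{s}]}\)); a millisecond-based reading of
the same \(\sigma\) would inflate the noise a thousandfold.  Second, noise
is generated on a fixed 1-ms bucket grid, so halving `dt` refines the
deterministic part of the flow while leaving the driving noise path
untouched — a fixed-seed run converges as `dt` shrinks instead of jumping
to a different realization.  Third, each region owns a counter-based
stream hashed from `(seed, region index)`: simulations are bit-reproducible
and a region's noise does not depend on how many other regions exist, so an
uncoupled network equals the corresponding set of single-region runs
exactly.

### Hemodynamics

Gating activity drives the classical Balloon–Windkessel cascade
(vasodilatory signal, inflow, venous volume, deoxyhemoglobin;
`hemodynamic_params()` holds \(\kappa = 0.65, \gamma_h = 0.41,
\tau = 0.98\,\mathrm{s}, \alpha = 0.32, \rho = 0.34, V_0 = 0.02,
k_1 = 7\rho, k_2 = 2, k_3 = 2\rho - 0.2\)), and BOLD is reported as percent
signal change sampled at the TR.  Inside `simulate_bold()` the cascade is
integrated on a 1-ms subgrid of the neural step (its time constants are
three orders of magnitude slower than the neural `dt`); the standalone
`balloon_windkessel()` uses Heun steps and matches an adaptive stiff
integrator to better than \(10^{-4}\) relative to the response peak.  At
rest (zero input) the cascade sits exactly at its fixed point and the BOLD
output is identically zero.

### The operating point

Two practical obstacles appear when this model is run on small dense
networks.  The network's low-activity state creeps upward with coupling
`G` until the whole system cascades irreversibly into the high-activity
attractor; and the FC carries structural information only near the point
where that instability develops.  Two design choices address this:

* **Homeostatic input compensation** (`fic = TRUE`): each region's mean
  network input at the low-activity reference state is subtracted, so the
  resting operating point stays pinned at the isolated node's low root for
  any `G`, while the *fluctuations* still couple through the full directed
  SC.  This is a reduced stand-in for the local feedback inhibition that
  balances excitation in cortical circuits; it changes the fixed point, not
  the connectome-dependent Jacobian.

* **Relative coupling** via `critical_coupling()`: linearizing around the
  compensated fixed point, the network loses stability at
  \(G_c = -\lambda_0 / (\kappa_c\,\mathrm{perron}(C))\) where
  \(\lambda_0\) and \(\kappa_c\) are scalar functions of the node
  parameters and \(\mathrm{perron}(C)\) is the leading eigenvalue of the
  weight matrix.  All resting-state sessions and all candidate evaluations
  run at `G = G_frac * G_c(connectome)` (default `G_frac = 0.88`), which
  makes operating points comparable across connectomes that differ in
  size, density and weight scale — the same role that scanning `G` per
  connectome and keeping the best value plays when fitting real data
  (`scan_coupling()` provides that explicit scan).

For the synthetic cohort's sessions the node runs at `session_w = 0.6`, a
monostable low-activity configuration.  Near \(G_c\) the dynamics is then
an intermittent, avalanche-like fluctuation regime whose correlations are
shaped by the connectome, and — because no high-activity attractor exists —
it is stationary for arbitrarily long sessions.  The bistable default
configuration remains the reference for single-node analysis
(`find_fixed_points()`, basin separation, noise-driven switching), but at
this network size its high state captures the whole network within seconds
once `G` approaches criticality, which would make session statistics
depend on when the escape happened rather than on the connectome.  The
choice is a property of the synthetic study design, recorded here; both
regimes are exposed through ordinary parameters.

## Surrogate connectomes

Each surrogate isolates one structural feature:

* `average_group()` — elementwise mean of max-normalized cohort members
  (the group-average connectome; individuality removed).
* `filter_by_union_mask()` — keep only connections seen by at least one
  (symmetric) reconstruction, in either direction: pure false negatives,
  directionality preserved on survivors.
* `symmetrize()` — \((W + W^\top)/2\): directionality removed, total
  weight conserved; unidirectional connections acquire a spurious
  reciprocal (a false positive) at half strength.
* `asymmetrize()` — redistribute each pair sum between the two directions
  in a directed reference's proportions; pair sums are conserved.
  Recovering directions from a symmetric matrix is ill-posed, so the rule
  is explicit and the reference ratios are the only information used.
* `hybridize()` — replace one region's full incoming + outgoing profile
  with a reference's (the hybrid connectome).  Full-profile replacement is
  the default because a reference can contribute connections the base
  missed; a restricted mode overwrites only base-supported positions.
* `mirror_left_from_right()` — rebuild the left hemisphere as the mirror
  image of the right via the homotope map, the construction forced on
  tracer atlases built from unilateral injections.

## Functional metrics

`static_fc()` (Pearson FC), `fcd()` (sliding-window FC-to-FC correlation,
boxcar windows, defaults 60 samples window / 5 step at TR = 1 s),
`fmc()` (correlations between windowed FC link series),
`predictive_power()` (upper-triangular Pearson between simulated and
empirical FC — raw correlation, no Fisher transform),
`global_signal_regress()`, `session_similarity()` (within- vs
cross-subject FC correlations), and `fc_lateralization()`.  The
lateralization index maps the Euclidean distance between homotopic FC
profiles through \(LI = 1/(1 + d)\); any strictly decreasing map preserves
the rank-based downstream results, and this one fixes \(LI = 1\) for a
perfectly mirrored FC.

## The synthetic cohort

`synth_config()` fixes the study conditions; every generator is a pure
function of (config, seed).  The ground truth (`make_ground_truth()`) is a
directed, weighted, bihemispheric connectome: distance-dependent wiring
probability (`exp(-d / 3 mm)`), log-normal weights following an exponential
distance rule (log-weights fall by 0.5 per mm — long-range connections are
systematically weak, as in tracer data), strong directional asymmetry
(log-ratio SD 1.5, 30% unidirectional pairs), boosted homotopic callosal
links, and a left hemisphere built as the mirror of the right and then
perturbed multiplicatively (SD `asymmetry_eps = 0.3`), so the brain is
lateralized by a controlled amount.

Subjects (`make_cohort()`) share that backbone with a per-pair log-normal
weight jitter (SD 1.0) plus sparse edge flips (10%): individuality lives in
connection strengths and in topology, while the backbone's direction
ratios are shared — consistent with treating strengths as the main
individual determinant.  The jitter is deliberately larger than real
cohort variability so that fingerprint effects are resolvable within
minutes of simulated recording; consequences of that exaggeration are
discussed under limitations.

`degrade_dmri()` emulates tractography: each true directed edge is dropped
with probability \(1 - e^{-\lambda \ell}\) (length-dependent false
negatives), the result is symmetrized (directionality is invisible to
diffusion MRI), and spurious symmetric edges are added on absent pairs.
The `deterministic` preset (\(\lambda = 0.10/\mathrm{mm}\), 2% false
positives) favors specificity; the `probabilistic` preset
(\(\lambda = 0.05\), 15% false positives drawn up to the full true weight
range, emulating occasional strong spurious bundles) favors sensitivity.
Degradations under a shared seed share their error pattern: pipeline
biases are systematic, not subject-specific — everyone misses the same
long tracts.

`make_sessions()` simulates repeated recordings from the true connectome
with independent noise seeds, adds measurement noise (5% of the regional
BOLD SD) and returns per-session FC.  Defaults: 40 regions, 5 subjects,
4 sessions of 300 s at TR = 1 s.

## Experiments

* `experiment_pp_ranking()` scores, per subject, the true connectome, its
  union-mask-filtered and symmetrized variants, the two degraded
  reconstructions and the cohort average of the deterministic ones,
  against the subject's sessions, and emits Welch tests
  (Bonferroni-corrected), Cohen's d and percentile-bootstrap intervals for
  the planned contrasts.
* `experiment_hybrid_scan()` corrupts one region's profile severely (90%
  of its connections dropped, survivors strongly distorted), then measures
  the change in PP from substituting each region's profile with the group
  reference.  Substitutions share the base simulation's noise seed (common
  random numbers), so ΔPP isolates the structural change and substituting
  the base into itself gives exactly zero.
* `experiment_lateralization()` hybridizes each left region from the true
  and from the mirrored group reference and relates the mirror penalty to
  the empirical FC lateralization of that region; with `asymmetry_eps = 0`
  the two references coincide bit-for-bit and the report flags itself as
  degenerate.

All three are pure functions of (config, seed); statistics tables are
re-derivable from the emitted raw PP tables with the stats module alone.

## Statistics

`welch_test()`, `t_tests()` and `pearson_r_p()` wrap the standard R
implementations; `bonferroni()` is `min(1, m p)`; `cohens_d()` uses the
classic pooled SD; `bootstrap_ci_mean_diff()` is a seeded percentile
bootstrap (5000 resamples by default, groups resampled independently) of
the standardized mean difference; `mann_whitney_u()` returns the midrank U
and its normalization \(U / (n_x n_y) \in [0, 1]\) (0.5 means
indistinguishable weight distributions), computed on the common support
when comparing connectomes via `weight_similarity_U()`.

## Problem sizes and numerical choices

The analyses that the tests and `scripts/acceptance.R` run use two scales,
chosen once as the package's study conditions: the *cohort scale* (40
regions, 5 subjects × 4 sessions of 300 s, `dt = 0.1` ms) for the
functional fingerprint, and the *analysis scale* (20 regions, 300-s
sessions, `dt = 0.5` ms) for the connectome-variant ranking, hybrid and
lateralization experiments, where many candidate connectomes must each be
simulated across ten master seeds.  Directional cohort-level claims are
judged across ten master seeds with a binomial criterion (at least 8/10),
because single stochastic runs can invert small effects.

Numerical details worth knowing: gating is clamped to \([0, 1]\) after
every step; the transfer function switches to a series expansion within
\(|d(ax - b)| < 10^{-8}\); fixed points are located by dense bracketing
plus bisection to \(10^{-14}\); weight normalization is a single scalar
rescale so zero patterns never change; tract lengths are carried as
geometric distances and are untouched by weight operations; and the
text-matrix format writes 17 significant digits so read/write round trips
are exact.

## Limitations

* The model is delay-free; tract lengths enter only descriptively
  (filtering, degradation), never as conduction delays.
* Region invariance: one parameter set for all regions; connectome
  differences are the only symmetry breaking.
* The synthetic cohort exaggerates individual variability and directional
  asymmetry relative to real mouse cohorts so that effects are resolvable
  at desk scale; passing tests demonstrate that the pipeline detects these
  structural signals when present, not that real data carries them at the
  same strength.
* The smallest-margin claims are at the resolution limit of the analysis
  scale.  The individual-vs-group-average contrast (a fraction of a PP
  point in real data too) holds in a majority of master seeds but not
  reliably in eight of ten; the same applies to the top-rank clause of the
  hybrid-rescue experiment — the corrupted region's substitution is
  positive and highly ranked in most seeds, yet substituting the group
  reference into an *intact* region also repairs directionality and false
  negatives, and that repair spread can outrank the targeted rescue — and
  to the lateralization-penalty correlation at `asymmetry_eps = 0.3`.
  Larger cohorts, longer sessions or stronger generator effects would
  sharpen all three; the tests report the honest outcome at the stated
  conditions.
* FC from the monostable near-critical regime shows weak functional
  connectivity dynamics compared to the bistable switching regime;
  `fcd()`/`fmc()` quantify whatever dynamics is present but the synthetic
  sessions are not designed to exhibit pronounced checkerboards.
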
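---
title: "Methods: simulating, measuring and modelling sprint EMG coordination"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating, measuring and modelling sprint EMG coordination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sprintkan)
```

## The scientific setting

sprintkan models a randomized crossover sprint study: a cohort of sprinters
runs 100 m under three neurostimulation conditions (sham, motor-cortex
tDCS, dorsolateral-prefrontal tDCS) while surface EMG is recorded from four
lower-limb muscles — rectus femoris (RA), biceps femoris (BF), tibialis
anterior (TA) and lateral gastrocnemius (GL) — at 1000 Hz. The sprint is
split into three phases (0–30 m acceleration, 30–60 m speed maintenance,
60–100 m speed endurance). Three analysis layers sit on top:

1. **Intermuscular coherence (IMC)** — magnitude-squared coherence between
   antagonist muscle pairs (RA–BF and TA–GL), band-averaged in the alpha
   (8–15 Hz), beta (15–30 Hz) and gamma (30–50 Hz) bands, interpreted as
   shared neural drive.
2. **A Kolmogorov–Arnold network (KAN)** mapping nine neuromuscular
   features (six band coherences plus the RA iEMG, RMS and median
   frequency) to phase velocity, trained with sparsity and entropy
   regularization, pruned, and compressed into a closed-form equation.
3. **Repeated-measures inference** — per-outcome one-way RM-ANOVA over the
   three conditions with Mauchly's sphericity test, Greenhouse–Geisser
   correction, Bonferroni post hocs and partial eta-squared.

Because no raw recordings are available, the package ships a synthetic
cohort generator whose defaults encode the study conditions, so that every
stage of the pipeline is testable end to end.

## The synthetic cohort and the common-drive model

`generate_cohort()` produces one 4-channel recording plus one phase
velocity per (participant, condition, phase) cell; the default design is
30 × 3 × 3 = 270 cells. Trial duration is phase distance divided by the
cell's mean velocity (e.g. 30 m at 11.59 m/s ≈ 2.59 s).

Coherent activity is created with a *common-drive* model. For each muscle
pair and band, a band-limited unit-variance Gaussian source $s$ is mixed
into both channels:

$$x = \kappa s + \sqrt{1-\kappa^2}\,e_x, \qquad
  y = \kappa s + \sqrt{1-\kappa^2}\,e_y,$$

with $e_x, e_y$ independent noises filtered identically to $s$. The
expected band coherence is then $\kappa^4$, so a target coherence $c$ is
achieved with $\kappa = c^{1/4}$ (`calibrate_mixing()`). Every channel
additionally carries independent broadband (20–450 Hz) noise with RMS
0.3 mV; at that level the analytic dilution of in-band coherence is below
0.01 and the calibration holds within the ±0.05 tolerance verified by the
test suite. Band-limited noise is generated by coloring white Gaussian
noise in the frequency domain with the zero-phase magnitude response of a
4th-order Butterworth band-pass — spectrally identical to
forward–backward filtering, with no edge transients.

Default per-cell coherence targets follow the study's reported band means.
Two reported gamma values (0.98 and 1.10 for TA–GL at 60–100 m) reach or
exceed the mathematical maximum of magnitude-squared coherence; the
generator clamps all targets at 0.95, since a common-drive model with any
independent noise cannot reach 1. This clamp is a documented discrepancy,
not a resolution.

Velocities come in two modes:

* **table** (default): each cell draws from its configured
  (mean, SD), truncated at ±3 SD, plus a participant-level intercept
  (SD 0.2 m/s) shared across that participant's cells so grouped
  cross-validation is meaningful. The residual SD is reduced to
  $\sqrt{\mathrm{SD}^2 - 0.2^2}$ so the *total* per-cell SD reproduces the
  configured values rather than inflating them.
* **formula**: the packaged reference equation (below) is evaluated on the
  features extracted from the generated signals, plus Gaussian noise
  (default SD 0.15 m/s). This mode is the ground truth for model-recovery
  experiments.

Participants also receive a log-normal EMG amplitude factor (log-SD 0.2)
emulating gain variability between subjects; it propagates into iEMG and
RMS but not into coherence or median frequency.

**What the generator does not emulate.** Signals are stationary Gaussian
mixtures, so they lack bursting, stride-locked modulation, motor-unit
structure, movement artifacts and fatigue drift. Because the coherent
band components dominate the spectrum, the median frequency of synthetic
channels sits near 30 Hz rather than the 60–120 Hz typical of real sprint
EMG. Passing tests therefore demonstrate correctness of the estimators and
of the modelling machinery under the assumed statistical structure — not
robustness to real-world EMG pathologies.

## EMG conditioning and features

Per the acquisition convention, signals are band-pass filtered 20–450 Hz
(4th-order zero-phase Butterworth), full-wave rectified, and smoothed with
a 50 ms centered moving RMS whose windows shrink at the edges (no padding,
so no fabricated data at phase boundaries). Per phase and channel,
`features_for_phase()` computes

* iEMG $= \sum |x_n| / f_s$ (mV·s), on the rectified filtered signal;
* RMS $= \sqrt{\tfrac1N\sum x_n^2}$ (mV), on the filtered signal;
* MF — the frequency splitting the Welch power spectrum (20–450 Hz) into
  equal halves, linearly interpolated between bins. MF is computed on the
  filtered, *unrectified* signal, since rectification distorts the
  spectrum. Spans shorter than one Welch segment fall back to a single
  full-span periodogram; spans shorter than 0.5 s are rejected.

## Intermuscular coherence

`cross_spectra()` is a Welch estimator: Hann-windowed, mean-detrended
segments of 0.5 s with 50% overlap, averaged into one-sided auto- and
cross-spectral densities; the realized segment count $L$ follows
$\lfloor (N - n)/\mathrm{step} \rfloor + 1$. Coherence is the pointwise
ratio $|S_{xy}|^2 / (S_{xx} S_{yy})$; zero-power bins map to coherence 0
(with a warning) so band averages always exist. Band averages use
half-open intervals $[f_{lo}, f_{hi})$ so the 15 and 30 Hz boundary bins
are never counted twice. Both muscle pairs (RA–BF and TA–GL) are
computed: the results require both even though the narrative text names
only one.

Two significance conventions are exposed: the fixed reporting threshold
0.5, and the analytic 95% confidence limit
$1 - \alpha^{1/(L-1)}$ for an $L$-segment estimate. Tables default to the
fixed threshold; the analytic limit is what the independence tests use.

The estimator is validated two ways: against a brute-force
explicit-DFT implementation (agreement to 1e−8), and end-to-end — running
the IMC stage on generator output recovers the configured band targets
within ±0.05 on 60 s calibration signals. At single-trial lengths
(2.6–4 s, L ≈ 9–15) the estimator variance is substantially larger; the
per-trial coherence features carry that noise by design.

## The Kolmogorov–Arnold network

Every edge $(i,j)$ of layer $l$ carries a univariate cubic B-spline
$\Phi_{ij}(x) = \sum_k c_{ijk} B_k(x)$ on a uniform knot grid with $G$
intervals extended by three knots per side ($G+3$ basis functions, a
partition of unity, $C^2$ at the knots); nodes sum their incoming edges.
There is no residual base activation — edges are pure splines. Default
widths are [9, 5, 3, 1] and the default grid is $G = 5$; the sweep
evaluates [3, 5, 10, 20, 50, 100].

Numerical choices that matter, with the reasoning:

* **Input and target scaling.** Features are min-max scaled to $[0,1]$
  (the representation-theorem domain), fitted on the training fold only.
  The target is z-scored internally and predictions are mapped back to
  m/s; this makes the fixed regularization weights and the pruning
  threshold scale-free.
* **Initialization.** Edges initialize as random linear ramps (spline
  coefficients placed along the Greville abscissae with slope
  $\sim N(0, 1/\sqrt{n_{in}})$ plus small jitter). White-noise
  coefficient initialization gives a pure-spline deep network no
  gradient flow and training is erratic; the linear-ramp start provides
  the flow that residual activations provide in other KAN variants while
  staying inside the spline function class.
* **Objective.** Mean squared error plus
  $\lambda(\mu_1 \sum_e \lVert c_e \rVert_1 + \mu_2 \sum_e S(c_e))$ with
  per-edge entropy $S$ computed on $p_k = c_k^2 / \sum_k c_k^2$ (natural
  log, probabilities floored at 1e−12 inside the log). Defaults
  $\lambda = 0.01$, $\mu_1 = 1$, $\mu_2 = 10$.
* **Optimization.** 20 training iterations, each an L-BFGS cycle of 10
  line-search steps, with analytic gradients (spline derivatives
  backpropagated through the layers; verified against finite differences
  to 1e−6). The first quarter of the budget runs unregularized: the
  entropy gradient concentrates small coefficients before weak-but-real
  edges can emerge, and the warm start lets them establish. After the
  warm phase the hidden-layer spline domains are refreshed from the
  observed activations.
* **Out-of-domain inputs.** Inside the network, values beyond an edge's
  knot range continue linearly with the edge's average (secant) slope.
  Flat clamping collapses predictions for held-out participants whose
  feature ranges exceed the training fold's, and boundary-tangent
  extrapolation amplifies boundary wiggles; the secant is the stable
  middle ground. The exported basis evaluator clamps (with a warning), as
  its contract states.
* **Grid parameter reading.** $G$ is the number of knot intervals; the
  constant 3 appearing as the basis-sum bound is the spline degree. The
  sweep includes 5 alongside the published sweep values because the
  headline fit names grid 5 as optimal while the sweep list omits it;
  the package asserts neither, the validation loss decides.

**Pruning.** Edge importance is the standard deviation of the edge's
output over the training inputs (standardized-target scale); edges with
$w \le 0.2$ are masked, then nodes without active incoming or outgoing
edges are removed. If thresholding would disconnect the output, the
default is an error with guidance; the pipeline uses
`fallback = "backbone"`, which additionally keeps the
maximum-importance connected path from the output back to an input.
Pruned models are refit with the regularized objective but without a new
warm phase (a pure polish; re-warming a sparse path overfits it).

**Symbolic compression.** Each surviving edge is replaced by the best
$c\,g(ax+b)+d$ with $g \in \{x, x^2, e^x, \log, \sin, \text{const}\}$:
$(a, b)$ by coarse grid search refined with Nelder–Mead, $(c, d)$ by
closed-form least squares, selected by
$\mathrm{mse}/\mathrm{var} + \lambda_c C(g)$ where $C(g)$ counts free
parameters (const 1, x 2, x² 3, exp 3, log 4, sin 4). The default
$\lambda_c = 0.002$ separates family complexity without swamping genuine
fit differences between similar curves. When all edges past the first
layer come out affine, the network flattens into an additive closed form
over the raw features; otherwise the nested symbolic network is kept and
evaluated as such.

The packaged reference equation (`reference_sprint_equation()`)

$$y = 11.085 - 0.0017x_1 - 0.0002x_3 - 0.0016x_5 - 0.0036x_6
      + 0.2996x_7 + 0.0005x_8 - 0.0006x_9
      + 1.168\times10^{-5}e^{2.6409x_2} + 3.561\times10^{-6}e^{2.6896x_4}$$

is the worked example of such a compressed model and the generative truth
for recovery tests. Two observations about it shape what recovery
experiments can show. First, with coherence features bounded in $[0,1]$
and iEMG of order a few mV·s, more than 97% of the equation's variation
comes from the $x_7$ (iEMG) term; the exponential terms contribute at most
$\sim 2\times10^{-4}$ m/s, three orders of magnitude below the 0.15 m/s
noise, so their recovery from data generated at these scales is not
statistically possible — the recovery experiments measure what the
machinery does under honest conditions rather than guaranteeing that
outcome. Second, the variable definitions used here are the printed ones
(x1–x3 RA–BF alpha/beta/gamma, x4–x6 TA–GL alpha/beta/gamma, x7–x9 RA
iEMG/RMS/MF), even though the surrounding narrative elsewhere calls x2
and x4 gamma-band coherences; the conflict is noted, not resolved.

## Cross-validation and the grid sweep

`cross_validate()` partitions *participants* (default 3 folds): the nine
rows of one participant are correlated through the random intercept and
amplitude factor, and row-level splits would leak. Row-level splitting
remains available behind `grouped = FALSE` for comparison. Per fold the
pipeline is scale → train → prune(+refit) → evaluate held-out R², with
fold-specific initialization seeds derived deterministically from the
master seed. The grid sweep reports mean train/validation MSE per grid
value and selects the argmin of validation loss, ties toward the smaller
grid. `run_full()` chains simulate → features → IMC → matrix → sweep →
CV → final fit → prune → symbolize → ANOVA tables and writes a JSON +
Markdown report; identical (config, seed) give byte-identical reports.

On formula-mode cohorts at the default conditions (270 rows, noise SD
0.15), the grouped-CV R² of the full pipeline typically lands between
0.4 and 0.7 across cohort seeds, against a ceiling of roughly 0.72–0.75
set by an iEMG-only linear fit on the same data. The shortfall is the
printed objective itself: the per-edge entropy weight simultaneously
biases the dominant edge and lets residual noise spread across junk edges
that survive the 0.2 threshold. This is reported as measured; the
regularization weights are not tuned away from their published values.

## Statistics stage

`rm_anova()` computes the classical within-subject decomposition
explicitly (grand/participant/condition means), Mauchly's W via the
multivariate model, Greenhouse–Geisser
$\hat\varepsilon = \mathrm{tr}(A)^2 / ((k-1)\,\mathrm{tr}(A^2))$ from the
contrast-transformed covariance $A = C S C^\top$, both uncorrected and
GG-corrected p-values (the conventional rule — apply GG when Mauchly
p < 0.05 — selects the headline p), partial
$\eta_p^2 = SS_\text{effect}/(SS_\text{effect}+SS_\text{error})$, and
Bonferroni-corrected paired post hocs. The suite cross-checks the
decomposition against an explicit sums-of-squares oracle (1e−10) and
against `anova.mlm(test = "Spherical")`, and verifies the two-condition
identity $F = t^2$.

`partial_eta_from_f()` exposes the back-computation identity
$\eta_p^2 = F \cdot df_1 / (F \cdot df_1 + df_2)$, which reproduces the
published effect sizes from their printed F statistics and degrees of
freedom exactly as printed. The printed error degrees of freedom (27 for
a 30-participant three-condition within design, where the standard
decomposition gives 58) cannot be derived from any model considered here;
the package reports standard degrees of freedom and leaves the identity
function as the bridge to the printed triplets.

## Problem sizes used by the tests

The test suite runs the full default cohort (270 trials) for the
cardinality and determinism checks, 60 s two-channel signals for
coherence calibration (5 seeds per target), 10 cohort seeds for the
model-recovery experiment, and 20-seed simulations for the statistical
power properties. These sizes keep every experiment comfortably inside a
single-core run while leaving the estimator variances small relative to
the tolerances being asserted.

## Known limitations

* The generator's spectra are stationary and band-dominated; see above.
* Coherence features at single-trial lengths are noisy by construction;
  the study-level coherence contrasts are only qualitatively reproduced.
* The symbolic library is the fixed five-family set; no rational or
  piecewise forms.
* Deep (three-hidden-layer) KANs under the published regularization
  weights underfit relative to their linear ceiling on these data; the
  package documents rather than masks this.
* Only one-way within-participant designs are supported in the
  statistics stage (no mixed or two-way models).
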
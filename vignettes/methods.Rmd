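---
title: "Models and methods: effective connectivity of bias-trained bistable perception"
author: "bistabledcm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific question

When a constant ambiguous image (a Rubin face–vase) is viewed, perception
alternates between two interpretations. A "biasing" training block — a
modified, unambiguous version of the image that enforces the faces
interpretation — can shift subsequent perception toward the trained
percept. The question this package's analysis addresses is *how* that
control is implemented in cortex, and whether its implementation changes
with age: do older observers resist the externally induced bias by
recruiting top-down connections from anterior (middle temporal, inferior
orbitofrontal) to early visual (lingual, precuneus) sources?

The pipeline runs from raw behavioral events (button presses reporting
the current percept during six 60-s ambiguous trials before and after
training) and region-level BOLD series, through a first-level GLM and ROI
summary extraction, to bilinear dynamic causal models (DCMs) of the
four-region network and random-effects Bayesian model selection (BMS)
across subjects. Because no subject-level data are publicly deposited for
this paradigm, the package ships a synthetic-cohort generator whose
defaults encode the study conditions, so every stage is exercised end to
end with no downloads.

# Behavioral model

Each press reports the percept that *begins* at that moment; a percept
lasts until the next press or the trial end, and the interval before the
first press carries no report and is excluded from duration averages
(back-extending the first percept to the trial onset is available as an
option but not the default). All percepts across the six trials of a
block are pooled regardless of switch count. The **bias ratio** is the
mean duration of the trained ("faces") percept after training divided by
the same quantity before training: values above 1 indicate susceptibility
to the bias. Subjects are included only if every analyzed trial contains
at least three switches (presses after the first); the generator
rejection-samples trials so synthetic subjects always satisfy this.
Cohorts are compared with Welch's t-test plus Cohen's d (pooled SD), and
the initial percept is checked for cohort/block associations with
chi-square tests (Fisher fallback when expected counts fall below 1).

# Design matrices and stimulus functions

The session concatenates three blocks with no run breaks: six 60-s
ambiguous trials + 6-s fixations, sixteen 16-s non-ambiguous training
trials + 4-s fixations, six further ambiguous trials + 6-s fixations
(1112 s, 556 scans at TR = 2 s). Nine task regressors are built as
microtime boxcars (16 bins per TR) convolved with a canonical
double-gamma hemodynamic response (peak ≈ 5 s, undershoot at 16 s,
peak:undershoot 6:1, 32-s support, unit sum): the two ambiguous-block
presentations, the training-block presentation, and presses plus 2-s
pre-switch (block 2: pre-press) windows per block. Motion nuisance
columns and a constant follow. The **pre-switch event** is the 2000-ms
window ending at each press, truncated at the trial onset for early
presses; overlapping windows within one condition are merged, since a
step function cannot exceed one.

The DCM sees four *unconvolved* step functions on the same microtime
grid: ambiguous-stimulus presentation in blocks 1 and 3 (driving), and
the pre-switch windows in blocks 1 and 3 (modulatory). Block 2 is
modeled in the GLM but contributes no DCM input; the session is inverted
whole (the alternative — excising block 2 — is a configuration choice we
did not take, because the hemodynamic return to baseline during training
is informative for the decay parameters).

# ROI extraction

For each ROI (8-mm sphere), voxel series are adjusted for **effects of
interest**: the fitted contribution of every regressor other than the two
ambiguous-block and two pre-switch regressors is removed. We implement
the adjustment as the residual-forming projection on the nuisance
columns, which guarantees the adjusted series are exactly orthogonal to
motion, presses, the constant and the block-2 regressors; the retained
effects and residuals pass through. (Removing the full-model fitted
nuisance contribution instead leaves a correlated remnant whenever task
and nuisance columns overlap in time — pre-switch windows abut presses by
construction — so the projection form is the one that actually removes
the confounds.) The **principal eigenvariate** is the first singular
component of the (per-voxel mean-centered) adjusted block, scaled so that
a block of identical voxels returns the common series, and signed to
correlate positively with the voxel mean; the explained-variance fraction
is the first squared singular value over the total. An optional
inclusion mask keeps only voxels passing an effects-of-interest F-test at
p < 0.05 (uncorrected), mirroring common practice; synthetic tests use
all sphere voxels.

# The DCM

Neuronal dynamics are bilinear:
dz/dt = (A + Σ_j u_j B^(j)) z + C u_driving,
with intrinsic coupling A (reciprocal connections among LIN, PRE, MTG,
IOF except between MTG and IOF; self-connections parameterized as
−0.5·exp(θ) Hz so stability is structural), modulation B^(j) of
connection strengths by the pre-switch inputs, and driving input C from
the ambiguous-stimulus onsets into all four regions.

Each region's BOLD is produced by balloon–Windkessel hemodynamics:
vasodilatory signal ds/dt = z − κs − γ(f−1); inflow df/dt = s; venous
volume τ·dv/dt = f − v^(1/α); deoxyhemoglobin
τ·dq/dt = f·E(f,ρ)/ρ − v^(1/α)·q/v with extraction
E(f,ρ) = 1 − (1−ρ)^(1/f); and readout
y = 100·V0·(k1(1−q) + k2(1−q/v) + k3(1−v)) in percent signal change with
k1 = 7ρ, k2 = 2, k3 = 2ρ − 0.2. Defaults are the classical
κ = 0.64 s⁻¹, γ = 0.32 s⁻¹, τ = 2 s, α = 0.32, ρ = 0.32, V0 = 0.04; κ and
τ are estimated per region as log-scalings of these nominal values (the
two parameters the age comparison interrogates).

**Model space.** All four models share A (14 allowed entries) and C
(both driving inputs reach all regions); they differ only in which
connections the pre-switch inputs may modulate: model 1 — bottom-up
(LIN/PRE → MTG/IOF) before training, top-down (MTG/IOF → LIN/PRE) after;
model 2 — both directions in both blocks; model 3 — bottom-up in both;
model 4 — top-down in both.

## Numerical integration

The coupled system is integrated on a microtime grid of TR/16 = 0.125 s.
Two implementation choices matter and are deliberate:

* **Heun (explicit trapezoid) steps** rather than plain forward Euler.
  The drift is evaluated twice per bin with the bin's (piecewise
  constant) input value, making the scheme second-order within bins and
  placing input discontinuities exactly on bin boundaries. Forward Euler
  at this grid has O(dt) global error of roughly 1% of signal, large
  enough to distort parameter estimates; Heun reaches the
  matrix-exponential closed form to better than 1e-4 at a 2/64-s grid.
  With innovations the scheme is Euler–Maruyama in the noise term
  (additive, so the strong order is unaffected), and noiseless
  simulation is exactly the innovation-scale → 0 limit.
* **Log-coordinates for f, v, q.** The three positive hemodynamic states
  are integrated as logarithms — an exact change of variables, standard
  in this model family — so positivity can never be violated by a
  discrete step. This matters during inversion, where trial steps may
  propose strongly negative sustained drive; in plain coordinates such
  proposals crash the integrator rather than being gracefully rejected.
  The extraction ratio is normalized by −expm1(log(1−ρ)) so the rest
  point (z = s = 0, f = v = q = 1) is a bit-exact fixed point.

Stochastic innovations enter the neuronal states only (additive Gaussian
increments of scale innovation_sd·√dt per bin), drawn in R under the
caller's seed so simulation is bit-reproducible; observation noise is
added to the sampled BOLD.

# Inversion: variational Laplace

A stochastic DCM calls for an estimator (generalized filtering) that
estimates the hidden neuronal fluctuations alongside the parameters. Reimplementing generalized filtering is out of scope
here; instead the package inverts the **deterministic** forward model by
Gauss–Newton variational Laplace, with endogenous fluctuations absorbed
into an AR(1)-plus-white observation-noise model (fixed AR coefficient
0.2 at TR = 2 s, configurable; one log-precision hyperparameter shared
across regions, estimated with a N(4, 1/2) prior on the whitened scale).
This preserves the quantities the analysis interrogates — model ranking
and the signs of B and C parameters — at desk scale, and its residual
approximation error is visible and tested rather than hidden.

Priors (native scales): off-diagonal A ~ N(0, 1/16) Hz; B ~ N(0, 1/4);
C ~ N(0, 1); self-connection log-scaling ~ N(0, 1/16); log κ- and
τ-scalings ~ N(0, 1/64). Masked-out entries carry prior variance exactly
zero and are pinned; perturbing them cannot change the forward model.
Jacobians are central finite differences (step 1e-4); each Gauss–Newton
step is Levenberg–Marquardt damped and accepted only if the Laplace free
energy

F = log p(y | θ̂) − ½ e'Π₀e + ½ log|ΣΠ₀|

does not decrease; the λ hyperparameter is re-optimized exactly (1-D
root-finding) after every accepted step, and the posterior covariance is
mean-field between parameters and the noise hyperparameter. Convergence:
|ΔF| < 1e-2 nats on three successive accepted iterations, or 64
iterations; if no damped step can improve F by more than the tolerance
the optimizer reports convergence at a stationary point. On a
linear-Gaussian harness this machinery reproduces the conjugate
closed-form posterior (mean and covariance) to better than 1e-3 relative,
and on noiseless synthetic data it recovers the generating parameters
exactly — both are tested.

Per-region goodness of fit is the coefficient of determination
R² = 1 − RSS/TSS of the posterior-mean prediction, reported unclipped.

# Bayesian model selection and group statistics

Fixed-effects BMS sums free energies over subjects and softmaxes.
Random-effects BMS uses the variational Dirichlet scheme: subject
responsibilities u_nk ∝ exp(F_nk + ψ(α_k) − ψ(Σα)), concentrations
α_k = α₀ + Σ_n u_nk (uniform prior α₀ = 1), iterated to |Δα| < 1e-6;
**exceedance probabilities** (the posterior probability that a model is
the most frequent in the population) are estimated from 10⁶ seeded
Dirichlet draws, giving ≈ 0.01 Monte-Carlo tolerance. Per-subject
winning models are the argmax responsibilities, ties broken to the lowest
index with a warning.

Group inference on parameters uses the classical summary-statistic
approach: one-sample two-sided t-tests on per-subject posterior means of
an addressed parameter (e.g. the post-training MTG→LIN modulation), with
Cohen's d = mean/SD; hemodynamic age effects are eight Welch tests
(decay and transit time × four regions), reported uncorrected.

# The synthetic cohort: what it emulates, and what it does not

Percept holding times are lognormal (heavy-tailed holding times are
typical of bistable perception), median 4 s and log-SD 0.5 for both
percepts before training; the post-training faces median is scaled by a
cohort bias-ratio target — 1.6 for young (susceptible) and 0.92 for older
(resistant) — bracketing a realistic post-training scale (mean trained-percept
durations of roughly 7 s in susceptible young vs 4.2 s in resistant
older observers) without claiming to reproduce particular values. The initial percept is Bernoulli(0.5) with a
~1-s report latency.

The BOLD ground truth is model 1 for every subject. The shared intrinsic
matrix has excitatory bottom-up (0.10–0.18 Hz) and mildly inhibitory
top-down (−0.05 to −0.12 Hz) couplings around −0.5 Hz self-decay. Driving
inputs use a +0.035 Hz baseline with the hypothesis-bearing entries at
−0.025 Hz: young subjects receive negative drive to LIN and PRE before
training and to LIN only after; older subjects receive negative
post-training drive to LIN and IOF and carry the age effect of interest,
a +0.4 Hz group-mean top-down MTG→LIN modulation of the post-training
pre-switch input. These drive magnitudes are deliberately small: block
inputs stay on for 60 s, so the steady-state activity they induce through
the network gain must keep every region's inflow well inside the balloon
model's physiological domain (sustained z below about −γ has no
resting-flow solution) and the evoked BOLD within a realistic ±3%.

Every subject carries heterogeneous pre-switch modulations on *both*
modulatory inputs: bottom-up block-1 entries drawn from N(0, 0.3²) and
top-down block-3 entries from N(0, 0.2²), with only the older cohort's
MTG→LIN block-3 entry carrying a nonzero group mean (+0.4 Hz). This is
the generative story consistent with a model space in which the same
model wins in both cohorts while only one cohort shows a consistent group
modulation: the modulations exist in every subject, and the group
question is whether they point the same way. It also determines what the
group t-tests measure — cross-subject consistency against realistic
between-subject variance, not per-subject existence. Without per-subject
modulations at all, models that disagree only about modulation direction
would be likelihood-equivalent and model recovery would be undefined;
and with zero between-subject variance, a one-sample t-test at n = 6
becomes sensitive to the estimator's small-sample bias (below).

Noise: neuronal innovations at 0.01 Hz/√s and observation noise at 0.25%
signal change (about a fifth of the typical evoked SD). The innovation
level is deliberately an order of magnitude below the evoked drive: the
deterministic variational-Laplace estimator absorbs endogenous
fluctuations into its AR(1)+white noise model, and at substantially
higher innovation levels the flexible modulatory parameters begin to
soak up the smooth fluctuation-driven residuals of the high-variance
regions, biasing model selection toward the most flexible modulation
structures. That regime genuinely requires a stochastic estimator
(generalized filtering), which is out of scope; the limitation is stated
here rather than hidden.

A second, smaller artifact of the deterministic substitute deserves
note: modulatory parameters whose true value is zero acquire a small
positive posterior-mean bias (≈ +0.05 Hz under the default noise
levels). This is a property of the likelihood itself, not of the
optimizer — initializing at the generating parameters converges to the
same mode, and in the noiseless limit recovery is exact. Against
realistic between-subject variance the bias is immaterial for group
inference; against artificially homogeneous cohorts a small-n one-sample
t-test can flag it as a spurious group effect.

Consequently, passing tests demonstrate the pipeline's correctness and
its inferential validity in the modest-fluctuation regime — they do not
certify behavior on strongly fluctuation-driven data, nor do they
stand in for human cohort-level estimates, which would require the
(undeposited) original recordings.

What the generator does not emulate: spatial preprocessing artifacts
(realignment, smoothing), physiological noise (cardiac/respiratory),
scanner drift, percept-locked endogenous dynamics (presses are
statistically independent of the innovations, whereas in a real brain the
switches *are* caused by them), and any whole-brain spatial structure
(ROI voxel blocks are rank-1 loadings plus isotropic noise inside an
8-mm sphere).

# Study sizes and runtime choices

The packaged recovery study inverts 4 models × 12 subjects (6 young, 6
older) on full-length sessions (556 scans, 4 regions) — about 50
gradient-based inversions of 39–47 parameters each, a few seconds per
inversion with the compiled integrator. The demo analysis scripts use
6 + 6 subjects; the behavioral analyses use the full-size cohort design
(14 + 16) since press streams are cheap. Reproducibility checks run a
deliberately small two-model, four-subject pipeline twice and require
byte-identical summary JSON: determinism is size-independent.

# Degenerate inputs and edge cases

Zero-variance data are rejected in R² computation; all-zero voxel blocks
are rejected; rank-deficient designs fall back to pseudo-inverse
solutions with a warning, and nuisance projections use QR residuals so
zero columns (conditions with no events, kept for column-count
stability) are harmless. Exact ties in per-subject model probabilities
break to the lowest model index with a warning. Integration failures
(divergent neuronal states, |log f| > 50) name the offending parameter
scales in the error; during inversion they mark a rejected optimization
step instead of aborting the fit. Presses earlier than 2 s into a trial
yield truncated pre-switch windows; presses outside every trial window
are a validation error.
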
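---
title: "Latent SDE dynamics of repetitive human motion: model, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent SDE dynamics of repetitive human motion: model, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motionsde)
```

## The problem and the model

A smartphone gyroscope strapped near a trouser pocket records angular
velocity about three axes at 30 Hz. Repetitive motions — walking, running,
squats, jumping jacks — show up as roughly periodic multi-harmonic signals
whose period, amplitude mix across axes, and noise level vary by person.
`motionsde` models a 4-channel observation stream (three axes plus their
Euclidean magnitude, all z-scored) with a two-dimensional latent state
$z_t$ whose evolution is a simplified neural stochastic differential
equation,

$$\mathrm{d}z_t = \mu_\theta(z_t)\,\mathrm{d}t + \sigma_\theta\,\mathrm{d}W_t,$$

with an MLP drift and a single learned positive diffusion scalar,
discretized by Euler–Maruyama. The latent dimension is fixed at $k = 2$: it
is the smallest space that can hold a limit cycle, and it is directly
plottable, which is the point of the method — the latent trajectory *is*
the characterization of the motion.

The generative side decodes the midpoint target
$\bar{x}_{t+1} = (x_t + x_{t+1})/2$ from $z_t$ through a Gaussian MLP
decoder with one shared learned standard deviation. Decoding the raw frame
tends to produce oscillatory latents and decoding the next frame overly
smooth ones; the midpoint sits between the two. The prior over the initial
state is $\mathcal N(\mu_0, 0.2^2 I)$ with $\mu_0$ the projection of the
first frame onto the two leading principal components of the training
frames ($\sigma_0$ fixed, not trained; history length $m = 0$).

The filtering posterior $q(z_t \mid x_{0:t})$ is a Gaussian with isotropic
covariance whose means all come from one causal GPT2-style transformer (two
pre-norm decoder blocks, one head, learned token and positional
embeddings). The causal mask makes each posterior mean a function of past
and current frames only — the model never peeks at the future, so the same
weights work online. Training maximizes the sequential evidence lower
bound: a reconstruction expectation under one reparameterized sample per
step, minus the initial KL against the PCA prior, minus closed-form
Gaussian transition KLs evaluated at the sampled previous state. A window
of $L$ frames contributes $L-1$ reconstruction terms and $L-2$ transition
terms; with the default $L = 91$ the encoder consumes 90 tokens and its
attention maps are $90 \times 90$.

## Parameters that matter

| parameter | default | meaning / why |
|---|---|---|
| `T` (window length) | 90 | about three walking cycles at 30 Hz; windows carry `T`+1 frames |
| latent dimension | 2 (fixed) | plottable; sufficient for limit-cycle dynamics |
| `sigma0` | 0.2 | prior sd around the PCA anchor, dimensionless latent units |
| `dt` | 1 | one Euler–Maruyama substep per 30 Hz sample; any physical time scale is absorbed into the learned drift and diffusion |
| drift / decoder hidden widths | 64, 64 | small smooth vector fields suffice in 2-D; configurable |
| `embed_dim` | 32 | transformer width; the single head uses the full width as key dimension |
| batch size | 128 | windows per AdamW step |
| learning rate / weight decay | 1e-3 / 1e-2 | AdamW conventions; decay applied uniformly, including embeddings and layer-norm gains |
| `contrast_weight` | 0 | weight of the optional contrastive term; 0 disables it and provably leaves the contrast network untouched |
| KDE percentile `q` | 5 | membership threshold: about 95% of training latents are members of their own region |
| smoothing window | 5 | trailing moving average over latent steps before region labeling |

The diffusion scalar is parameterized through a softplus and the two
observation/posterior scales through exponentials, so positivity holds for
any parameter value. The posterior scale is one global learned scalar: the
ELBO stays well-posed without per-step variance heads, at the cost of
homoscedastic posterior uncertainty.

## What the synthetic generator emulates — and what it does not

Real recordings of this kind are personal data and are not shipped;
instead, the generator produces multi-subject, multi-motion recordings
with known ground truth. Each motion archetype is a fundamental sinusoid
plus two harmonics (weights 1, 0.4, 0.15) per axis — gyroscope gait
signals are multi-harmonic — with a motion-specific period (walking 30
samples per cycle, running 20; squats 45 and jumping jacks 25 as fixture
defaults) and a motion-specific mix of axis amplitudes: leg swing
dominates the mediolateral axis when walking, running adds strong thigh
pitch, squats are slow hinge rotations, jumping jacks mix abduction axes.
Distinct mixes matter: if every motion excited the axes in the same
proportion, all motions would collapse onto a single direction of
observation space and no latent method could tell them apart — nor would a
real sensor ever see that degeneracy. Subjects perturb tempo
(U(0.85, 1.15)), amplitude (U(0.7, 1.3)) and per-axis phase (U(0, 2π)),
and add white Gaussian noise (0.05 rad/s by default). Phase offsets of
exactly zero on all axes make the three channels scalar multiples of one
waveform (a rank-one signal); experiments therefore use phase-shifted
subjects, as drawn profiles essentially always are. Motion switches carry
the accumulated oscillator phase across the switch, so the change is in
frequency, not an artificial jump.

Not emulated: sensor bias and drift, accelerometer channels, gait
asymmetries, fatigue, non-stationary tempo. Passing tests on this
generator show that the machinery — inference, training, regions,
switching — behaves as designed on signals with the right gross structure;
they do not certify performance on real human data.

## Numerical choices

* **Gradients.** All gradients (MLPs, layer norm, causal softmax
  attention, the full ELBO including the reparameterized sample paths and
  both KL families) are hand-derived reverse-mode; the suite checks them
  against central differences at relative tolerance 1e-4.
* **z-scoring** uses the population (divisor $n$) standard deviation, fit
  on the chronological 80% training split only, making the two-point
  example $[0,2] \to [-1,1]$ exact and leaving no test-set leakage.
* **PCA sign ambiguity** is resolved by forcing the largest-magnitude
  loading of each component positive; the projection is fit once on all
  training frames.
* **Stochastic estimates.** Outer ELBO expectations use one sample per
  step by default (`mc_samples` configurable); validation losses use
  seeded draws so histories reproduce bit-for-bit from the config seed.
  Every derived seed comes from one global seed through a fixed integer
  hash.
* **Initial-state optimization** runs adaptive-moment descent (500
  iterations, step 1e-2) on $z_{-T_0}$ only, through a deterministic
  drift-only rollout — a stochastic rollout would make the objective
  itself noisy. The incumbent (best-so-far) iterate is tracked, so the
  reported trace is non-increasing, and if descent somehow ends worse than
  the PCA start the PCA result is returned with a flag: the optimized
  start never loses to the baseline.
* **KDE regions** use per-axis Scott's-rule bandwidths
  ($\mathrm{sd}\cdot n^{-1/6}$). The membership threshold is the 5th
  percentile of the density at the training points: the paper-style
  contour plots show regions, a percentile rule makes membership testable.
* **Switch semantics.** Labels are the argmax region density of the
  trailing-mean trajectory; steps below every region threshold are
  `"abnormal"`. A *switch* is a change of the held region label; abnormal
  excursions do not constitute switches (walking–abnormal–walking is a
  transient, walking–abnormal–running is one switch). On scaled-down
  models a switch may still be accompanied by brief label flicker when the
  two motions' latent regions touch.
* **Degenerate inputs** fail fast with classed errors: zero-variance
  channels, too-short recordings, non-monotone timestamps, single-user
  contrast batches, unfit priors, NaN losses (reported with the offending
  ELBO term).

## Design decisions where the design was open

* The negative-pair contrast term is implemented as the standard
  discriminator form $\log(1 - \sigma(C))$; the literal printed variant
  $\log \sigma(1 - C)$ is available behind `literal_contrast` — the two
  differ only by a reparameterization of the logit but the standard form
  saturates correctly at both ends. Negative pairs are drawn uniformly
  from other users within the batch, aligned by time step; gradients flow
  to the contrast weights and the posterior, not the generative side.
* The contrastive term can group windows by subject (user
  identification) or by motion (`contrast_by = "motion"`): pooling several
  motions in one latent space benefits from a term that pushes the
  motions' latent populations apart, and the same mechanism serves both
  uses.
* Window stride defaults to `T` (non-overlapping) for training; stride 1
  is available for dense trajectory extraction. Long recordings are
  encoded chunk-wise at the transformer's maximum length and concatenated;
  each chunk restarts the posterior's context, a visible but brief
  transient.
* The 20% held-out split doubles as the validation monitoring set for the
  overfitting early-warning check (validation loss stopped improving
  `patience` epochs ago and has increased since).

## Scaled-down experiment sizes

The experiments in the test suite and in `scripts/acceptance.R` are sized
for a single CPU core: recordings of 1 800–2 400 samples (1–1.3 minutes of
signal), 15–40 training windows, networks of width 16–32, and 100–250
epochs with batch size 8. Under these conditions the trained model
preserves the walking/running periods in its latent trajectories to within
about 1%, identifies two tempo- and amplitude-separated users with
held-out pairing accuracy above 0.95, and dates a mid-recording
walking-to-running switch to within a few steps. Small batches are
deliberate at this data scale: with only tens of windows, full-batch
training would take one optimizer step per epoch and the contrast scorer
would see too few updates to converge.

## Known limitations

* $k = 2$ is hard-wired; higher-dimensional latents would need a
  visualization layer this package does not provide.
* One global posterior scale means uncertainty is not time-resolved.
* Chunked encoding of long streams introduces periodic context resets;
  a streaming encoder with carried state would remove them.
* The hand-rolled KDE is exact but $O(n)$ per query point; regions built
  from very long training runs would want subsampling.
* Training is single-threaded R; it is comfortable at the scales above
  but not intended for hour-long multi-subject corpora.
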
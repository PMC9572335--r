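# motionsde

Latent-dynamics characterization of repetitive human motions — walking,
running, squats, jumping jacks — from smartphone gyroscope recordings.

A pocket-worn phone's gyroscope sees a repetitive motion as a noisy,
high-dimensional periodic signal. `motionsde` compresses such signals into a
two-dimensional latent trajectory that keeps the motion's temporal
signature (its cycle frequency) while exposing structure you cannot read
off the raw signal: which motion is being performed, which person is
performing it, and when the motion changes.

## The model

Observations are 4-channel frames `x_t` (the three angular-velocity axes at
30 Hz plus their magnitude, all z-scored on the training split). Latent
states `z_t` in R² follow a neural stochastic differential equation

    dz_t = mu_theta(z_t) dt + sigma_theta dW_t

with a small MLP drift `mu_theta` and a learned positive scalar diffusion
`sigma_theta`, discretized by Euler–Maruyama (one step per sample). A
Gaussian MLP decoder models the midpoint target
`xbar_{t+1} = (x_t + x_{t+1}) / 2` — the compromise between reconstruction
and one-step prediction. The prior over the initial state is
`N(mu_0, 0.2² I)` with `mu_0` the PCA projection of the first frame.

The intractable filtering posterior `q(z_t | x_{0:t})` is amortized by a
small causal GPT2-style transformer (two layers, one head): causal
self-attention guarantees each posterior mean uses only past and current
frames, so the model is usable online. Generative and inference parameters
are trained jointly with AdamW by maximizing the sequential evidence lower
bound

    ELBO = sum_t E_q[ log p(xbar_{t+1} | z_t) ]
           - KL(q(z_0|x_0) || p(z_0))
           - sum_t E_q[ KL(q(z_t|x_{0:t}) || p(z_t|z_{t-1})) ],

with every KL in closed form. An optional contrastive term trains a scorer
`C(x_t, z_t)` so same-source (observation, latent) pairs score high and
cross-source pairs low — sharpening user-specific (or motion-specific)
latent structure for identification.

On top of the trained model the package provides: optimized initial latent
states (gradient descent on `z_{-T0}` against a pre-window of
observations), kernel-density "normal latent regions" per motion with a
percentile membership threshold, motion-switch detection on rolling-mean
latent trajectories, and attention heat-map extraction.

All network gradients (MLPs and the transformer) are computed by
hand-derived reverse-mode backpropagation, verified in the test suite
against central-difference oracles.

Because raw study recordings are not distributable, the package includes a
first-class synthetic generator of multi-subject, multi-motion gyroscope
signals (per-motion periods and axis profiles, per-subject tempo,
amplitude, phase and noise), used by every test and experiment.

## Worked example

```r
library(motionsde)

rec <- generate_recording(motion_archetype("walking"),
                          subject_profile("S1", phase_offsets = c(0.4, 1.9, 3.4),
                                          noise_sd = 0.05),
                          n_steps = 1200, seed = 1)
rec
#> <sensor_recording> subject=S1 motion=walking  1200 samples @ 30 Hz

fit <- fit_motion_model(rec, T = 60, embed_dim = 16,
                        drift_hidden = 16, decoder_hidden = 16,
                        config = train_config(n_epochs = 60, batch_size = 8, seed = 0))
fit
#> <motion_fit> 15 train / 3 test windows, 60 epochs
#>   final loss: train 504.3439, val 508.1975
#> <motion_model> latent SDE (drift 2-16-2, sigma=0.109) + GPT2 posterior (2 layers, 1 head(s), embed 16)
#>   window T=60, prior fitted

lat <- latent_trajectory(fit$model, do.call(rbind, fit$data$test_windows),
                         normalized = TRUE)
dominant_period(lat[, 1])
#> [1] 30.5
```

The walking signal was built with a 30-sample cycle; the inferred latent
trajectory on held-out data oscillates with a dominant period of 30.5
samples — the latent space preserves the motion's time-domain frequency,
which is the property everything else (regions, switching, identification)
builds on. `attention_heatmap(fit$model, window, layer_index = 1)` returns
the causal attention weights (rows sum to 1, strictly upper triangle 0)
behind each posterior mean.

A thin command-line wrapper over these functions ships in
`inst/cli/motionsde.R` (`simulate | preprocess | train | infer | analyze`).

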
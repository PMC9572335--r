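Package: motionsde
Title: Neural Stochastic Differential Equation Latent Dynamics for
    Gyroscope-Based Human Motion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Characterizes repetitive human motions (walking, running,
    squats, jumping jacks) recorded by a smartphone gyroscope at 30 Hz.
    A two-dimensional latent stochastic differential equation with a
    neural-network drift and scalar diffusion models the motion dynamics;
    a small causal GPT2-style transformer provides the filtering
    variational posterior q(z_t | x_0:t), and both are trained jointly
    by maximizing a sequential evidence lower bound with AdamW. Includes
    a synthetic multi-subject gyroscope signal generator, an optional
    contrastive loss for user identification, optimization of initial
    latent states, kernel-density normal-latent-region estimation, and
    motion-switch detection on latent trajectories. All network gradients
    are computed by built-in reverse-mode backpropagation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
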
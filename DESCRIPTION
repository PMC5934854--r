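Package: vestibsim
Title: Simulating Vestibular Self-Motion Inference with Particle Filters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A generative model of head-velocity perception during yaw
    rotation and sequential Bayesian inference over it. Head velocity is a
    latent state observed through noisy semicircular-canal measurements
    (healthy) or pure neuronal noise (bilateral vestibulopathy); an
    efference-copy-like knowledge signal, gated by an active/passive switch,
    sharpens the one-step-ahead prediction. Inference is carried out by a
    bootstrap particle filter with systematic resampling, cross-checked
    against an exact conditionally linear-Gaussian filter, plus an off-line
    imagery mode that runs the prediction chain without sensory updates.
    Includes perception metrics (perceived gain, response lag, posterior
    uncertainty, zero-motion score), condition builders for healthy and
    vestibulopathic agents, rehabilitation interventions (sensor-noise
    inflation, prior sharpening), parameter sweeps, and a seeded,
    configuration-driven experiment runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
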
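---
title: "Modelling vestibular self-motion inference: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling vestibular self-motion inference: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`vestibsim` simulates an agent inferring its own head velocity during a yaw
head turn, under four crossed conditions — healthy or bilaterally
vestibulopathic (BVP) sensors, passive or self-initiated movement — and
under two belief-level rehabilitation interventions. This vignette explains
the model, the default parameters and why they have the values they do, the
numerical machinery, and what the simulations can and cannot say.

## The generative model

Time is discretized at `dt` seconds. The latent head angular velocity
$\Omega_t$ (deg/s; positive = leftward yaw, our documented sign convention)
follows a damped random walk with an optional pull toward a knowledge
signal $u_t$:

$$\Omega_t \mid \Omega_{t-1} \sim N\!\big((1-bS)\,a\,\Omega_{t-1} + bS\,u_t,\;\sigma_q^2\big)$$

* $a$ — per-step persistence. The agent's "laws of physics": head velocity
  does not jump, it decays smoothly toward rest.
* $\sigma_q$ — the innovation sd, i.e. the **width of the dynamic prior**.
  This is the quantity cognitive training sharpens.
* $b \in [0,1]$ — how strongly the prediction is pulled toward the
  knowledge signal; $S \in \{0,1\}$ is the binary active/passive switch.
  Knowledge enters as a convex combination on the velocity level rather
  than as an additive control input. This keeps the model conditionally
  linear-Gaussian given $(u_t, S)$, so an exact filter exists and every
  particle-filter result can be checked against a closed form.

The agent's **sensor model** is $y_t \sim N(\Omega_t, \sigma_v^2)$ with the
*assumed* noise width $\sigma_v$ — the quantity conventional rehabilitation
inflates. The **world** need not agree with the agent's beliefs: healthy
observations really are $\Omega_t$ plus Gaussian noise; BVP observations
are Gaussian neuronal noise generated independently of $\Omega_t$. The
untreated BVP agent keeps the healthy sensor model — it has no way of
knowing its sensors are deafferented — and this mis-specification is what
makes the noise-only likelihood drag the posterior toward zero during
active movement.

The true trajectory is a raised-cosine velocity bell,
$\Omega(t) = A\sin^2(\pi (t-t_0)/T)$ inside the movement window: smooth,
zero-valued and zero-sloped at both ends, with closed-form displacement
$AT/2$ used as a test oracle.

## Default parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `dt`, `total_time` | 0.01, 2.0 | s | resolves the 1-s turn with 100 steps at plausible neural update rates |
| amplitude $A$, duration $T$, onset | 60, 1.0, 0.5 | deg/s, s, s | a brisk 1-s head turn of 30 deg total displacement |
| healthy `sensor_noise_sd` | 10 | deg/s | noticeable scatter relative to the 60 deg/s peak, as in semicircular-canal afferent variability |
| `bvp_noise_sd` | 2 | deg/s | deafferented nerves retain only low-amplitude spontaneous activity, well below healthy transduction noise; see below |
| knowledge gain / noise / delay | 1, 2, 0 | –, deg/s, s | efference copy treated as an unbiased but slightly noisy velocity expectation |
| decay $a$ | 0.995 | per step | velocity persistence with a ~2 s relaxation time |
| $\sigma_q$ | 6 | deg/s per step | a broad dynamic prior: the passive agent must rely on its sensors |
| $b$ (untreated) | 0.8 | – | strong but not total reliance on the efference copy |
| assumed $\sigma_v$ | 10 | deg/s | matches the healthy world — correct for healthy agents, mis-specified for BVP |
| initial mean / sd | 0, 1 | deg/s | the head starts at rest, and the agent knows it |
| sensor inflation | 10 | – | conventional rehabilitation: an order of magnitude less trust in vestibular data |
| prior sharpening / trained $b$ | 3, 0.95 | – | cognitive training: a markedly narrower dynamic prior, near-full reliance on predictions |
| particles $N$, resample threshold | 5000, 0.5 | – | see numerics |

All are configurable through `default_config()` / YAML files; the values
above define the package's study conditions and are not tuned per run.

**Why `bvp_noise_sd = 2` rather than the healthy 10.** The BVP noise
amplitude controls only how far the noise-driven posterior wanders, not the
systematic attenuation of active-movement estimates (that is set by the
assumed $\sigma_v$, which fixes the Kalman gain pulling the posterior
toward the zero-mean data). Closed-form analysis of the exact filter shows
that with noise amplitude 10 the passive BVP posterior mean has a
stationary sd near 5 deg/s — its estimate would visibly wander rather than
remain at zero, contradicting the defining clinical signature the model
exists to reproduce (a BVP patient cannot detect passive self-motion).
Physiologically, a deafferented vestibular nerve carries severely reduced
spontaneous activity, so a residual noise floor well below healthy
measurement noise is the realistic choice. With 2 deg/s the passive
zero-motion score has median ≈ 0.05 while the active attenuation
(gain ≈ 0.68) is untouched.

## Inference

**Bootstrap particle filter.** Particles start from
$N(\text{initial mean}, \text{initial sd}^2)$. Each step propagates every
particle through the prediction mean plus a $\sigma_q$ innovation, adds the
Gaussian observation log-likelihood to its log-weight, and normalizes with
log-sum-exp (weights never leave log space unnormalized, so underflow
cannot zero them collectively). Posterior mean and sd are the weighted
moments (the sd is the weighted, biased estimator — at $N \geq 5000$ the
bias is negligible and the estimator is the standard SMC choice). The
effective sample size $1/\sum w_i^2$ triggers **systematic resampling**
below $0.5N$: one uniform draw $u$, offspring positions $(u+j)/N$ against
the cumulative weights, which guarantees every offspring count is within 1
of $N w_i$. The cumulative-weight vector is renormalized by its last
element to keep `findInterval` monotone under round-off.

**Exact filter.** Given $(u_t, S)$ the model is linear-Gaussian, so a
Kalman-style recursion with prediction variance
$(a(1-bS))^2 P_{t-1} + \sigma_q^2$ is exact. It is the oracle in the test
suite: at $N = 50{,}000$ the particle filter must agree within 2 % of the
trajectory amplitude on all six named conditions, and its RMSE must fall
monotonically over $N \in \{10^2, 10^3, 10^4\}$ averaged over 10 matched
seeds. The exact filter also handles the $\sigma_v = 0$ limit (posterior
collapses onto the observations), which the likelihood-weighting particle
filter cannot.

**Imagery mode.** `run_imagery()` iterates the prediction recursion with no
update step: mean driven by the knowledge signal, variance growing by the
prediction recursion. Inflating $\sigma_v$ by $10^6$ makes the full filter
reproduce imagery to within 0.5 % of amplitude — filtering with an
uninformative likelihood *is* off-line simulation, which is the formal
reading of motor imagery in this model.

**Seeding.** Every random source (observations, knowledge, filter) draws
its seed from one master seed through a documented base-31 polynomial hash
modulo $2^{31}-1$, computed in exact double arithmetic so it is identical
on every platform. Replicate seeds hash the patient type rather than the
full condition label, so all conditions sharing a world (e.g. the three
BVP rehabilitation arms) see identical noise realizations and comparisons
are fully paired. Reruns with the same configuration and master seed
produce byte-identical CSVs.

## Metrics

* **Displacement gain** (headline) and **peak gain**: estimated ÷ true
  displacement, and posterior mean at the true peak time ÷ true peak.
  Displacement gain is robust to jitter at the peak. "Reduced VOR gain" in
  BVP is operationalized as displacement gain < 1 — an analogy at the
  perceptual level, not an oculomotor simulation.
* **Response lag**: the non-negative delay (≤ 0.3 s by default) maximizing
  the cross-correlation between estimate and delayed truth, with parabolic
  interpolation around the discrete argmax for sub-step resolution. The
  search is restricted to non-negative lags because a causal filter cannot
  systematically lead its stimulus. A flat trace returns 0 with a
  degenerate-input warning.
* **Mean uncertainty**: mean posterior sd over the movement window.
* **Zero-motion score**: peak |posterior mean| ÷ true peak; the
  passive-BVP signature is a median below 0.1 (a design threshold — the
  underlying claim is qualitative).

## What the simulations show — and what they do not

The synthetic world emulates the *informational* situation of the
vestibular periphery: a latent velocity, noisy-or-uninformative
measurements, and an internal expectation for self-initiated movement. It
deliberately omits semicircular-canal transfer dynamics (high-pass
filtering, cupula time constants), 3-D kinematics, otolith/translation
channels, explicit visual or proprioceptive fusion (absorbed into the
abstract knowledge signal), oculomotor dynamics and covert saccades, and
any learning across sessions. Passing the test suite therefore shows that
the inference machinery produces the qualitative perceptual signatures
under the stated assumptions — not that real patients' gains or lags take
these numeric values. No quantitative clinical measurements enter the
model, and none are claimed to be reproduced.

Problem sizes in the shipped tests and acceptance script: 201-step grids,
20 paired replicates for condition suites (10 for sweeps and
convergence curves), 5000 particles for experiments and 50,000 for oracle
comparisons. These sizes give Monte Carlo errors one to two orders of
magnitude below every margin being tested.

## Open design points, resolved

* **Is the switch $S$ inferred?** No: it is set by the condition (passive
  or active), matching the graphical model's treatment of $S$ as given.
  Inferring $S$ would make the model a switching state-space model and is
  out of scope.
* **Where does BVP-active attenuation come from?** Both a likelihood pull
  toward zero-mean data and a possibly reduced knowledge gain could
  attenuate; the package exposes both knobs but the defaults attenuate via
  the likelihood pull alone (knowledge gain 1), the mechanism the
  mis-specified sensor model produces on its own.
* **Interventions are idempotent at factor 1 and commute**, so
  "conventional + cognitive" is well-defined regardless of application
  order; both act only on the internal model, never the world.
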
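---
title: "Methods: hierarchical diffusion modelling and causal difference-in-differences for stimulation studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hierarchical diffusion modelling and causal difference-in-differences for stimulation studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem this package addresses

A within-subject perturbation experiment — for example, inhibitory
theta-burst stimulation over a prefrontal region — asks whether a targeted
neural system is causally necessary for one kind of decision but not
another. Participants make matched perceptual and value-based choices about
identical stimuli, in short alternating task blocks, before and after the
perturbation. Because the two tasks share stimuli, responses and motor
demands, the value task serves as a within-subject control: any effect of
the perturbation that is specific to the perceptual task shows up as a
difference-in-differences (DID),

$$\phi = [\mathbb{E}(V \mid \text{post, perceptual}) -
          \mathbb{E}(V \mid \text{pre, perceptual})] -
         [\mathbb{E}(V \mid \text{post, value}) -
          \mathbb{E}(V \mid \text{pre, value})],$$

for any behavioural, latent or neural variable $V$. `driftdid` implements
the full analysis chain for such designs — data simulation, hierarchical
Bayesian drift-diffusion modelling, neural-covariate model comparison, and
trial- and subject-level DID regressions — as a tested, reproducible
pipeline. Everything runs on synthetic data with the statistical structure
such experiments assume, so every stage is verifiable without any
external download.

## The decision model

Choices and response times are modelled as a one-dimensional Wiener
accumulation process: evidence $x_t$ starts at a fraction
$\beta = 0.5$ of the boundary separation $\alpha$ and evolves with drift
$\delta$ and unit diffusion until it is absorbed at $\alpha$ (the correct
response, under accuracy coding) or at 0. Observed response time is the
absorption time plus a non-decision time $\tau$ covering sensory encoding
and motor execution. The drift on a trial with ordinal evidence level
$E \in \{1,2,3,4\}$ is $\delta = \kappa E$: a single free drift scale
$\kappa$ per subject and condition cell, rather than separate drifts per
evidence level.

Three modelling conventions deserve note:

* **Diffusion scale.** The diffusion coefficient is fixed at
  $\sigma = 1$. Drift, boundary and diffusion are only jointly identified
  up to a common factor, so a scale convention is required;
  `choice_probability()` is invariant under the common rescaling, which
  the tests check.
* **First-passage density.** The two-boundary Wiener first-passage density
  is computed with the complementary small-time and large-time series
  expansions, switching by whichever needs fewer terms at truncation
  tolerance $10^{-10}$ (the usual adaptive rule). The joint density over
  both boundaries integrates to one; unit tests verify normalisation to
  $10^{-3}$ and agreement with brute-force path simulation at three
  binomial standard errors per histogram bin.
* **Mean decision time.** The derived measure
  `decision_time(alpha, kappa)` implements the hyperbolic-tangent
  expression $t_d = (\alpha/\kappa)\tanh(\kappa\alpha)$ exactly as used in
  this analysis tradition for the accumulated-evidence construction. This
  is *not* the classical mean first-passage time from a midpoint start,
  $(\alpha/2\delta)\tanh(\delta\alpha/2)$, which the package provides
  separately as `mean_fpt()` and uses as the simulator oracle. The two
  differ by construction (the former is a per-evidence-unit convention);
  we implement the printed measure for the accumulated-evidence chain
  $aE = \alpha t_d / 2$ and the classical form for simulator validation,
  and make no attempt to reconcile them. The trialwise surrogate used as
  a BOLD regressor is $aE_i = \sqrt{RT_i / E_i}$, with $E$ entered as the
  ordinal level 1-4 (the regressions use the same coding, so the units
  question dissolves by consistency).

## The synthetic-data generator

The generator is a first-class module: it defines the study conditions
under which everything downstream is tested.

* **Design.** 8 sessions of 32 trials per subject (256 total), sessions
  1-4 pre- and 5-8 post-stimulation, with the last two sessions also
  flagged as a recovery period. Sessions consist of alternating task
  blocks of 7-9 trials (the starting task is randomised per session, as
  the block order is not constrained by the design); each session splits
  16/16 between tasks so that the full factorial task x evidence level x
  correct side is exactly balanced at 16 trials per cell. Rating pairs
  are not simulated; trials are generated directly at target evidence
  levels, since the pairing algorithm that selects item pairs at
  admissible rating gaps (5-20% area gaps; 1-4 value gaps) resamples
  internally and only its output distribution matters. A behaviourally
  inert task-irrelevant evidence level is included so the standard
  control-regressor set is constructible.
* **Behaviour.** Choices and RTs are drawn from the package's own path
  simulator (Euler-Maruyama, step $10^{-4}$ s, with the
  Broadie-Glasserman-Kou continuity correction that shifts both
  boundaries inward by $0.5826\sigma\sqrt{dt}$; without it the simulated
  RT distribution is visibly biased at this step size). Trials are
  censored at the 3 s response window, and an independent Bernoulli miss
  process (default rate 0.02 — the observed rate of non-responses is not
  published, so this is a fixed design choice of plausible magnitude)
  marks further trials invalid. Invalid trials carry no outcome and never
  enter any likelihood or regression.
* **Parameters.** Group means default to $\kappa = 0.4$ per evidence
  unit, $\alpha = 1.6$, $\tau = 0.35$ s with between-subject standard
  deviations 0.08, 0.2 and 0.05: accuracies then span roughly 0.65 at
  evidence level 1 to 0.93 at level 4 with mean RTs near 1 s, the
  qualitative pattern such experiments show. The default `"boundary"`
  scenario lowers the perceptual boundary by 0.35 after stimulation
  (faster, less accurate perceptual choices — the reduced-criterion
  account); `"ndt"` shortens the value task's non-decision time by
  0.06 s; `"both"` combines them; `"null"` applies nothing.
* **Neural coupling.** A latent standard-normal signal $\theta_i$ per
  trial enters the effective boundary as $\alpha + \gamma\theta_i$ when
  $\gamma > 0$. The observed single-trial beta is $\theta_i$ plus
  Gaussian measurement noise (sd 0.5), z-scored within subject over valid
  trials — matching the usual preprocessing of single-trial GLM betas,
  where only within-subject variation is interpretable. Measurement
  noise attenuates the recoverable coupling by
  $1/\sqrt{1 + 0.5^2} \approx 0.89$, which recovery tests take into
  account. Gaussian noise is the simplest model consistent with z-scored
  betas; real betas have heavier tails and temporal autocorrelation the
  generator does not emulate, so passing tests demonstrate estimator
  correctness under the assumed structure, not robustness to fMRI noise
  pathology.

## Hierarchical Bayesian estimation

Each subject contributes one $(\kappa, \alpha, \tau)$ triplet per
task x phase cell, drawn from cell-level group distributions:
normal for $\kappa$, normal truncated at zero for $\alpha$ and $\tau$.
Priors are weakly informative — group means
$\kappa \sim N(0, 5)$, $\alpha \sim N(1.5, 1)$ truncated positive,
$\tau \sim N(0.3, 0.25)$ truncated non-negative, all scales
half-normal(0, 1) — because the original analysis tradition does not
publish its priors; a sensitivity test doubles all prior scales and
requires group posterior means to move by less than 5%. The printed
hierarchy in this tradition indexes parameters by trial; we treat
parameters as subject x cell constants, the standard identifiable choice
at this scale (trial-level parameter variation is not separably
identified from diffusion noise without much larger designs), and do not
offer a trial-level mode.

The sampler is self-contained adaptive Metropolis-within-Gibbs:

* subject-level parameters by one-at-a-time Gaussian random-walk
  Metropolis with Robbins-Monro step adaptation (target acceptance 0.44)
  during burn-in only;
* group means and scales by univariate slice sampling on their exact
  conditionals, including the truncated-normal normalising constants;
* a joint translation move that shifts a cell's group mean and all its
  subject values together (every fourth sweep with data, every sweep
  without). This decorrelates the hierarchical location from its
  offspring — the classic funnel — and is what makes a zero-data fit
  reproduce its prior (a sanity mode the tests exercise with a
  Kolmogorov-Smirnov check).

Chains run sequentially with seeds derived from one base seed. The
retained-draw arithmetic is exact (`draws/thin` per chain, so the
published-scale preset of 100,000 post-burn-in draws thinned by 100
yields exactly 1,000 per chain). Convergence is monitored by
rank-normalised split $\hat R$ — stricter than the classic statistic —
against the conventional 1.05 bound; non-convergence is reported by
warning and a flag, never silently. Posterior hypothesis tests report
$p_{\mathrm{mcmc}}$, the posterior mass on the side of zero opposite the
stated direction, floored at $1/(N+1)$ so finite samples never report
exactly zero; the direction is always explicit. The posterior DID of a
group-level parameter is computed drawwise across the four cells.

Desk-scale default budgets (3 chains, 2,000 burn-in + 5,000 draws,
thin 5) converge comfortably on the default synthetic scenario; the test
suite uses smaller problem sizes (4-8 subjects, 256-512 trials each,
budgets of 300-3,000 post-burn-in sweeps) chosen so each property is
demonstrated at the smallest scale at which it is statistically decisive.

## Neural-covariate model variants and DIC

Four a-priori variants attach the z-scored trialwise covariate
$\theta$ to the diffusion parameters: Model 1 to the boundary
($\alpha + \gamma\theta$), Model 2 to the drift
($\kappa E + \gamma\theta$), Model 3 to both with separate scales,
Model 4 to both with one shared scale. Coupling scales are estimated per
subject under a fixed group prior $N(0, 0.5)$ (the hierarchy of $\gamma$
is unpublished in the source tradition; a fixed subject-level prior keeps
each coupling's effective dimensionality honest in model comparison,
where a learned hyper-scale would shrink null couplings toward zero and
hide their complexity cost from the DIC). The effective
boundary is floored at 0.05 evidence units — $\alpha + \gamma\theta$ can
go non-positive for extreme betas — with the floored fraction counted
and reported (under default settings it stays below 1%).

Models are compared by the deviance information criterion
$\mathrm{DIC} = \bar D + p_D$ with $p_D = \bar D - D(\bar\theta)$
(the variance-based $p_V = \mathrm{var}(D)/2$ is available behind a
flag). The deviance focuses on the subject-level parameters, the standard
focus for hierarchical DIC. With all couplings pinned to zero every
variant's likelihood reduces exactly to the baseline's, which the tests
assert; selection consistency is demonstrated as a win-rate study over
replicate synthetic datasets generated under Model 1.

## Causal regressions

Trialwise DID regressions use a logit link for choice accuracy and an
identity link for RT, with `Task`, `TMS`, their product (the causal
coefficient $\phi$), and controls defaulting to task-relevant
evidence, task-irrelevant evidence and (for choice) RT. Inference uses
cluster-robust sandwich variances at the subject level with the CR1
small-sample factor and $t$ inference on $G-1$ degrees of freedom — the
standard choice at ~20 clusters. Complete separation (possible in small
synthetic cells) triggers a Firth-penalised fallback with a warning.

Because the logit link is nonlinear, the interaction coefficient maps to
a non-zero probability-scale difference even when the true causal effect
is zero. The correction refits the model without the interaction and
takes the trial-averaged difference of predicted probabilities — an
average partial effect over the observed covariate distribution (the
evaluation point is not specified in the source tradition; averaging
over observed rows is the conventional choice). Note one mechanical
consequence the tests document: with maximum-likelihood logit fits the
*overall* mean corrected difference is pinned near zero by the score
equations, so the informative quantities are the per-cell averages,
which the package reports alongside.

The three-way specification adds the neural covariate and all its
two-way products, making $\phi$ the `Neur x Task x TMS` coefficient;
lower-order terms are structurally required and their omission is an
error. Subject-level summaries (one row per subject x cell) are analysed
with the same three-way fixed-effects model under clustered errors; a
random-intercept variant via `lme4` is available, since the exact
mixed-effects structure is a free choice at this level.

## Orchestration and reproducibility

`run_pipeline()` chains simulate, fit, (optionally) model comparison,
DID regressions and a posterior-predictive check, logging one
machine-parseable line per stage event. Configuration is nested
key-value YAML validated against the default schema (unknown keys are
rejected). Every stage draws its seed deterministically from the one
base seed, and the run manifest records the config snapshot, stage
seeds, wall times, convergence summary and an MD5 hash of every output
file; rerunning the same configuration reproduces identical hashes,
which the tests assert. The posterior-predictive check simulates the
fitted design from a subsample of posterior draws and reports per-cell
accuracy and RT deciles with Monte-Carlo intervals next to the observed
values.

## Known limitations

* No inter-trial variability parameters (sv, st, sz) of extended
  diffusion models, and no collapsing bounds; the model class is exactly
  the one under test.
* The sampler is a random-walk scheme: adequate at the package's problem
  sizes, but not a replacement for gradient-based samplers at much
  larger scales.
* The generator's neural covariate is Gaussian and serially independent;
  conclusions about estimator behaviour under realistic fMRI noise
  require real betas.
* Empirical results from the motivating experimental literature (real
  participants' regression coefficients, model-comparison margins) are
  not reproduced here: they require the original dataset, and nothing in
  this package's tests asserts them.
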
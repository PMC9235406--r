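---
title: "Methods: the ART cognitive model, its simulator, and its estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the ART cognitive model, its simulator, and its estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The task

The Angling Risk Task (ART) is a sequential risk/reward task in the BART
family. On each of 30 trials the player repeatedly decides to *cast* (earn
5 points per red fish, at the risk of a yellow fish that forfeits the
trial's points) or to *collect* (bank the accumulated points). The
yellow-fish probability is 0.05 in the first five-trial block and rises by
0.05 per block, to 0.30. The trial's loss event is pre-generated: each
trial carries a maximum-cast value at which the yellow fish will be caught,
drawn from a geometric distribution on {1, 2, ...} with success probability
equal to the block's yellow-fish probability (so its mean is the reciprocal
1/p; over the canonical design the mean is 49/6 = 8.17). Task versions
(A, B, C) reorder the max-cast values within probability blocks, so all
versions share the same per-block multiset of loss times.

The behavioural summary score is the **adjusted score**: the mean number of
casts over trials ended by voluntary collection. Forced-fail trials are
excluded, and a player with no collected trial has a missing (not zero)
score, which propagates as missing through all statistics.

## The cognitive model

An agent is described by two non-negative parameters:

* risk propensity $\gamma^{+}$, which sets the internally optimal number of
  casts for a trial with loss probability $p$:
  $\omega = -\gamma^{+} / \ln(1 - p)$ — increasing in $\gamma^{+}$,
  decreasing in $p$;
* behavioural consistency $\beta$, the steepness of the logistic decision
  rule $P(\text{cast at opportunity } l) = 1 / (1 + e^{\beta (l - \omega)})$.

At $l = \omega$ the cast probability is exactly 0.5; $\beta = 0$ makes
every decision a coin flip; large $\beta$ makes the agent cast exactly
$\lfloor \omega \rfloor$ times. $\omega$ is used as a continuous quantity:
the logistic rule is defined for real $\omega$ and nothing requires
rounding it.

Each opportunity is a Bernoulli observation. A trial collected after $c$
casts contributes $c$ cast terms and one collect term
($1 - p^{\text{cast}}$ at opportunity $c+1$); a forced-fail trial with $m$
casts contributes only $m$ cast terms, because the yellow fish censors the
collect decision. The cast that catches the yellow fish *is* an observed
cast decision — the agent chose to cast; only the never-made collect
decision is censored. This is the standard treatment for BART-family
models. The points column never enters the likelihood; only the cast/collect
decisions are modelled. The collect decision is scored as a
$(1-p^{\text{cast}})$ Bernoulli outcome rather than treated as absorbing
without a likelihood contribution; this follows the source model family,
and because every uncensored trial ends in exactly one collect, the choice
affects all parameter values coherently rather than selectively.

All evaluation goes through `plogis()`, which saturates smoothly, so large
$\beta |l - \omega|$ cannot overflow.

## The synthetic cohort generator

Because the study's trial-level data are not deposited, every downstream
stage is validated on simulated cohorts whose generative structure matches
the inference model by construction:

* individual parameters are lognormal:
  $\gamma^{+}_i = e^{\theta_i}$, $\theta_i \sim N(\mu, \sigma)$, which
  keeps both positivity constraints automatically. The location is
  parameterised as $\log(\text{mean}) - \sigma^2/2$ so that a group
  spec's `gamma_mean`/`beta_mean` are the *population means on the natural
  scale*, directly comparable to reported group means;
* default group means in the demo configuration are the reported posterior
  group means (control: $\gamma^{+} = 1.39$, $\beta = 0.25$; dyslexia:
  $\gamma^{+} = 3.65$, $\beta = 0.07$) with group sizes 11 and 24;
* published group-level results of this task family report no
  between-subject dispersions, so the log-scale SD defaults (0.2 in the
  acceptance protocol, 0.3 in the demo
  config) are conventions chosen inside the 0.2–0.5 range typical of
  individual-difference parameters in hierarchical BART models — documented
  here, configurable everywhere, and not tuned against any test outcome;
* plays are simulated decision-by-decision from the logistic rule, with
  forced-fail censoring applied exactly as in the task;
* covariates (reading scores, TIV-corrected volumes) are built as
  standardized target parameter + independent Gaussian noise, giving the
  requested population correlation; correlations to $\beta$ are defined on
  the log scale, matching the log transform used in the association
  analysis. For $\gamma^{+}$ targets the covariate's marginal is not
  exactly Gaussian (the standardized target is lognormal), which is
  irrelevant for correlation recovery but worth knowing if you inspect
  marginals;
* one master seed drives named substreams (design, parameters, decisions,
  covariates), so each component is independently reproducible.

What the generator does **not** emulate: learning or fatigue across trials,
reaction times, heavy-tailed or bimodal individual differences, and any
dependence of decisions on banked points. A green recovery test therefore
establishes that the estimation machinery is correct *under the model's own
assumptions*, not that the model is adequate for any particular empirical
cohort.

## Hierarchical estimation

Each group is fitted independently with its own $(\mu, \sigma)$ per
parameter — the reported non-overlapping group credible intervals imply
group-wise posteriors rather than a shared hyperprior, and independent fits
make the group comparison conservative. Priors are weakly informative:
$\mu \sim N(0, 1.5)$ (on the log scale this covers natural-scale values
from roughly 0.03 to 30) and $\sigma \sim \text{half-}N(1)$. Both are
config-exposed.

The sampler is an adaptive Metropolis-within-Gibbs scheme, written for this
package because no general-purpose MCMC engine is assumed available:

1. per-subject latents $\theta_i, \phi_i$: independent Gaussian random-walk
   proposals, vectorised across subjects, with per-subject step sizes
   adapted toward 0.44 acceptance during warmup;
2. locations $\mu$: exact conjugate Gibbs draws;
3. scales $\sigma$: random-walk on $\log \sigma$ with the half-Normal prior
   and log-scale Jacobian;
4. a joint *translation* move (shift $\mu$ and all latents together), which
   removes the location–latent random-walk coupling;
5. an interweaved *scale* move in non-centered coordinates (rescale
   $\sigma$ and the latent deviations with the standardized residuals held
   fixed), which traverses the funnel that appears when the data constrain
   individual parameters weakly (small $\beta$ cohorts).

Moves 4–5 are why the centered parameterization suffices here: they are the
interweaving equivalent of the non-centered parameterization used by
gradient-based samplers, and with them split R-hat on all monitored
quantities reaches < 1.05 at the default 4 chains x (1500 warmup + 1000
kept, thinned by 16). Random-walk samplers decorrelate slowly, hence the
thinning default; kept-draw counts match the usual reporting convention
while total computation stays near three minutes per 40-subject group on
one CPU. The defaults were sized to pass the R-hat threshold with margin
on the hardest regime exercised here (large risk propensity with
near-coin-flip consistency), where the likelihood constrains individual
parameters weakly.

The group-level "mean" is reported per draw as the lognormal population
mean $e^{\mu + \sigma^2/2}$ (`group_mean_*`), which is the quantity
comparable to a natural-scale group mean; the per-draw average of sampled
individual parameters (`group_avg_*`) is emitted alongside, since a figure
caption's "group mean" could be either construction. In practice the two
agree closely.

Convergence is never silently ignored: every monitored quantity gets split
R-hat and an autocorrelation-based effective sample size; a fit that misses
the threshold is returned with `converged = FALSE`, printed as such, and
propagated into pipeline reports as a warning — it does not raise.

Chains are initialised from a coarse per-subject grid MLE with
overdispersed jitter, which keeps initial transients short and makes R-hat
an honest between-chain diagnostic rather than a test of burn-in length.

## Statistics

* **Adjusted score**: see above; missing propagates.
* **Two-sample Bayes factor**: the default-prior (JZS) Bayes factor — a
  Cauchy prior on the standardized effect (scale $\sqrt{2}/2$, the
  "medium" default of the common Bayes-factor software) with
  Jeffreys nuisance priors — computed by 1-D quadrature over the
  $g$-representation. The test suite checks it against an independent
  route: integrating the noncentral-$t$ predictive over the Cauchy prior.
* **One-way Bayes-factor ANOVA**: $g$-prior on sum-to-zero group effects
  (orthonormal basis, prior scale 0.5), $g \sim$ InverseGamma(1/2,
  $r^2/2$), marginal likelihood by 1-D quadrature; the oracle is Monte
  Carlo integration over the same prior. Quadrature was chosen over
  approximations because group counts here are tiny and the integral is
  one-dimensional.
* **Permutation test**: two-sided mean-difference permutation p with the
  add-one convention $(b+1)/(B+1)$, so p is never exactly 0; an exact
  enumeration mode exists for small samples. Mean difference is the
  implemented statistic — the conventional default for a two-group
  location comparison — and the choice is config-exposed.
* **Associations**: Pearson r with two-sided p on complete cases; $\beta$
  is log-transformed (positive skew). Bonferroni-adjusted p-values are
  attached only when a family of tests is declared, and both adjusted and
  nominal values are emitted, since reported practice is ambiguous on this
  point.
* **TIV correction**: the plain ratio volume/TIV ("corrected by" read
  literally); residual-regression correction would be a reasonable
  alternative but is not the default reading.
* **BF interpretation bands** (<1 favours null; 1–3 anecdotal; 3–10
  moderate; >10 strong) are annotations in reports, never decision rules.

## Numerical and design notes

* Logistic terms: `plogis(..., log.p = TRUE)` throughout; likelihood
  equality with a term-wise brute-force oracle is asserted at $10^{-10}$.
* The schedule constructor rejects designs whose final probability reaches
  1, where $\omega$ would be degenerate.
* Trial and opportunity indices are 1-based in every file format.
* The whole pipeline (simulate -> fit -> score -> associate -> report) is
  driven by one JSON config with unknown keys rejected, emits a manifest
  with a config hash, and reproduces simulation outputs byte-identically
  under a fixed seed. JSON (not YAML) is the config format because the
  target environment guarantees a JSON parser.
* One pre-generated max-cast sequence is shared by all subjects (reordered
  into versions), matching the task narrative; per-subject designs can be
  produced by calling the generator per subject if wanted.

## Known limitations

* Real-cohort results (group-difference Bayes factors, striatal
  correlations) require the undeposited study data; this package
  reproduces the *procedures* and validates them on synthetic cohorts.
* With weakly informative data (small $\beta$, 30 trials) group-mean
  estimates shrink perceptibly toward the prior; the acceptance protocol's
  40-subject cohorts keep this within the posterior's own uncertainty, but
  single-subject estimates at 30 trials are strongly hierarchically
  pooled and should be interpreted as such.
* The sampler is tuned for the moderate dimensions of this design
  (tens of subjects); very large cohorts would warrant a gradient-based
  sampler.
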
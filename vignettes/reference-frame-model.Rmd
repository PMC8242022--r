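---
title: "Modelling the crossed-hands deficit: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the crossed-hands deficit: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of the science it implements:
the generative model of crossed-hands tactile temporal-order judgments
(TOJ), the behavioural statistics, the hierarchical Bayesian estimator
and its sampler, and the design decisions taken where more than one
reasonable choice existed.

## The task and the deficit

In a tactile TOJ trial two brief vibrations are delivered, one to each
thumb, separated by a signed stimulus onset asynchrony (SOA); the
participant reports which hand was stimulated first. With the hands
crossed over the midline accuracy collapses, because the external
(spatial) code for the touch points to the wrong response while the
internal (anatomical) code points to the right one. The canonical
design crosses two postural factors within participant — hand posture
(uncrossed/crossed) and body posture (sitting upright / lying on the
left side) — and manipulates vision (blindfold or not) between
experiments. Eight SOAs are used (±50, ±100, ±200, ±400 ms; negative =
left hand first), 12 blocks of 64 trials, giving 24 trials per
(body × hand × SOA) cell; `schedule_trials()` reproduces exactly this
block structure, with SOAs balanced and shuffled within block and
starting postures counterbalanced across participants.

## Generative model

The probability of a right-first response is logistic in the SOA,

$$p(t) = \frac{1}{1 + e^{-\theta t}},
\qquad
\theta_{\mathrm{uncrossed}} = \omega_{\mathrm{int}} + \omega_{\mathrm{ext}},
\qquad
\theta_{\mathrm{crossed}} = \omega_{\mathrm{int}} - \omega_{\mathrm{ext}},$$

so the uncrossed curve is always rising while the crossed curve can be
flat or even inverted when the external weight dominates. Participant
weights in the upright posture are drawn from truncated Gaussians on
$(0, \infty)$ with population means $\mu_{\mathrm{int}},
\mu_{\mathrm{ext}}$ and SDs $\sigma_{\mathrm{int}},
\sigma_{\mathrm{ext}}$. Body posture acts through two population
context multipliers: lying-down weights are
$\delta_{\mathrm{int}}\,\omega_{\mathrm{int}}$ and
$\delta_{\mathrm{ext}}\,\omega_{\mathrm{ext}}$, identical for every
participant. A hypothesis therefore has $6 + 2N$ parameters and
implies four psychometric curves per participant. The likelihood is
binomial at each SOA in the right-/left-first tallies $r_t, l_t$:

$$\log p(d_i \mid \omega_{\mathrm{int}\,i}, \omega_{\mathrm{ext}\,i})
 = \sum_t r_{t\,i}\log p_i(t) + l_{t\,i}\log\bigl(1 - p_i(t)\bigr),$$

with the binomial coefficient omitted — it is constant in the
parameters and cancels from every Metropolis–Hastings ratio.

**Time units.** SOAs are stored in integer milliseconds at the I/O
boundary and converted to seconds inside the model
(`time_unit = 1e-3`). In seconds, realistic slopes are of order 1–15,
which makes a proposal SD of 0.26 a sensible random-walk step; in
milliseconds the same printed step sizes would be absurdly large
relative to plausible slopes. The factor is an explicit argument
everywhere it matters.

**Priors.** Each participant's upright weights carry the
truncated-Gaussian population prior *including its truncation
normalizer* $1/\bigl(1 - \Phi(-\mu/\sigma)\bigr)$. The normalizer is
not optional here: $\sigma$ is itself sampled, so the normalizer's
dependence on $(\mu, \sigma)$ affects the posterior. Population
parameters get flat, strictly positive hyperpriors with generous upper
bounds (100 for means and SDs, 10 for the deltas; configurable in
`hyperprior_spec()`) — effectively flat over the posterior mass, while
keeping the posterior proper. The context parameters are treated as
population parameters like the rest.

## The sampler

`fit_reference_frames()` runs independent random-walk
Metropolis–Hastings chains. On every iteration *all* $6 + 2N$
parameters are perturbed jointly by independent Gaussian steps —
category SDs 0.26 (weights and means), 0.23 (population SDs), 0.02
(context parameters) — and the move is accepted with probability
$\exp(\Delta \log \text{posterior})$. Out-of-support proposals are
rejected through their $-\infty$ posterior rather than reflected or
re-drawn, which preserves detailed balance with the symmetric Gaussian
proposal. Initial values are drawn uniformly from documented ranges
(weights and means in 0.5–20, SDs in 0.1–5, deltas in 0.5–1.5), so
chains start dispersed.

The default budget is 5 chains × 250,000 samples with a 50,000-sample
burn-in. The inner loop is compiled (Rcpp); a pure-R reference loop is
retained behind `run_chain(..., engine = "R")` and the test suite
asserts the two engines produce bit-identical chains from the same
seed, because both consume R's RNG in the same order. Long runs can be
thinned (`thin`) purely to bound memory; the acceptance study keeps
every 10th draw. A desk-scale budget (2 × 40,000, burn-in 8,000) is
available via `reduced_budget_config()`; it gives usable point
estimates but noticeably worse split-chain R-hat on the slow
directions (below).

**Diagnostics and summaries.** Convergence is judged by the standard
split-chain potential scale reduction factor, computed per parameter
after halving each chain, with $\hat R \le 1.02$ across the six
population parameters as the criterion. Intervals are equal-tail 95%
credible intervals from the pooled post-burn-in samples, using linear
interpolation between order statistics (R's default quantile rule,
type 7).

**Mixing.** The slowest directions are $\mu_{\mathrm{ext}}$ and
$\sigma_{\mathrm{ext}}$: a truncated Gaussian with small mean and
large SD fits a set of positive weights almost as well as one with a
larger mean and small SD, creating a ridge the random walk crosses
slowly, especially when lying-down data compress the external weight
(small $\delta_{\mathrm{ext}}$). The full budget resolves this; short
runs may not. Observed acceptance rates at the canonical design are
around 10–12%, somewhat below the 20–35% the step sizes were
originally tuned for — plausibly because the population weight scales
of the simulated data differ from those of the data the steps were
tuned on. We keep the published step sizes rather than re-tuning.

## Behavioural layer

The PCD (proportion-correct difference) score sums the
uncrossed-minus-crossed accuracy difference over the eight signed SOAs,
per participant and body posture; accuracy respects the sign
convention (at negative SOAs the correct response is left-first). The
score is bounded by ±8 and is 0 in expectation for a chance responder.
PCD tables feed a 2×2 mixed ANOVA (body posture within, vision
between). Effect sizes are *generalized* eta-squared — each effect's
sum of squares over itself plus all subject-related error sums of
squares — the appropriate variant for mixed designs. One-sample
t-tests against 0 use Cohen's $d = \bar x / s$. No multiple-comparison
correction is applied, matching the hypothesis-driven analysis it
mirrors; $\alpha$ is 0.05, two-sided, throughout. Figure error bars
use the within-subject correction: subject-mean centring plus the
$\sqrt{C/(C-1)}$ bias factor for $C$ conditions; the condition set is
an argument because panel composition is a plotting choice, not a
model quantity.

## Trial filtering

Two printed exclusion rules, and only those: trials whose response
code is `timeout` (the apparatus times out 3.5 s after the second
vibration; the code, not the latency, is authoritative) and premature
responses with latency strictly below 100 ms — a latency of exactly
100 ms is retained, reading "less than" literally. Filtering is
idempotent and partitions the input; removed trials take no part in
any downstream statistic. There is no outlier rejection and no
participant-level exclusion.

## Synthetic data: what it emulates, and what it does not

Real trial-level data for this paradigm are not publicly archived, so
`simulate_experiment()` generates experiments with exactly the
statistical structure the model assumes: truncated-Gaussian
populations, logistic responses, shared context multipliers, the
canonical block structure. Truncated-normal draws use inverse-CDF
sampling (exact and seed-stable; no rejection loop). Timeout and
premature trials can be injected to exercise the filters; premature
trials respond at chance with latencies below 100 ms, and normal
latencies are uniform in 300–1500 ms — nuisance plumbing, not a
response-time model.

The population means and SDs are not published, so no silent defaults
exist: `truth_config()` requires them, and `truth_preset()` documents
one choice — $\mu_{\mathrm{int}} = 8$, $\mu_{\mathrm{ext}} = 5$,
$\sigma = 2$ (per-second units) — picked so uncrossed accuracy is near
ceiling at ±400 ms and the upright deficit matches the size reported
in full-vision experiments; the presets' context parameters (1.25/0.31
full vision, 1.16/0.16 blindfold) are representative published point
estimates for these conditions.

Because the generator *is* the model, passing recovery tests shows the
estimator is consistent and the pipeline correct — it does not show
the model fits real hands. Real data have lapses, fatigue and learning
across blocks, latency–accuracy dependencies, and possibly
participant-specific posture effects; none are generated (the model
has no such parameters), so model misspecification is untested by
construction.

## Verification strategy

Every layer is checked against something it does not share code with:
the likelihood against direct `dbinom` computation; the prior against
the closed-form truncated-normal density; the sampler against (i) the
known moments of a truncated Gaussian when the likelihood is flat and
(ii) 2-d grid quadrature on a single-participant posterior with the
population level frozen, agreeing within 2%; the mixed ANOVA against a
hand-computed sums-of-squares oracle; the simulator against
closed-form truncated-normal moments and binomial sampling bounds.
Parameter recovery is exercised at two scales: ten replicate
experiments at a short budget checking interval coverage of the
generating deltas, and two full-protocol fits (20 participants,
5 × 250,000 samples, thin 10) checking that the recovered context
parameters land inside the published credible intervals and that all
population R-hats are at most 1.02. The full-protocol fits take about
two minutes each on one CPU with the compiled kernel.

## Known limitations

* The convergence diagnostic is the standard split-chain PSRF, which
  is bounded below by ~1; published R-hat ranges extending below 1
  must come from a different estimator, which we do not attempt to
  reverse-engineer.
* Acceptance rates at the canonical design sit below the 20–35% band
  the published step sizes were said to achieve (see *Mixing*).
* One vision group per fit: the model deliberately has no
  vision-by-posture joint structure.
* No probit/Gumbel links, no lapse parameters, no per-participant
  context multipliers, and no adaptive proposal tuning — the sampler
  reproduces the published estimator, not a better one.
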
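# crosstoj

Analysis toolkit for **crossed-hands tactile temporal-order judgment
(TOJ) experiments**: when the hands are crossed over the body midline,
people become markedly worse at reporting which hand was vibrated
first. The size of this *crossed-hands deficit* is thought to reflect a
weighted integration of two codes for touch location — an **internal**
(anatomical, skin-based) reference frame and an **external** (spatial)
one that points to the *wrong* response when the hands are crossed. The
package is written for psychophysicists who want to simulate such
experiments, score them, and estimate the reference-frame weights with
a hierarchical Bayesian model.

## The model

The probability of a "right hand first" response at signed stimulus
onset asynchrony *t* (negative = left hand first; seconds internally)
is logistic,

```
p(t) = 1 / (1 + exp(-θ t))
θ_uncrossed = ω_int + ω_ext        (frames agree)
θ_crossed   = ω_int − ω_ext        (frames conflict; may be negative)
```

Each of *N* participants has upright weights (ω_int, ω_ext) drawn from
truncated-Gaussian populations (limits 0, ∞) with means μ_int, μ_ext
and SDs σ_int, σ_ext. Lying on the side rescales every participant's
weights by population **context parameters** δ_int, δ_ext, so one
hypothesis — 6 population parameters plus 2N participant weights —
generates four psychometric curves per participant. The per-participant
likelihood is binomial at each SOA in the right-/left-first tallies;
population parameters carry strictly positive uniform hyperpriors. The
joint posterior is sampled by a random-walk Metropolis–Hastings
algorithm (all parameters perturbed jointly; proposal SDs 0.26 for
weights and means, 0.23 for SDs, 0.02 for context parameters; 5 chains
× 250,000 samples, 50,000 burn-in), with split-chain R-hat as the
convergence diagnostic.

The behavioural layer scores the deficit per participant and posture as
the **PCD** (proportion-correct difference): the uncrossed-minus-crossed
accuracy difference summed over the eight SOAs (±50, ±100, ±200,
±400 ms), analysed with a 2×2 mixed ANOVA (body posture within, vision
between; generalized eta-squared), one-sample t-tests with Cohen's *d*,
and within-subject-corrected error bars.

## Worked example

Simulate a 20-participant full-vision experiment from the documented
preset (μ_int = 8, μ_ext = 5, σ = 2, δ_int = 1.25, δ_ext = 0.31),
filter, score and fit:

```r
library(crosstoj)
sim    <- simulate_experiment(truth_preset("full_vision"), seed = 42)
counts <- aggregate_counts(filter_trials(sim$trials)$trials)

scores <- pcd_scores(counts)
aggregate(pcd ~ body_posture, scores, mean)
#>   body_posture       pcd
#> 1         side 0.4208333
#> 2      upright 1.6791667

tt <- one_sample_t(scores$pcd[scores$body_posture == "upright"])
#> upright PCD vs 0: t(19) = 6.87, p = 1.5e-06, d = 1.54

fit <- fit_reference_frames(counts,
                            config = sampler_config(thin = 10, seed = 42))
print(fit)
#> Hierarchical reference-frame model fit
#>   participants: 20  chains: 5  samples/chain: 250000 (burn-in 50000)
#>   acceptance rates: 10.2%, 10.4%, 10.4%, 10.4%, 10.2%
#>   max split-chain R-hat (population): 1.018
#>
#> Population posterior means [95% equal-tail CI]:
#>   mu_internal      8.675  [7.701, 9.714]
#>   mu_external      4.142  [0.597, 6.257]
#>   sigma_internal   1.965  [1.325, 2.920]
#>   sigma_external   3.700  [2.117, 6.521]
#>   delta_internal   1.270  [1.179, 1.365]
#>   delta_external   0.299  [0.217, 0.384]
```

The upright session shows a large deficit (mean PCD 1.68, *d* = 1.54)
that shrinks when lying down (0.42); the fit recovers the generating
context parameters — the external weight is cut to about a third when
lying on the side (δ_ext ≈ 0.30) while the internal weight grows
slightly (δ_int ≈ 1.27). `summary(fit)`, `coef(fit)` and `plot(fit)`
expose the posterior table, point estimates and trace plots.

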
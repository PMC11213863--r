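# avddm

Hierarchical drift-diffusion modelling of multisensory (audiovisual versus
unisensory) perceptual decision-making across the adult lifespan.

`avddm` is for researchers who study how ageing changes speeded
two-alternative decisions when evidence arrives through one sense or two.
It takes tidy per-trial behavioural tables (participant, age, sensory
condition V/A/AV, stimulus coherence HC/LC, RT in ms, correctness) and
carries them through a complete, testable pipeline:

1. **Synthetic data** — a generator that reproduces the balanced
   three-condition design (3 blocks x 72 trials, 3,000 ms deadline) and an
   age-structured parameter model, so every downstream stage can be
   validated without access to any real dataset.
2. **Preprocessing** — participant exclusion below 50% overall accuracy
   (timeouts count as errors) and per-participant RT filtering outside
   median ± 2.5 raw MADs, timeouts included.
3. **Likelihood** — the exact Wiener first-passage-time joint density
   f(boundary, t | δ, θ, τ, z), evaluated by adaptively truncated
   small-time/large-time series (compiled, vectorised), with accuracy
   coding (upper boundary = correct) and z fixed at 0.5.
4. **Hierarchical Bayesian fitting** — participant-level δ/θ/τ nodes under
   group-level (μ, σ) per conditional-dependency cell (condition x
   coherence x age group, up to 12 cells per parameter), sampled by
   Metropolis-within-Gibbs with conjugate/slice group updates and
   funnel-breaking interweaved moves, for each of the 8 variants (the 2³
   subsets of {δ, θ, τ} allowed to vary).
5. **Diagnostics** — Gelman-Rubin R̂ (pass threshold 1.02), DIC model
   comparison (ΔDIC > 10 = substantial), 90% highest-density regions, and
   posterior predictive checks on signed-RT deciles and accuracy per cell.
6. **Multisensory metrics** — AV−V contrasts, the optimal-combination gap
   δ_AV − √(δ_V² + δ_A²), measures of inverse effectiveness
   (X_LC^MS − X_LC^US) − (X_HC^MS − X_HC^US), and Pearson age
   correlations with 95% CIs.
7. **Power** — minimum N for the fixed-model multiple-regression F test
   (noncentrality λ = f²·N).

See the methods vignette (`vignettes/hierarchical-diffusion-methods.Rmd`)
for the model, priors, sampler design and every documented default.

## Worked example

```r
library(avddm)

required_sample_size(3, f2 = 0.10, alpha = 0.05, power = 0.95)
#> [1] 176

sim <- simulate_dataset(design_spec(), age_generative_model(), 12, seed = 42)
pp  <- preprocess(sim$trials)
print(pp$report)
#> Exclusion report
#>   participants: 12 -> 12
#>   trials:       2592 -> 2205
#>   removed: accuracy criterion 0 | timeouts 5 | MAD outliers 382

post <- fit_hddm(pp$trials, variant = 8, n_chains = 3, n_iter = 1500,
                 burn_in = 300, thin = 2, seed = 42,
                 age_threshold = median(unique(pp$trials$age)))
print(post)
#> Hierarchical diffusion posterior (variant 8 )
#>    3 chains x 600 retained draws ( 1800 pooled )
#>    288 nodes, 12 participants

conv <- convergence_report(post)
cat("max Gelman-Rubin over group nodes:", round(conv$max_rhat, 3), "\n")
#> max Gelman-Rubin over group nodes: 1.06
cat("DIC:", round(dic(post)$dic, 1), "\n")
#> DIC: -1057.8

est <- participant_estimates(post)
g   <- participant_opt_gaps(est)
hc  <- age_correlation(g$HC, g$age)
cat("HC optimal-combination gap vs age: R =", round(hc$r, 2),
    ", p =", signif(hc$p, 2), "\n")
#> HC optimal-combination gap vs age: R = 0.12 , p = 0.72
```

Reading the output: 176 is the a-priori minimum cohort for 95% power at
f² = 0.10 with three predictors. The 12-participant demo cohort loses 5
timeouts and 382 MAD outliers in preprocessing, fits the all-varying
variant with acceptable convergence (R̂ max 1.06 at these short demo
settings), and yields a positive but — at this small n — non-significant
age correlation of the high-coherence multisensory benefit. The package's
validation suite shows the same correlation becoming strongly positive at
cohort sizes of 60 with the default generator (see
`tests/testthat/test-acceptance.R`), mirroring the qualitative pattern the
pipeline is designed to detect. A negative DIC is unremarkable: deviance
is −2·log-likelihood and RT densities routinely exceed 1.

The full pipeline (simulate → preprocess → fit → diagnose → ppc →
metrics, with a MANIFEST of checksummed artifacts) runs via:

```r
run_pipeline(pipeline_config(seed = 5L, n_participants = 8L), "out_dir")
```

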
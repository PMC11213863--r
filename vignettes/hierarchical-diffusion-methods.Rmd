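---
title: "Hierarchical diffusion modelling of multisensory decisions: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical diffusion modelling of multisensory decisions: methods and design choices}
  %\VignetteEncoding{UTF-8}
---

## The scientific problem

Older and younger adults differ in how quickly and how cautiously they turn
sensory evidence into categorical decisions, and in how much they benefit
from having two senses (vision and audition) instead of one. `avddm`
implements a complete analysis pipeline for this question: per-trial
reaction times (RTs) and accuracies from a three-condition object
categorisation task (visual V, auditory A, audiovisual AV; two stimulus
phase-coherence levels HC/LC; two categories, face/car) are preprocessed,
fitted with a hierarchical Bayesian drift-diffusion model (DDM), compared
across model variants, checked predictively, and summarised into
multisensory-benefit statistics correlated with chronological age.

## The decision model

Each trial is modelled as a one-dimensional Wiener diffusion with unit
noise coefficient accumulating evidence between two absorbing boundaries a
distance `theta` apart, starting at the unbiased midpoint (`z = 0.5`), with
drift `delta` (evidence/s) and a non-decision offset `tau` (s) for encoding
and motor latency. Accuracy coding is used throughout: absorption at the
upper boundary is a correct response, at the lower an error. Inter-trial
variabilities of all parameters are fixed at 0, and no lapse/contaminant
mixture is included.

The joint first-passage density of (boundary, time) is evaluated with the
standard dual series: a small-time expansion and a large-time expansion,
each truncated adaptively so the absolute error is below `eps` (default
1e-7 per evaluation), choosing at every point whichever branch needs fewer
terms. The closed-form absorption probability
`P(upper) = (1 - exp(-2 v z a)) / (1 - exp(-2 v a))` is used for choice
probabilities and for boundary draws in the exact simulator. All internal
mathematics is in seconds; trial tables carry RTs in milliseconds and are
converted exactly once, at the likelihood-module boundary.

### Numerical choices

* Density truncation error `eps` applies to the full joint density: the
  standardised-series tolerance is rescaled by the drift/boundary
  multiplier so the guarantee holds on the returned value.
* The exact trial simulator inverts the cumulative first-passage
  distribution on a quadratically spaced grid of 20,000 points of
  normalised time (dense near zero, where the density peaks under strong
  drift); boundary choice uses the closed form. An independent
  Euler–Maruyama simulator (step 1e-4 s) with Brownian-bridge
  within-step crossing correction is provided as a cross-check and is used
  as the oracle in the density-agreement tests.
* The highest-density region (HDR) of a sample is the shortest window
  containing `ceiling(mass * n)` sorted points; ties are broken toward the
  lower start.
* RTs at or below a cell's `tau` make the log-likelihood `-Inf`; the
  sampler never proposes such states because each participant's `tau`
  nodes are bounded above by that participant's minimum retained RT.

## The hierarchy and its sampler

Participant-level `delta`, `theta`, `tau` nodes are drawn from group-level
normal distributions (mean `mu`, spread `sigma`) per
conditional-dependency cell — sensory condition x coherence x age group,
at most 12 cells per parameter family. Eight variants are fitted: the 2^3
subsets of {delta, theta, tau} allowed to vary over cells, from "nothing
varies" (variant 1) to "all vary" (variant 8). Priors are weakly
informative and positivity-respecting: `mu_delta ~ N(0, 5)`,
`mu_theta ~ N(1.5, 2)` truncated positive, `mu_tau ~ N(0.3, 0.3)`
truncated non-negative, and `sigma ~ half-normal(2)`. These are recorded
in the posterior metadata.

Exact Gibbs sampling is impossible for the Wiener likelihood, so the
sampler is Metropolis-within-Gibbs: participant nodes take single-site
normal random-walk proposals against cached per-cell likelihoods, with
proposal scales adapted in log space during burn-in only (batches of 25,
Robbins–Monro step sizes) and frozen afterwards, so detailed balance holds
on all retained draws. Group means are drawn exactly from their conjugate
normal conditionals (truncated by rejection where positivity applies) and
group spreads by stepping-out slice sampling.

Centered hierarchical parameterisations suffer a well-known funnel: when a
group spread approaches zero its members pin to the mean and single-site
updates cannot escape. Two interweaved joint moves fix this: a
*translation* move that shifts a group mean and all its member nodes
together (the hierarchical terms cancel; only the data likelihood and the
mean's prior decide), and a *rescaling* move that multiplies the spread
and all member deviations by a common log-normal factor (the hierarchical
terms cancel against the transformation Jacobian). Both are standard
Metropolis–Hastings kernels on the same joint target. The group-level
block runs twice per sweep; it is cheap relative to the participant sweep
and the spreads of weakly identified cells (for example `theta` in cells
at ceiling accuracy) are the slowest-mixing quantities.

Defaults follow the conventional design: 5 chains of 11,000 iterations,
the first 1,000 discarded as burn-in and the remainder thinned by two,
retaining 25,000 pooled draws. The deviance (-2 log-likelihood) is stored
at every retained draw; DIC is `2 * Dbar - D(theta_bar)` with
`theta_bar` the posterior means of the participant-level nodes, and a DIC
gap above 10 is flagged as substantial evidence. Convergence is judged by
the classic Gelman–Rubin statistic (no rank-normalisation) on retained
draws, with 1.02 as the pass threshold.

The age-group split is a configurable threshold, 60 years by default.
Cohort-dependent analyses in this package's own validation runs use the
sample median instead, which guarantees both groups are populated in any
simulated cohort and splits sizes to within one.

## What the synthetic-data generator emulates

The generator reproduces the design of the motivating experiment — 3
blocks of 72 trials, exactly balanced over 3 conditions x 2 coherences x 2
categories, pseudorandomised within block, 3,000 ms deadline — and an age
structure with the qualitative pattern the analysis is built to detect:

* drift decreasing with age in every cell (defaults around -0.008 to
  -0.012 evidence/s per year on unisensory intercepts of 1.3–2.5);
* boundary increasing with age in A/LC, AV/LC and V/HC (+0.006/yr on
  intercepts of 1.4–1.5);
* non-decision time increasing with age in V/LC only (+1.5 ms/yr on 350 ms);
* AV drift equal to the optimal unisensory combination
  `sqrt(delta_V^2 + delta_A^2)`, plus an age-increasing benefit at high
  coherence only (default 0.02/yr above a reference age of 18).

No quantitative effect sizes exist to copy, so the default slopes and
spreads (0.3/0.15/0.04 for delta/theta/tau) were chosen once as values a
practitioner would call realistic for this class of task: they give
per-cell accuracies mostly in the 0.75–0.99 range, mean RTs of 0.6–1.2 s,
a benefit large enough at the oldest ages (about 1.4 evidence/s) to be
detectable against estimation noise in a 60-participant cohort, and age
trends that remain comfortably clear of the positivity floors. Ages are
drawn uniformly over 18–90 by default.

The generator does *not* emulate several features of real data: lapses
and fast guesses (every simulated RT is a genuine first passage),
condition-order or fatigue effects, within-participant parameter drift,
and any semantic structure of the stimuli. Consequently, passing recovery
tests demonstrates that the estimation machinery works on data satisfying
the model's assumptions — not that real behavioural data satisfy them.

### Preprocessing in validation runs

The preprocessing module implements the full exclusion policy: participants
below 50% overall accuracy (timeouts counted as errors; ties retained;
pooled across conditions by default, per-condition by flag) and, per
participant, timeouts plus RTs outside median ± 2.5 raw MADs (no
1.4826 consistency constant), pooled across conditions by default.
Parameter-recovery validation, however, feeds the fitter simulated trials
after timeout removal only: the MAD rule truncates the tails of perfectly
clean Wiener RT distributions and would bias drift estimates upward, so
applying it there would measure the filter rather than the sampler. On
real data, where the filter targets contaminant RTs the model does not
describe, the full pipeline applies both stages in the stated order.

## Derived multisensory statistics

From per-participant posterior point estimates (posterior means by
default; medians by flag) the package computes, per participant:

* AV − V differences for each parameter, per coherence level and
  collapsed (the mean of the two levels) — both modes are provided because
  per-coherence patterns and collapsed summaries answer different
  questions; per-coherence is the default;
* the optimal-combination gap `delta_AV - sqrt(delta_V^2 + delta_A^2)`
  per coherence, positive values indicating super-optimal multisensory
  accumulation;
* measures of inverse effectiveness
  `(X_LC^MS - X_LC^US) - (X_HC^MS - X_HC^US)`, with the unisensory
  reference cell selected per participant per coherence on point
  estimates: highest drift, lowest boundary, lowest non-decision time.

Cohort-level age associations are Pearson correlations with two-sided
t-test p values and Fisher-z 95% confidence intervals.

The a-priori power utility uses the noncentral-F fixed-model
multiple-regression family with noncentrality `lambda = f2 * N` (the
G*Power "R² deviation from zero" convention; alternative lambda
conventions shift the required N by one or two and are the reason the
convention is documented here).

## Validation problem sizes

The shipped test-suite exercises the pipeline at sizes chosen to make
each check informative while remaining desk-runnable: density
normalisation and simulator agreement on random parameter draws from
`delta in [-5, 5]`, `theta in [0.5, 3]`, `tau in [0.1, 0.6]` with up to
one million trials; group-level drift recovery on 40 participants x 216
trials fitted with 3 chains x 3,000 iterations (500 burn-in, thin 2);
DIC selection recovery on 3 replicate cohorts of 10 participants; and
benefit sign recovery on 60 participants. The same scaled sampler
settings back the reproducibility script in `scripts/`.

## Known limitations

* Point estimates feed the derived statistics; full posterior uncertainty
  is not propagated into the age correlations (matching common practice
  for this analysis style).
* The sampler is serial; chains run one after another.
* The deadline-induced right-censoring of RTs is handled by discarding
  timeouts, not by truncating the likelihood; with the default generator
  the timeout rate is well below 1%, but fits to data with heavy
  censoring would inherit a small drift bias.
* DIC is the only model-comparison criterion implemented, for parity with
  the workflow the package reproduces; it is known to favour complex
  hierarchical models.
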
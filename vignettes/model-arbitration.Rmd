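---
title: "Arbitrating models of perceptual confidence: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Arbitrating models of perceptual confidence: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

confarb implements a complete arbitration workflow for generative models of
perceptual confidence in a three-alternative forced-choice (3AFC) task:
simulate candidate observer models over a stimulus grid, find the stimulus
conditions where their confidence predictions maximally diverge, fit an
internal-noise parameter to trial data, score each model's confidence
predictions by cross entropy, and quantify how reliably the whole pipeline
identifies a known generating model. This vignette explains the models, the
estimators, and the design decisions that were genuinely open, in enough
detail that a reader could re-derive every number the package produces.

## The generative foundation

On each trial three stimuli (e.g. random-dot kinematograms differing in
motion coherence) are shown at once; the observer picks the strongest
(the *type-1* decision) and rates confidence (the *type-2* judgment). The
true stimulus strengths form a 3-vector $c$; the observer only receives a
noisy percept

$$d \sim \mathcal{N}(c,\; \sigma I_3).$$

**A note on units:** `sigma` multiplies the covariance matrix entries, so it
is a per-component *variance*; the percept standard deviation is
`sqrt(sigma)`. This convention is used everywhere — the noise fit, the
synthetic observers' `sigma ~ U(0.5, 5)`, and the search grid — and is
worth keeping in mind when comparing with parameterizations that treat the
noise scalar as a standard deviation.

All four models share this foundation, assume equal prior probability (1/3)
for each stimulus being the strongest, and differ only in how they map $d$
to a choice and a confidence rating:

* **plio** (marginalizing Bayesian ideal observer): posterior over the three
  "stimulus $i$ is strongest" hypotheses, marginalizing the likelihood of
  $d$ over the full 3-D grid of candidate strength triplets partitioned by
  their argmax. Confidence is the posterior probability of the chosen
  option.
* **plh** (hierarchical Bayesian observer): first infers each source
  strength to equal the observed evidence ($c_i^* = d_i$), then evaluates
  the posterior under the three projected sources $[d_1,0,0]$, $[0,d_2,0]$,
  $[0,0,d_3]$. The kernel reduces to
  $p_i \propto \exp(-\sum_{j \ne i} d_j^2 / 2\sigma)$, so its choice tracks
  $\arg\max_i |d_i|$: near the origin a strongly *negative* evidence
  component can win, the one place its choices deviate from the other
  models.
* **aio** (3-point Bayesian ideal observer): axis-aligned sources with a
  single shared scalar strength marginalized over the 1-D grid,
  $p_i \propto \sum_c \mathcal{N}(d; c\,e_i, \sigma I_3)$.
* **rce** (response-congruent evidence, the "max" rule): choice
  $\arg\max_i d_i$, confidence $d_{choice}$ — the raw evidence on the chosen
  axis, ignoring the alternatives.

Under equal priors, equal variances and zero covariance, plio, aio and rce
make identical type-1 choices (the task collapses onto "which component of
$d$ is largest"), which the test suite verifies exactly on shared percept
streams; only their confidence rules differ. That separation — same
accuracy, different confidence — is what makes confidence-based model
arbitration possible at all.

### The marginalization set of the ideal observer

The most consequential ambiguity in specifying the marginalizing observer is
*which* set of candidate sources hypothesis $i$ marginalizes over. Read as a
per-axis scalar marginalization (one strength on axis $i$, zero elsewhere),
the model becomes mathematically identical to the 3-point observer — yet the
two models' predictions demonstrably differ (their pairwise effect sizes at
the selected conditions are around 1, not 0). confarb therefore implements
the region reading: hypothesis $i$ owns the region
$\{c : \arg\max c = i\}$ of the full 3-D grid. Grid triplets whose maximum
is attained by several components sit on region boundaries; by default their
prior mass is shared equally across the tied hypotheses
(`tie_handling = "share"`), which conserves total prior mass and preserves
permutation symmetry. `"exclude"` (drop boundary triplets) and `"all"`
(count them fully under every tied hypothesis, i.e. overlapping weak-
inequality regions) are available as explicit variants; empirically the
shared-mass default reproduces the reference effect-size table best.

### Numerical handling

All densities are evaluated on the log scale. Because the trivariate normal
with diagonal covariance factorizes, the grid marginalization is computed
per percept as a product of three per-axis density tables, shifted by their
row maxima before exponentiation (the shift cancels in the posterior
normalization); this is exact and leaves no room for underflow even at the
largest grid strengths and smallest noise levels. Type-1 ties — impossible
for continuous percepts but reachable in degenerate tests — are broken
uniformly at random from the seeded stream.

## Grid simulation and confidence normalization

`simulate_grid()` simulates every triplet of the default grid (strengths 0
to 5 in steps of 0.5, i.e. $11^3 = 1331$ points; 10,000 trials per point by
default). Within a run all models see the *same* percepts at each point, so
model differences are purely decisional; this common-random-numbers choice
(exposed, default on) reduces Monte-Carlo variance in every between-model
contrast and makes the type-1 agreement property exact rather than
statistical. Whether the original analyses shared percept streams across
models is not documented anywhere we could check; it affects only the
variance, not the expectation, of between-model comparisons.

Because three models emit posterior probabilities in $[1/3, 1]$ while the
max rule emits strength units, confidence is z-scored *within model* before
any comparison. Two scopes exist and are used in different stages:
pooling over the whole grid (condition selection) and pooling over just the
three design conditions (fitting and recovery, matching what can be done
with real subjects who only ever see those conditions). Only sufficient
statistics (choice counts, confidence sums and squares, overall and per
choice) are stored per point unless trial retention is requested, so the
full-grid run fits comfortably in memory.

## Selecting utility-maximizing conditions

At every grid point and for each of the 6 model pairs, `cohens_d_map()`
computes the pooled-SD Cohen's d between the two models' z-scored confidence
distributions,

$$d = \frac{\mu_B - \mu_A}{\sqrt{(s_A^2 + s_B^2)/2}},$$

with sample variances (the $n-1$ convention; at $10^4$ trials per point the
choice is numerically irrelevant and is fixed purely for reproducibility).
Points are ranked by the summed *absolute* d over the 6 pairs — the sign of
each pair's d is an artifact of pair ordering, so summing signed values
would be meaningless. Because the task is fully symmetric, permuted triplets
are collapsed to one canonical ascending representative, averaging the
summed effect size over the class members (a small variance reduction).
Points whose maximum strength is attained by two or more components are
excluded: they have no unambiguous correct answer for a 3AFC experiment.
The top-ranked survivors on the default grid include the three conditions
used throughout the package's defaults, $[0,0,3.5]$, $[3.5,4.5,5]$ and
$[4,4.5,5]$; note that many high-ranking conditions score similarly, and
which three of them a practitioner takes forward is partly a practical
choice, so exact top-3 identity should not be over-interpreted.
`robustness_check()` verifies that rescaling the covariance (0.5x, 1.5x)
leaves the ranking and the selection unchanged.

`design_from_strengths()` converts the selected strengths into experiment
coherences by the fixed scale 0.16 (chosen so the hardest condition is not
at ceiling). A condition like $[0,0,3.5]$ has two tied non-maximal
coherences, which would make "second-best" undefined for choice
categorization; a tie epsilon of 0.0001 is added to exactly one tied
component, *in coherence space after scaling*, giving $[0, 0.0001, 0.56]$.

## Fitting: noise by type-1 fit, arbitration by type-2 fit

Each subject's internal noise is fitted by minimizing the type-1 cross
entropy $CE_1 = -\sum_x p(x)\log q(x)$ between the empirical distribution
over choice categories (highest / second / lowest coherence chosen, per
condition, conditions weighted by trial counts) and the model's simulated
distribution. The objective is itself a Monte-Carlo estimate, so the search
is a plain grid over $\sigma \in [0.25, 6]$ in steps of 0.05 with a fixed
per-candidate simulation seed: with common random numbers the objective is
deterministic and the argmin reproducible; ties go to the smaller sigma.
Because the cached per-candidate simulations do not depend on the subject,
`build_sigma_cache()` computes them once and every subject is fitted
against the same cache. In the default shared mode one sigma is fitted from
the common argmax choice rule; per-model mode fits each model against its
own rule (only the hierarchical observer's differs, and its noisier
argmax-$|d|$ choices make its fitted sigma run high — visibly so for
hierarchical-generated data at large true sigma).

The arbitration statistic is the type-2 cross entropy: for each condition
$\times$ choice-category cell, the subject's and the model's z-scored
confidence samples are smoothed by a Gaussian KDE, evaluated on a shared
512-point grid spanning the pooled range plus three bandwidths, and
accumulated as $-\sum p \log q$ with the cells weighted by the subject's
empirical cell frequencies. Subject cells with fewer than 2 trials are
skipped and logged. Two estimator details deserve emphasis, because both
were found to silently dominate the model comparison if done otherwise:

* **q enters as a density, not a grid-renormalized distribution.** The
  data side $p$ is normalized to a discrete distribution on the grid, but
  renormalizing $q$ as well would add a $-\log(\text{bin width})$ constant
  that differs between candidate models (the grid span depends on the model
  sample), and that constant can exceed the true divergence differences.
  With $q$ in density units the value approximates the differential cross
  entropy, is directly comparable across models, and can legitimately be
  negative for concentrated densities.
* **one bandwidth per cell, anchored to the data sample.** Scott's rule
  applied per sample smooths a 150-trial subject sample far more than a
  several-thousand-trial model sample; the generating model then looks
  systematically too narrow against its own data and a slightly wider
  competitor wins, destroying consistency. Both sides are therefore
  smoothed at the *data* sample's Scott bandwidth, which is also identical
  across candidate models.

No flooring is applied anywhere: a model density that underflows to zero
where the subject has mass yields $CE_2 = +\infty$, and these infinities are
informative — they drive the observer-exclusion rule in the recovery study,
mirroring how large-noise simulated observers are excluded in practice.

## Model recovery

`run_recovery()` generates synthetic observers from each model (by default
150 trials in each of the three conditions — the behavioral session size —
with true $\sigma \sim U(0.5, 5)$), fits each with the shared-sigma
pipeline, classifies by minimum finite $CE_2$, and tabulates the confusion
matrix. Generation and fitting use different child streams of the master
seed, and every observer's seed is drawn up front, so results are identical
regardless of execution order. Observers for whom *every* model's $CE_2$ is
non-finite (or the minimum is tied within $10^{-9}$) are excluded with a
reason rather than silently dropped; partial infinities simply eliminate
those models from the argmin, which keeps more observers than excluding on
any infinity would.

Synthetic observers pass the model's native confidence (posterior
probability, or evidence magnitude for the max rule) straight into the
within-subject z-scoring; no slider mapping, motor noise, lapses or
confidence criteria are simulated, because none of the candidate models
contains such components. Consequently the recovery study shows that the
*estimator* can tell the models apart on model-faithful data — it does not
show robustness to response processes real humans add on top, and real-data
conclusions should lean on the screening rules (overall accuracy at least
40%, easiest condition best) and on inspecting the per-cell fit, not on
recovery accuracy alone. Reaction times are carried through the trial
schema but never modeled.

In this implementation the hierarchical observer is the hardest to recover
(its confidence distributions sit closest to the 3-point observer's, and
its deviant choice rule biases the shared-sigma fit), and at small noise
levels the hierarchical and 3-point observers become nearly degenerate —
both produce near-certain posteriors, and only their rare-error signatures
separate them — so occasional flips between those two persist even with
generous trial counts.

## Problem sizes

The package defaults mirror the full protocol (10,000 trials per grid
point; sigma search 0.25–6 by 0.05; 150 trials per condition per synthetic
observer). The test suite and the acceptance script run deliberately
reduced versions chosen to keep Monte-Carlo error well inside the tolerance
they assert: 2,000 trials per grid point for the effect-size table
(standard error on a d of 3 is about 0.05), 500 per point for the
covariance-scale robustness rerun, 20 observers per model with
2,000-trial cached candidate simulations for recovery, and 10,000 trials
per condition for parameter recovery at $\sigma \in \{1,2,3,4\}$.

## Known limitations

* Only diagonal, equal-variance covariances are implemented; correlated or
  unequal-variance noise is out of scope, as are unequal priors over
  sources.
* The marginalization prior is flat on the *discrete* grid; it is a sum,
  not a continuous integral, so the posterior depends (weakly) on the grid
  resolution and range.
* $CE_2$ comparisons between wildly different cell sample sizes inherit the
  usual KDE caveats; the estimator choices above remove the leading-order
  biases but not the bandwidth sensitivity itself.
* The condition ranking reports Monte-Carlo point estimates; conditions
  with nearly equal summed effect size can swap ranks between seeds, which
  is why selection robustness is checked by rerunning rather than asserted
  from one run.
* Rank stability under covariance rescaling holds exactly in the
  scaled-strengths sense (multiplying strengths by $\sqrt{s}$ and the
  covariance by $s$ is an affine change that leaves every z-score and every
  effect size invariant), but *not* pointwise at fixed strengths: well
  below unit noise the easy points' confidence distributions become nearly
  degenerate, their pooled SDs collapse, and their effect sizes — and hence
  the top of the ranking — inflate dramatically. `robustness_check()`
  deliberately implements the harder fixed-strengths rerun so this behavior
  is visible rather than hidden.
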
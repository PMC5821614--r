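---
title: "Conformal prediction and gain-cost decisions for iterative screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conformal prediction and gain-cost decisions for iterative screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iterscreen)
```

## The problem

Modern screening automation makes it practical to test a compound library
in rounds: screen a random slice first, learn from it, then decide what —
if anything — to screen next. Classical virtual-screening metrics
(enrichment, early recognition) do not answer the operative questions of
that second round: *how many* compounds should be tested, and is testing
them worth the assay cost at all?

`iterscreen` answers both with two ingredients:

1. a **conformal classifier** whose error rate is controlled by a
   user-chosen significance level, so "screen the predicted actives at 80%
   confidence" is a well-defined, tunable policy; and
2. a **gain-cost function** that converts any candidate policy into a
   single expected-profit number, estimated entirely from the first-round
   data.

## The conformal model

The underlying classifier is a 500-tree random forest. For a compound
\(x\) and class \(c \in \{\text{active}, \text{inactive}\}\) the
*conformity score* \(s_c(x)\) is the fraction of trees voting for \(c\).
A held-out calibration set supplies reference distributions: for each
class, the sorted list of the scores \(s_c\) of calibration compounds
whose true class is \(c\) (label-conditional, or *Mondrian*,
calibration). The conformal p-value of a new compound for class \(c\) is

\[
p_c(x) = \frac{\#\{\,i : s_c^{(i)} < s_c(x)\,\}}{n_c + 1},
\]

the fraction of the augmented calibration list lying strictly below the
new score. Class \(c\) enters the prediction set iff
\(p_c(x) \ge \varepsilon\), so a compound can be predicted *active*,
*inactive*, *both*, or *empty*. Under exchangeability the per-class error
rate is at most \(\varepsilon\); per-class (rather than pooled)
calibration is what keeps that guarantee meaningful for the tiny active
class of a primary screen.

Design choices worth knowing:

* **Tie handling.** "Strictly below" means tied calibration scores do not
  raise the p-value. This is the conservative reading; a
  `smoothed = TRUE` option counts half of each tie, which restores exact
  validity but is off by default. Ties are common because vote fractions
  live on a grid of width 1/`n_trees`.
* **Denominator \(n_c + 1\).** The new compound joins the list before
  the fraction is taken: eight of nine calibration scores below a new
  score gives \(8/10 = 0.80\), not \(8/9\).
* **70/30 split.** `floor(0.7 n)` compounds grow the forest, the
  remainder calibrate, so calibration is non-empty for \(n \ge 2\).
* **Aggregation.** The aggregated predictor (`acp()`) repeats the ICP
  over `n_iterations` fresh 70/30 splits (default 100) and takes
  per-class median p-values; the even-count median is the mean of the two
  central order statistics. Per-iteration seeds are `seed + b`, so
  iterations are individually reproducible and their order is irrelevant.
  Aggregation trades the exact finite-sample guarantee for stability; the
  validity tests below measure how closely the aggregate still tracks the
  confidence level.
* **Internal validation.** Each iteration leaves out 20% of the training
  compounds, fits on the rest and scores only the left-out 20%; a
  compound's p-values aggregate only iterations in which it was left out,
  so they are out-of-sample. A compound never left out keeps `NA`
  p-values and is excluded from metrics instead of being imputed. An
  iteration whose leave-out draw strands a class (fewer than two
  compounds left) is resampled wholesale with a shifted seed.

## The gain-cost function and the decision

Screening one compound costs `screen_cost` (defaults scanned over 6, 10
and 14 arbitrary units, representing cheap biochemical to costly
phenotypic assays); an identified hit earns `hit_gain` (default 400, a
level at which an unselected full screen is roughly breakeven). The total
gain of a campaign is the sum over both rounds of hits times gain minus
compounds times cost — linear, hence additive over disjoint screened
sets.

`iterative_screen()` estimates, for each significance level in the grid
(defaults 0.1–0.4, i.e. confidence 90–60%), the gain of screening the
compounds predicted *single-label active*, by scaling the
internal-validation selection and hit fractions proportionally to the
unscreened remainder. Proportional scaling is the assumption-free choice
— with a random initial screen the remainder is exchangeable with the
training data, so per-compound rates carry over in expectation. Two
baselines complete the scan: screening everything (hits projected from
the training hit rate) and screening nothing (gain 0). The decision is
the argmax of estimated test-side gain; training-round costs are sunk at
decision time, though reported totals include them. If no alternative
beats zero, the recommendation is to stop. Ties go to the
higher-confidence level, then to fewer screened compounds. When the cost
of the initial screen exceeds five times the estimated subset gain the
decision carries a low-expected-gain warning: empirically such campaigns
rarely end in overall profit.

## The synthetic-library generator

Benchmarking the workflow needs libraries whose truth is known.
`simulate_library()` draws features i.i.d. per compound — standard
normals (descriptor-like) or sparse Bernoulli bits at density 0.02
(fingerprint-like) — and assigns labels through a logistic model on the
first `n_informative` features with weight `effect_size`, the intercept
solved numerically so the marginal hit rate is exactly the requested
value. Rows are exchangeable by construction, which is precisely the
regime in which conformal validity is guaranteed, and label noise can be
added to blunt separability.

What the generator does *not* emulate: chemical structure (scaffold
clustering, activity cliffs, assay artefacts) and the resulting
non-exchangeable neighbourhood correlations of real libraries. Passing
validity tests on synthetic data therefore demonstrates the machinery is
correct under the model's own assumptions, not that any particular real
screen satisfies them — with real data the random initial draw is what
makes exchangeability plausible.

The test-suite benchmark conditions mirror public primary-screen
statistics: hit rates from 0.4% to 12.5%, feature width 32 with 16
informative features, and `effect_size = 1.5`, which lands the fitted
models in the performance regime typical of well-behaved screening
models (validity near 0.8 at 80% confidence, efficiency 0.6–0.9).
Library sizes are scaled down from the hundreds of thousands to
6,000–20,000 compounds, chosen as `max(6000, 80 / hit_rate)` so that
even the rarest-hit libraries retain ~16 or more actives in the 20%
training screen; below that the internal hit-fraction estimate
degenerates and no decision procedure is informative. The
decision-recovery study uses 40 ACP iterations and the transfer study
25, both downscaled from the default 100 for the same reason the
libraries are: the procedure's behaviour, not its production scale, is
what the tests certify.

## Worked example

```{r example, eval = FALSE}
lib <- simulate_library(library_spec(
  n_compounds = 6000, hit_rate = 0.025, n_features = 32,
  n_informative = 16, effect_size = 1.5, seed = 112
))
run <- iterative_screen(lib, n_iterations = 15, screen_cost = c(6, 10, 14),
                        seed = 212)
print(run)
summary(run)   # validity/efficiency per level, internal vs test
plot(run)      # estimated vs realized gain across confidence levels
```

The printed decision reports, per cost level, the chosen policy, its
estimated and realized gains, and the best gain any scanned policy could
have achieved on the remainder (the oracle); `regret_report()` expresses
the shortfall as a percentage of the oracle's total gain, falling back to
an absolute difference (flagged) when that total is non-positive, where a
percentage would be meaningless.

## Featurisation

For real libraries, `compute_descriptors()` turns SMILES into a 97-wide
physicochemical/constitutional descriptor matrix (OpenBabel properties
plus graph descriptors computed in-package; the list is configurable and
any subset/reordering of `default_descriptors()` is accepted), and
`morgan_fingerprints()` produces circular-fingerprint identifiers
(radius 2 by default) folded onto 4096 bits by modulo hashing —
`hash_fingerprint_indices()` is exposed separately and is a pure function
of the raw index multiset. Unparsable SMILES are dropped and reported,
never zero-imputed: a silently corrupted feature row would poison the
calibration lists, which is worse than a missing compound.
Structure standardisation is deliberately a pass-through hook
(`standardize_smiles()`): standardisation pipelines are
organisation-specific and belong upstream.

## Numerical and degenerate-input choices

* All randomness flows from one integer seed with a documented
  derivation (`seed + iteration`, retries shifted by a fixed step); any
  result is bit-reproducible from its seed, and package functions restore
  the caller's RNG state.
* A class absent from a proper-training or calibration part raises an
  error immediately in `fit_icp()`; aggregate procedures resample the
  iteration rather than propagating a half-calibrated model.
* An initial screen with fewer than two compounds of a class aborts with
  guidance (enlarge the library/fraction, or accept a stratified draw via
  `stratified = TRUE`, which breaks the exchangeability argument and is
  flagged as such).
* Empty calibration lists, empty significance grids, p-values outside
  \[0, 1\], and hit counts exceeding screened counts are all rejected
  loudly.

## Limitations

* Two rounds only; multi-round policies, per-compound costs and budget
  constraints are out of scope.
* Binary activity; no regression or multi-class conformal variants.
* The gain estimate inherits the noise of the internal-validation hit
  counts: with very few training actives (rare-hit libraries screened at
  20%) the decision can pick a neighbouring significance level or stop
  early/late; the low-expected-gain warning exists precisely for that
  regime.
* Median aggregation has no exact finite-sample validity proof; its
  tracking of the confidence level is established empirically in the test
  suite.
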
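---
title: "Methods: magpie-swarm binary wrapper feature selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: magpie-swarm binary wrapper feature selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rbmofs)
```

## The model

`rbmofs` treats feature selection as minimization of a wrapper objective
over binary masks `b ∈ {0,1}^D`:

> fitness(b) = α · (1 − acc(b)) + (1 − α) · |b| / D

where `acc(b)` is the accuracy of a k-nearest-neighbour classifier trained
on a stratified 75% split and evaluated on the remaining 25%, using only
the features in `b`, and `|b|` is the subset size. Lower is better. The
search itself runs in the continuous unit box: a swarm of `N` agents moves
under the RBMO/IRBMO update rules, and every evaluated position is
binarized before scoring.

Assumptions worth stating explicitly:

* features are numeric (categorical columns must be encoded upstream);
* every class has at least two samples, so a stratified split exists;
* the hold-out accuracy is an unbiased estimate for a *fixed* mask, but
  the optimizer maximizes it over thousands of masks — the selected
  subset's reported accuracy is therefore optimistically biased, and the
  winning mask can include features that only help on that particular
  split (see *Limitations*).

## The optimizers

**RBMO.** Each iteration, each agent takes a foraging step
`X_i + rand·(mean(group) − X_rs)` — the group is a small party of 2–5
agents with probability `p = 0.5`, otherwise a large cluster of 10–N —
followed by a prey step anchored at the incumbent best,
`X_food + CF·rand·(mean(group) − X_rs)`, with the step-size schedule
`CF = (1 − t/T)^(2t/T)` decaying from 1 to 0. Group members are drawn
without replacement; the reference agent `X_rs` is drawn from the whole
population and may coincide with a group member.

**IRBMO** replaces those behaviors with: an elite search (with probability
`S = 0.5` a move from the best along `X_eq − X_R1`, where `X_eq` is the
mean of the top three agents; otherwise Brownian exploration around a
random member of the elite pool — the top three plus their mean), a
collaborative hunt (a Cauchy-scaled contraction toward the best, or a
Lévy-flight step away from it), greedy memory storage, and a
food-abundance compensation step with a second greedy acceptance.

**Greedy selection.** A candidate replaces the agent's position only when
its fitness is strictly lower; exact ties keep the incumbent. This makes
the best-so-far curve monotone non-increasing by construction — a property
the test suite checks over random quadratic objectives for both variants.

### Design choices where the behavioral narrative is open

Several scalars of the update rules have no canonical definition; the
package fixes them once and exposes none of them as tuning knobs:

* branch probabilities `S` and `p`: 0.5 (unbiased branch choice);
* food abundance `A = 1 − t/T`, so elite-led exploration dominates early
  and reserve recombination late;
* perturbation scalar `E ~ N(0,1)` and moderator `L ~ U(0,1)`, redrawn per
  update; Brownian factor `rb ~ N(0,1)` per dimension; Cauchy factor
  `cv` a standard Cauchy scalar per update (a scalar keeps the contraction
  direction of the hunt coherent);
* Lévy steps via Mantegna's construction with stability exponent
  `β = 1.5` (`σ_u ≈ 0.6966`), one scalar step scaling the whole vector;
* out-of-bounds coordinates are clamped to the violated bound;
* the loop runs exactly `T` iterations after the initial evaluation.

One ordering question deserves a note. The storage (greedy) behavior is
listed once per iteration in the usual RBMO presentations, but the prey
step starts from the incumbent best rather than from the agent, so a
search-phase candidate would be silently discarded if selection ran only
at the end. RBMO here therefore applies greedy acceptance after *each* of
the two phases (two evaluations per agent-iteration). IRBMO chains elite
search into the hunt and accepts greedily after the hunt and again after
the compensation step — also two evaluations per agent-iteration.

## Binarization

Three families are supported, chosen by the `transfer` argument of
`select_features()`:

* **threshold** (default): `b_j = 1 ⇔ x_j > 0.5`; the boundary value 0.5
  maps to 0. Deterministic, re-derived from the continuous position at
  every evaluation.
* **S-shaped** `s1..s4`: the transfer value is the probability of
  *setting* the bit, redrawn per evaluation.
* **V-shaped** `v1..v4`: the transfer value is the probability of
  *flipping* the agent's current bit, so each agent keeps a persistent
  mask across evaluations (seeded from the threshold rule at its first
  evaluation, updated at every subsequent one). `v2` (the erf form) is the
  recommended preset among the eight variants.

In exact arithmetic every V-value lies in `[0, 1)`; in double precision
`|erf|` saturates to 1 for arguments beyond about 6, which is harmless for
the flip semantics.

An empty mask is never scored: the default *penalty* policy assigns it
fitness 1 (the worst possible value), keeping the search space untouched;
the alternative *repair* policy sets one uniformly chosen bit first.

## The wrapper classifier

KNN with `k = 5` (configurable), Euclidean distance over the selected
features, min–max scaled to `[0, 1]` using training-set ranges only — the
scaler never sees test rows, and a constant training column scales to 0.
Two deterministic tie rules remove any platform dependence: equal
distances are broken by the lower training-row index, and a tied vote goes
to the tied class with the smallest aggregate neighbour distance. The test
suite checks the implementation against a naive double-loop oracle on
random problems.

Fitness values are memoized per run keyed on the mask, since a converging
swarm re-evaluates the same masks many times; the cache is exact and does
not alter the random-number stream (binarization draws happen before the
lookup).

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `pop_size` | 30 | swarm size `N` (≥ 4; the elite pool needs top-3 plus one) |
| `max_iter` | 100 | iteration budget `T` |
| `alpha` | 0.99 | weight on classification error vs subset-size ratio |
| `k` | 5 | KNN neighbours |
| `train_fraction` | 0.75 | stratified split, largest-remainder allocation |
| `transfer` | threshold | binarization rule |
| `seed` | — | one integer reproduces the entire run |

The 30-agent × 100-iteration × 30-run protocol is the standard evaluation
setting of this literature; `run_experiment()` uses it by default and
derives run `r`'s seed as `seed + r − 1`, redrawing the stratified split
each run (which is what run-to-run standard deviations refer to).

## Multi-run evaluation and comparison

Per run the package records fitness, accuracy, sensitivity, specificity,
F-score and subset size; binary problems report the minority class as
positive (configurable), multi-class problems macro-average the
one-vs-rest metrics, and any 0/0 rate is an undefined marker excluded from
averages. Aggregation uses the sample (n−1) standard deviation and reports
the average subset size both as a raw count and as a fraction of `D`.

Algorithms are compared with a two-sided Wilcoxon rank-sum test at the 5%
level — exact enumeration for tie-free samples with combined size ≤ 12,
normal approximation with tie correction otherwise, and a degenerate `NaN`
marker when all values coincide — with per-problem win/tie/loss decided by
mean direction when the test is significant. Friedman mean ranks (mid-rank
ties) give the overall ordering; the chi-square statistic is reported but
the rank table is the headline. Improvement over a baseline is
`100·(baseline − improved)/baseline` per problem, averaged across
problems.

## The synthetic generator

`generate_synthetic()` plants known structure: informative columns are
class-conditional Gaussians with unit variance and means `class_sep`
apart; redundant columns are random linear combinations of the informative
block plus `N(0, 0.1²)` noise; noise columns are standard Gaussians
independent of the label; labels are balanced between two classes and
optionally flipped with probability `label_noise`. The returned object
records which columns are informative, so recovery can be scored exactly.

What it emulates: the low-to-moderate-dimensional, mostly numeric,
moderately separable tabular problems of the UCI/KEEL medical benchmarks.
What it does not: categorical attributes, missing-data patterns,
class imbalance beyond the residual ±1 of balancing, multi-class
structure, or correlated noise. Passing the recovery tests therefore shows
that the machinery optimizes its stated objective and separates planted
signal from noise under clean conditions — not that it will match any
particular published accuracy on real data.

## Study sizes used by the test suite

The package's own checks run at deliberately modest sizes chosen to
exercise the claims: the update-rule collapse suite is exact arithmetic;
monotonicity runs 100 random quadratics (`D ≤ 10`, 10 agents, 50
iterations); the recovery study uses one 300 × 20 dataset (5 informative,
15 noise, `class_sep = 2`) with 10 IRBMO runs at the full 30 × 100
protocol; the variant comparison uses three synthetic datasets of varying
size and separation (300 × 20 at `class_sep` 2, 200 × 20 at 1.5 with 4
redundant columns, 400 × 30 at 1) with 10 runs per optimizer; the Wilcoxon
implementation is checked against exhaustive permutation enumeration over
200 random small-sample cases.

## Limitations

* **Hold-out wrapper bias.** Because fitness is accuracy on a single
  75/25 split, the optimizer can and does exploit noise columns whose
  sample correlation with the labels is nonzero on that split. On the
  300-sample recovery benchmark, bit-flip local optima of the objective
  itself contain several noise features: occasional noise selection is a
  property of the objective, not a search failure. Cross-validated fitness
  would reduce this at a proportional cost in evaluations; the package
  keeps the single-split convention of the literature it implements.
* The reported accuracy of the selected subset is optimistically biased
  for the same reason; honest generalization estimates need a further
  untouched test set.
* KNN is the only wrapper classifier; filter and embedded methods, and
  competitor metaheuristics, are out of scope.
* Runtime scales as `2·N·T` classifier evaluations per run (mask caching
  typically cuts the effective cost severalfold as the swarm converges).
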
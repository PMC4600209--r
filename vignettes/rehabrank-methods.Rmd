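---
title: "Ranking home-care assessment items: models, design choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking home-care assessment items: models, design choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the statistical machinery inside `rehabrank`, the
parameters that matter, the choices made where the design was genuinely
open, and what the synthetic-data tests do and do not demonstrate about
real assessment data.

## The screening problem

The input is a client-by-item table: several hundred assessment items per
client, mostly categorical or ordinal (only counts such as falls
frequency, and age, are treated as continuous), plus a binary outcome —
whether the client received physiotherapy or occupational therapy within
6 months of assessment. The question is not prediction per se but
*ranking*: which items carry the most information about subsequent
rehabilitation use, and how does that list compare with the items experts
chose for the intake screening algorithm?

## Frequency matching

The full-assessment population (long-stay clients) differs from the
intake-screening population, so every analysis sample is drawn to match a
target joint distribution over five variables: age band, gender, ADL
impairment, cognitive impairment, and falls. The derivations are fixed
thresholds: gender = 1 if male; ADL = 1 if any of the ten ADL performance
items is ≥ 1; cognition = 1 if the daily-decision-making item is ≥ 1;
falls = 1 if the falls count is ≥ 1. Age bands are closed on the left —
`[0,50)`, `[50,65)`, `[65,75)`, `[75,85)`, `[85,∞)` — which is how the
integer-year band labels (`50–64`, …) read most naturally.

Cell percentages become integer counts by largest-remainder (Hamilton)
apportionment: floor every exact quota `n·pct/100`, then hand the
remaining units to the cells with the largest fractional remainders. Two
properties motivated this choice over rounding alternatives: the total is
preserved exactly, and integer-exact quotas are reproduced exactly (a
0.06 % cell at n = 10,000 yields exactly 6 clients). Within a stratum,
clients are drawn uniformly *without* replacement — repeating a client
inside one sample would distort the likelihood — but the K ensemble
samples are drawn independently of one another, so a client may appear in
several samples. Sampling with replacement inside a short stratum is
available behind an explicit flag and a warning, for sources smaller than
the design calls for.

## The group-lasso path ranker

With dummy-coded categorical items, an item is a *group* of columns, and
the fitted object is the solution path of

$$\max_\beta \; \tfrac{1}{n}\,l(\beta; X, y) \;-\; \lambda \sum_g w_g \lVert \beta_g \rVert_2 ,$$

the grouped penalty forcing all of an item's dummy columns to enter or
leave together. The intercept is never penalized. Group weights default
to `w_g = sqrt(|g|)`, the standard normalization that keeps multi-level
items from being favored merely for having more columns. Items are
ranked by *entry order*: the item whose group first becomes nonzero at
the largest λ ranks 1. No λ is ever selected; the whole path is the
output. Main effects only — with 239 items there are already 28,441
two-way products, which is why interactions are delegated to the forest.

Numerical contract and choices:

* **Coding.** Reference-cell (drop first level) dummy coding; one group
  per item; continuous items are their own singleton groups.
* **Standardization.** Columns are centered and scaled to unit sample SD
  by default. The penalty compares gradient norms across groups, so
  leaving mixed-scale columns unstandardized would silently reweight
  items; constant columns are left unscaled, flagged, and can never
  enter (their null gradient is exactly zero once the intercept is fit).
* **λ grid.** `λ_max = max_g ‖X_g'(y − ȳ)‖₂ / (n w_g)` is computed
  analytically; the default grid is 100 log-spaced points down to
  `1e-3 · λ_max`. Entry order, not coefficient accuracy, is the output,
  so grid density only needs to resolve entry *order*; ambiguous shared
  intervals are bisected (see below).
* **Solver.** Accelerated proximal gradient (FISTA) with backtracking
  line search and gradient-based momentum restart, warm-started along the
  grid, implemented in C++. Convergence at every grid point is declared
  on the KKT residual of the penalized stationarity conditions
  (default 1e-6 on the standardized scale) and independently re-audited
  in the tests; a non-converged point is an error, never a silent result.
* **Entry refinement and ties.** When several groups first appear between
  adjacent grid points, the interval is bisected with warm-started refits
  until entries separate or the width drops below `1e-4 · λ_max`. Groups
  still tied at that floor are ordered by `‖∇_g‖₂ / w_g` at the tie
  point — the quantity whose crossing of λ defines entry. Groups that
  never enter share the averaged worst ranks, so every sample yields a
  complete ranking (which the aggregation arithmetic requires). A
  coefficient-norm threshold of 1e-10 separates "entered" from
  floating-point noise at the entry boundary.
* **Degenerate inputs.** A single-class outcome is an error; an all-zero
  or constant column is flagged and stays at zero along the whole path.

On instances small enough to brute-force, entry order from the default
grid plus bisection is tested to coincide with a 50×-denser grid, the
near-zero-λ end of the path is tested against the unpenalized logistic
MLE, and singleton-group entry order is cross-checked against an
independent lasso implementation.

## The forest ranker

The interaction-sensitive counterpart is permutation variable importance
from a random forest of classification trees: if permuting an item's
values barely changes out-of-bag performance, the item cannot matter
much. Defaults are the classic ones — 500 trees, `⌊√d⌋` candidate items
per split, minimum node size 5, Gini impurity. Categorical items enter
the forest natively as factors, so one assessment item is one variable
and importance is automatically at the same granularity as the path
ranker's groups; permuting an item permutes its whole column jointly.

The importance of item j is the drop in per-tree out-of-bag accuracy,
averaged over trees and over independent permutation repeats. One
implementation choice deserves note: per repeat, a single permutation of
the item's values across the whole sample is drawn and each tree is then
evaluated on its own out-of-bag rows, rather than drawing a separate
within-bag permutation per tree. This costs one prediction pass per
(item, repeat) instead of one per (item, repeat, tree), and the
machinery invariants are unaffected: the identity permutation produces
exactly zero drop, and a constant item has importance exactly zero.
Accuracy was chosen as the performance metric as the classical
permutation-importance definition; with ~20 % outcome prevalence it is
not a subtle metric, but importance *ranks* — the only quantity consumed
downstream — are insensitive to this at the planted effect sizes used.

## Ensemble aggregation

Rather than ranking once on the full source, K frequency-matched samples
of size n are drawn (sample k seeded `master_seed + k`), the ranker runs
on each, and item j is summarized by its mean rank
`r̄(j) = (1/K) Σ_k r(j,k)` together with a dispersion σ(j). The
dispersion is reported as the *standard error of the mean rank*,
`sd({r(j,k)})/√K`: reference tabulations of this design print top-item
dispersions in the 0.0–1.3 range, an order of magnitude below raw
across-sample rank SDs, which identifies them as a mean's dispersion;
since the reading is ambiguous in principle, the raw SD is emitted
alongside. For K = 1 the dispersion is defined as 0.

The full-scale study profile is K = 100 samples of n = 10,000. The
package's default test profile is K = 10 samples of n = 2,000 over a
~40-item battery with 200-tree forests — sizes chosen so the planted
signals are comfortably detectable while a complete two-ranker ensemble
remains a desk-scale computation; both profiles are plain configuration.

Comparing the two rankers mirrors the scatter-plot reading of the
original design: Spearman correlation of the mean-rank vectors, the items
both rankers place at or better than a cutoff (default mean rank ≤ 20 —
"ranked higher than 20" is read as numerically smaller, i.e. better), and
the items only one ranker favors. A planted interaction-only pair is the
designed stress case: its marginal (2×2-table) association is provably
weaker than its joint effect, so the main-effects-only path ranker
systematically places it behind equally strong main effects while the
forest does not — the mechanism by which the two lists diverge on real
data.

Signed directions for the jointly top-ranked items come from one
unpenalized joint logistic fit (for a multi-level item, the sign of its
largest-magnitude level coefficient); coefficients within 2 SE of zero
are flagged unstable, and complete separation falls back to a lightly
penalized refit, flagged as such.

## The rehabilitation-algorithm scorer

The expert screening tree produces a 1–5 priority score. Its
Self-Reliance indicator is fixed by definition — impaired iff C1 = 1 or
any of C2A–C2D (bathing, personal hygiene, dressing lower body,
locomotion) = 1 — and is hard-coded and exhaustively tested (all 32
binary patterns; monotone by construction). The tree itself is
configuration: the exact split sequence of the licensed algorithm is
published only in the instrument manual, so the packaged default
(`ra_tree_synthetic.yaml`) is a clearly labelled synthetic stand-in
assembled from the algorithm's published ingredients — ADL decline at the
root, then stair climbing, IADL difficulty and the Self-Reliance split.
Missing items are errors, never imputed: a screening score must not be
fabricated from incomplete data. The overlap report between data-driven
top items and the algorithm's items runs through an explicit item
crosswalk (packaged: ADL decline, stair climbing), because the two
instruments label equivalent content with different codes.

## The synthetic-cohort generator

The generator exists so that every downstream stage is testable without
confidential data. It emulates, and is tested for: the published joint
distribution of the five matching variables (multinomial cell assignment,
or exact largest-remainder quotas when guaranteed coverage of all 80
strata is needed); consistency between derived flags and the raw items
they summarize (an ADL-impaired client has 1–10 raw ADL items elevated,
the count drawn uniformly — the flags are defined only as any-item
thresholds, so the raw pattern within a flag is unconstrained); and a
Bernoulli outcome with `logit p = intercept + Σ planted main effects +
Σ planted interactions`. The default intercept of −1.4 (~20 % prevalence
under a null signal) is a free design choice — the real prevalence is not
public. The default battery (30 binary, 10 three-level, 2 continuous
items) is a desk-scale stand-in for the full battery. One seed expands
into fixed per-stage substreams (matching block, battery, outcome), so
each stage is individually reproducible.

What the generator does *not* emulate: realistic inter-item correlation
beyond the matching variables, missing-data patterns (missing cells are
validation errors by design), longitudinal repeat assessments, or the
real battery's size. Passing tests therefore demonstrate that the
machinery recovers known signal under the stated conditions — not that
any particular item list from real data is correct.

## Known limitations

* Entry-order ranking resolves ties only down to the bisection floor;
  below it the gradient-norm tie-break is a principled but arbitrary
  choice, and residual ties are averaged.
* Permutation importance is marginal: two items that matter only through
  their interaction both score high, but the importance values do not
  reveal the interaction as the reason.
* The packaged screening tree is synthetic; conclusions about the real
  algorithm's scores require the licensed tree as configuration.
* Frequency matching equalizes the five matching variables only;
  systematic differences between populations on unmatched variables
  remain.
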
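# rehabrank

Many home-care clients who could benefit from physiotherapy or
occupational therapy never receive it. Standardized home-care assessments
collect hundreds of items per client, and intake staff need to know which
of those items actually predict that a client will go on to use
rehabilitation services — and how well that data-driven picture agrees
with the expert-built screening tree used at intake. `rehabrank` is an R
package for exactly this screening problem: ranking a large battery of
mostly categorical assessment items by their predictive value for a binary
service-use outcome, on samples that are frequency-matched to the intake
population.

## What it computes

The analysis has two stages.

**Frequency-matched resampling.** Long-stay clients who receive the full
assessment differ systematically from the broader intake population, so
items are never ranked on the raw database. Instead, stratified samples
are drawn so that the joint distribution of five matching variables — age
band (`<50`, `50–64`, `65–74`, `75–84`, `>84`), gender, ADL impairment
(any of the ten ADL performance items ≥ 1), cognitive impairment
(daily-decision-making skill ≥ 1), and falls (falls count ≥ 1) — equals a
target population table. Percentages are converted to exact integer
counts by largest-remainder apportionment, so a cell holding 0.06 % of the
population contributes exactly 6 clients to a sample of 10,000.

**Ensemble variable ranking.** On each of K matched samples, every
included item j receives a rank r(j, k) from two independent rankers:

* *Group-lasso path ranker.* Penalized logistic regression
  `max_β l(β; X, y) − λ Ω(β)` with the grouped penalty
  `Ω(β) = Σ_g w_g ‖β_g‖₂`, solved along a decreasing λ grid. A
  categorical item's dummy columns form one group, so the item enters or
  leaves the model as a unit; items are ranked by the order in which their
  groups first become nonzero as λ decreases from λ_max (main effects
  only).
* *Forest ranker.* Permutation variable importance from a random forest
  of classification trees: the drop in out-of-bag accuracy when an item's
  values are permuted, aggregated at the item level. Trees model
  interactions automatically, so genuinely interacting items climb this
  ranking even when their marginal effects are weak.

Ranks are aggregated over the K samples into mean ranks
`r̄(j) = (1/K) Σ_k r(j, k)` with their dispersion σ(j), the two rankers
are compared (Spearman correlation, items top-ranked by both, items
top-ranked by only one), signed effect directions are fitted for the
jointly top-ranked items, and the result is set against the expert-derived
Contact Assessment rehabilitation algorithm — a 1–5 decision-tree score
implemented here as a configurable tree with the Self-Reliance indicator
(impaired iff C1 = 1 or any of C2A–C2D = 1) built in.

Because the real client data are confidential, the package ships a
synthetic-cohort generator: matching variables drawn from the packaged
population table, a configurable item battery, and outcomes drawn from a
logistic model with planted main effects and optional pairwise
interactions, so every stage is testable end to end.

## Worked example

```r
library(rehabrank)

tab <- default_stratum_table()          # packaged population distribution
spec <- generator_spec(
  n = 50000,
  planted_effects = list(X01 = 2.0, X02 = -1.5, T01 = 1.5),
  seed = 11)
src <- generate_cohort(spec, tab)

ep <- ensemble_ranks(src, tab, ranker = "path",   K = 10, n = 2000, master_seed = 1)
ef <- ensemble_ranks(src, tab, ranker = "forest", K = 10, n = 2000, master_seed = 1,
                     ranker_args = list(n_trees = 200))
head(ep$summary, 3)
#>   item mean_rank        se        sd
#> 1  T01       1.4 0.1632993 0.5163978
#> 2  X01       1.8 0.2494438 0.7888106
#> 3  X02       2.8 0.1333333 0.4216370

cmp <- compare_rankings(ep$summary, ef$summary, top_threshold = 10)
cmp
#> Rank comparison: Spearman 0.281
#>  3 item(s) top-ranked by both (cutoff 10 ): T01, X01, X02
effect_direction(src, cmp$both_top)
#>   item direction      coef         se stable
#> 1  T01         +  3.011067 0.04093228   TRUE
#> 2  X01         +  1.994998 0.03625437   TRUE
#> 3  X02         - -1.514013 0.03307709   TRUE
```

The three planted items are exactly the ones both rankers place on top:
`T01` and `X01` increase the odds of rehabilitation use (`+`), `X02`
decreases them (`-`), and each mean rank carries its standard error, so a
`1.40 (0.16)` entry reads as "nearly always ranked first or second across
the 10 matched samples". `run_pipeline()` wraps the whole sequence
(generate → match → rank with both rankers → aggregate → compare →
effect directions → overlap with the screening algorithm's items) and
writes every table with a provenance record; a thin command-line wrapper
lives in `inst/scripts/rehabrank.R`.

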
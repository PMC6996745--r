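# motiveprofiles

Why do people eat what they eat? Dispositional questionnaires ask for the
*typical* reasons ("I eat what I eat because of liking, habit, hunger, ...")
and treat eating motives as situation-stable traits. Event-contingent
ecological momentary assessment (EMA) instead captures the motives *in the
moment*, at every logged eating occasion. The two rarely agree perfectly:
people systematically overestimate how much most motives drive their eating
when asked in the abstract.

`motiveprofiles` is an R package for quantifying that trait-state agreement.
It takes a one-shot trait questionnaire (15 motives of The Eating Motivation
Survey, TEMS, rated 1-4) and an EMA event log with the same 15 state ratings
per eating occasion, and compares the resulting motive *profiles* at three
levels: the group (between-person), each motive (between-motive), and each
participant (within-person).

## The similarity model

For a trait profile `x` and a state profile `y` over the k = 15 motives,
four indices decompose the agreement:

- **Overall similarity** — the double-entry intraclass correlation. With
  `m` the grand mean of all 2k values,

  `ICC_de = Σ(xᵢ−m)(yᵢ−m) / ( [Σ(xᵢ−m)² + Σ(yᵢ−m)²] / 2 )`,

  equivalently the Pearson correlation over the doubled pairing
  {(xᵢ,yᵢ)} ∪ {(yᵢ,xᵢ)}. It penalizes shape, scatter and elevation
  disagreement simultaneously; `ICC_de²` is the share of state-profile
  variance explained by the trait profile.
- **Shape** — the Pearson correlation `r(x, y)`: rank-order agreement.
- **Scatter** — `Var_D = var(x) − var(y)`: spread difference.
- **Elevation** — `M_D = mean(x) − mean(y)`: overall level difference
  (positive = trait ratings sit higher).

Per motive, the package runs paired t tests on the per-person
(trait, state-mean) pairs with Cohen's `d_av = mean diff / ((SD_trait +
SD_state)/2)`, trait-state Pearson correlations across participants, and
the conventional descriptive bands (d > 0.8 large, > 0.5 moderate,
> 0.3 small; r ≥ 0.50 high, > 0.30 medium).

A seeded synthetic-cohort generator (`simulate_cohort()`) produces data
with the structure such studies assume — 35 participants, 8 days,
~888 occasions, a trait-over-state elevation bias on 12 of 15 motives,
motive-specific within-person fluctuation — so the whole pipeline is
testable without access to raw study data. `render_matrix()` draws the
person × motive data matrix (trait/state dashes, difference squares,
variance-shaded backgrounds, similarity-index columns) as deterministic
SVG.

## Worked example

```r
library(motiveprofiles)

d <- simulate_cohort(study_config(seed = 1))
d
#> <cohort_dataset: 35 participants, 893 eating events, 15 motives (simulated seed=1)>

a <- analyze_cohort(d)
a
#> <motive_analysis: 35 participants, 893 events>
#>   group similarity: ICC_de = 0.76, shape r = 0.94, Var_D = 0.18, M_D = 0.37
#>   motives rated higher as trait than state: 11 of 15 (alpha = 0.05)

head(a$motives[, c("motive", "mean_diff", "t_stat", "p_value", "cohen_d",
                   "effect_band")], 3)
#>   motive          mean_diff t_stat  p_value   cohen_d effect_band
#> 1 liking              0.534   6.06  7.29e-7     0.907 large
#> 2 habit               0.555   6.09  6.61e-7     1.000 large
#> 3 need_and_hunger     0.471   3.83  5.23e-4     0.823 large

render_matrix(d, file = "matrix.svg")
```

Reading the output: the group trait and state profiles agree well in shape
(r = 0.94) and spread (Var_D = 0.18), but trait ratings sit 0.37 scale
points higher on average (M_D), pulling the omnibus ICC_de down to 0.76;
11 of the 15 motives are individually rated significantly higher as traits,
with large effect sizes for motives such as liking and habit. This is the
pattern the generator is built to emulate.

An end-to-end run (CSV tables, SVG matrix, text report, JSON log) is one
call — `run_pipeline(run_config(sim_config = study_config(seed = 1),
out_dir = "out"))` — or, from a shell, the thin wrapper in `inst/cli/`:

```sh
Rscript inst/cli/motiveprofiles simulate --seed 1 --out out
Rscript inst/cli/motiveprofiles analyze --traits traits.csv --events events.csv --out out
```

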
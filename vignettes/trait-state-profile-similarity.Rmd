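---
title: "Trait-state profile similarity for momentary eating-motive data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trait-state profile similarity for momentary eating-motive data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motiveprofiles)
```

## The measurement problem

A dispositional (trait) questionnaire asks a person once why they
*typically* eat what they eat; an event-contingent EMA protocol asks the
same question at every logged eating occasion (state). Both use the same
instrument here: the 15 single-item motives of The Eating Motivation
Survey, each rated on a 4-point agreement scale. Averaging a participant's
state ratings across all their occasions yields a state profile directly
comparable to their trait profile, and the question becomes: how similar
are the two 15-element vectors?

## The similarity decomposition

For trait profile $x$ and state profile $y$ over $k$ motives, with $m$ the
grand mean of all $2k$ values, the omnibus index is the double-entry
intraclass correlation

$$ICC_{de} = \frac{\sum_i (x_i - m)(y_i - m)}
  {\left[\sum_i (x_i - m)^2 + \sum_i (y_i - m)^2\right] / 2},$$

which equals the Pearson correlation computed over the doubled pairing
$\{(x_i, y_i)\} \cup \{(y_i, x_i)\}$ — the package uses the closed form and
keeps the doubling construction as an independent test oracle (agreement
to $10^{-10}$ is asserted on 1,000 random pairs). The omnibus index is
deliberately harsh: any disagreement in shape (Pearson $r$), scatter
($Var_D$ = trait variance minus state variance over the $k$ motive
values) or elevation ($M_D$ = trait mean minus state mean) lowers it. When
the two profiles have equal mean and equal variance, $ICC_{de}$ coincides
with $r$; a pure elevation shift leaves $r$ at 1 but strictly decreases
$ICC_{de}$. $ICC_{de}^2$ is reported as the percentage of state-profile
variance explained by the trait profile.

The estimator definition deserves a note: the double-entry ICC is named in
the profile-similarity literature more often than it is written out, so
the closed form above is adopted as this package's definition, with the
doubling construction pinned as its oracle. All variances in the package —
inside $Var_D$, in the per-motive state fluctuation, in the between-person
comparisons — use the sample ($n-1$) denominator; published reports of
this kind rarely state the denominator, so consistency was chosen over
guesswork and the convention is asserted in the unit tests.

### Levels of analysis

* **Between-person (group)**: per-motive mean of trait ratings vs
  per-motive mean of the participants' state means. Person means are
  averaged *unweighted*, so a participant logging 40 occasions counts no
  more than one logging 10; the alternative (pooling events) answers a
  different question — "what does the average *occasion* look like" — and
  a fixture-based test documents that the two differ.
* **Between-motive**: for each motive, a paired two-sided $t$ test on the
  per-person (trait, state-mean) pairs, Cohen's $d$, and the
  between-person trait-state Pearson correlation.
* **Within-person**: the four indices per participant, own trait vector
  vs own state-mean vector.

### Cohen's d convention

Several $d$ variants exist for paired designs. The default here is the
averaged-SD convention $d_{av} = \bar{D} / [(SD_{trait} + SD_{state})/2]$,
because it reproduces the arithmetic relationships among the summary
statistics typically reported in this design (a mean difference of ~0.5
scale points against between-person SDs of ~0.3 gives $d$ near 2, which
the change-score standardization $d_z = t/\sqrt{n}$ does not); $d_z$
remains available via `d_method = "z"`. Raw p-values are primary — they
are what this analysis tradition reports — and a Holm-adjusted column is
emitted alongside for users who want family-wise control. Descriptive
bands use strict thresholds for $d$ (> 0.8 large, > 0.5 moderate, > 0.3
small, else negligible) and an inclusive high threshold for $r$
($\ge 0.50$ high, > 0.30 medium, else low).

## The synthetic cohort generator

The raw data of studies in this area are typically not deposited, so the
package ships a generator whose defaults (`study_config()`) emulate the
design the analysis is built for: 35 participants, 8 consecutive EMA days,
a zero-truncated Poisson number of occasions per day with mean 3.2
(expected total $35 \times 8 \times 3.2 = 896$, close to the ~888 such
studies report), and a realistic meal-type mix in which afternoon tea is
rare (~3%) and the other four categories each take roughly a quarter.

Per participant $p$ and motive $m$:

1. latent trait $\lambda_{pm} \sim N(\mu_m, \sigma_b^2)$, with the grand
   means $\mu_m$ declining linearly from 3.5 to 1.3 in catalog order,
   mimicking the strongly ranked average TEMS profile;
2. latent state level
   $\eta_{pm} = (\mu_m - b_m) + c\,(\lambda_{pm} - \mu_m) + \sqrt{1 - c^2}\,\sigma_b Z$,
   a bias-shifted convex mixture that keeps $\mathrm{Var}(\eta) =
   \sigma_b^2$ and makes the population trait-state correlation exactly
   the coupling parameter $c$;
3. reported trait rating = $\lambda_{pm}$ rounded half-up and clamped to
   [1, 4] (how a respondent maps a latent inclination onto a discrete
   scale; clamping produces the floor effects real low-mean motives show);
4. per occasion, state rating = $\eta_{pm} + N(0, \sigma_{w,m}^2)$,
   rounded and clamped the same way.

Defaults, chosen once on substantive grounds: elevation bias $b_m = 0.53$
scale points on 12 motives and 0 on `convenience`, `visual_appeal` and
`social_image` (the motives such studies find unbiased); coupling
$c = 0.5$ (yielding mostly positive, occasionally high per-motive
trait-state correlations); between-person SD $\sigma_b = 0.6$ (typical
4-point-Likert between-person variances of ~0.3-0.5); within-person SD
$\sigma_{w,m}$ of 0.45 for the low-fluctuation motives
(`traditional_eating`, `sociability`, `weight_control`,
`affect_regulation`), 0.85 for the high-fluctuation ones (`health`,
`convenience`, `pleasure`, `natural_concerns`, `visual_appeal`) and 0.7
otherwise, landing the observed per-motive state variances in the
~0.15-0.66 range with the low/high pattern reported for this instrument.
All randomness flows from the single config seed; identical config and
seed give byte-identical datasets.

**What the generator does not emulate** — and hence what passing tests do
not establish about real data: no circadian or weekday structure, no
autocorrelation between consecutive occasions, no missing or skipped
logs, no response styles (acquiescence, extreme responding), and
conditional independence of motives given the latent levels (real motive
ratings co-vary within an occasion). Parameter-recovery results below
therefore validate the *pipeline arithmetic*, not the behavioral model.

### A discretization caveat, and how the test is calibrated

Rounding and clamping are nonlinear: near the scale floor, adding
within-occasion noise before discretizing *raises* the expected observed
rating (mass below 1 is clamped up), and near the ceiling it lowers it.
With zero configured bias, low-mean motives therefore show a small
spurious negative trait-minus-state difference and high-mean motives a
small positive one — an instrument artifact of bounded discrete scales,
not a property of the paired test. The type-I-error calibration is
consequently run at mid-scale (all $\mu_m = 2.5$, zero bias), where the
discrete mapping is symmetric around the truth; 2,010 simulated null
motives put the empirical rejection rate of the nominal 5% test within
[0.035, 0.065]. The boundary artifact also shrinks the *recovered* grand
elevation bias below the configured average (about 0.34 recovered vs
0.424 configured over 40 seeds), which the recovery tests account for by
testing against a ±0.12 band rather than exact equality.

Monte-Carlo problem sizes used by the test suite — 40 seeds for
parameter recovery, 134 cohorts (2,010 motives) for calibration, 1,000
random pairs for the oracle equivalence — were chosen so binomial/MC
standard errors are small relative to the tested bands.

## The person × motive matrix

`render_matrix()` draws one row per participant (after a group "average"
row) and 21 columns: a profile sparkline, the 15-motive average, the 15
motive data boxes, and the four similarity indices. Within a data box the
trait (blue) and state (orange) dashes sit at $(v-1)/3$ of the cell
height; the colored difference square has *area* proportional to
|trait − state| (area, not side, so perceived magnitude tracks the
difference honestly); its color family marks the dominant assessment
(blue = trait higher, orange = state higher) and its depth the motive's
pronouncedness (midpoint mapped from [1, 4] to [0.25, 1]); the background
gray encodes the within-person state variance relative to 2.25 — the
theoretical maximum variance of a bounded 1-4 variable, $((4-1)^2/4)$ —
so renderings are comparable across cohorts. Index columns are shaded
light (similar) to dark (dissimilar): correlation-type indices via
$(v+1)/2$, elevation via $1 - |v|/3$, scatter via $1 - |v|/2.25$.
Undefined values render as hatched cells (indices) or white backgrounds
with an annotation (variances). Rows are ordered by descending overall
similarity by default, ties broken by ascending participant id; the SVG
is built as plain text with fixed number formatting, so identical input
produces byte-identical documents.

## Degenerate inputs and numerical choices

* Two constant identical profiles: $ICC_{de}$ undefined → `NA`, never an
  exception, so one flat profile cannot abort a batch analysis. The same
  policy covers constant profiles in $r$, zero-variance paired
  differences in the $t$ test, and undefined state variances for
  single-event participants.
* Fewer than 3 matched participants: means are reported, inferential
  fields are `NA` — the pipeline stays runnable on toy fixtures.
* Ratings are stored as doubles throughout; strict whole-number
  validation applies to raw input files only, since derived profiles
  (state means, group averages) are inherently fractional.
* Rounding to the discrete scale is half-up (`floor(x + 0.5)`), then
  clamping — symmetric around category midpoints, unlike banker's
  rounding, and so the natural model of a respondent's discretization.
* `min_events` defaults to 1: studies of this design report no exclusion
  threshold and no dropout, and a silent stricter default would change
  the effective sample size. Excluded participants are always listed,
  never silently dropped.

## Known limitations

* No confidence intervals or significance test for $ICC_{de}$ itself: the
  appropriate null for a profile-similarity ICC is design-dependent, and
  a bootstrap hook would be the honest extension.
* Whether published within-person indices were computed on rounded or
  full-precision state means is generally unknowable; this package uses
  full precision.
* The event-level data are aggregated to person means before testing;
  multilevel models of occasion-level variation are out of scope.
* The static SVG is a faithful but non-interactive stand-in for
  interactive profile-explorer tools (no sorting or filtering in the
  browser).
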
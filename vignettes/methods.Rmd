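---
title: "Generating and evaluating synthetic longitudinal EHR cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generating and evaluating synthetic longitudinal EHR cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(synthehr)
```

## The problem

Longitudinal clinical data — patients with multiple, irregularly spaced
encounters, each carrying coded diagnoses, categorical descriptors and
continuous measurements — is the substrate of most health-services
research, and also the hardest kind of tabular data to synthesise.
A useful synthetic cohort must preserve the hierarchy (patient → visits →
codes), the sequential structure (disease progressions across visits),
the temporal structure (intervals between visits, admission and discharge
times), mixed variable types, and informative missingness, and it must
come back out of the generator *in the same three-table layout as the
real data*, or it cannot be dropped into existing analysis code.

`synthehr` follows the now-standard token-based recipe: discretise
everything into a vocabulary of binary tokens, train an autoregressive
sequence model over visits, sample new token sequences — and then invert
the discretisation with a dedicated post-processing step that
reconstructs continuous values, calendar timestamps and full-resolution
diagnosis codes. The package also ships the evaluation battery used to
decide whether such a synthetic cohort can stand in for the real one, and
a simulator that produces cohorts with *known* structure so every stage
can be validated without access to restricted clinical data.

## Token representation

A `cohort_schema()` declares static fields (categorical, continuous, or
binary condition labels), visit fields, code systems, the inter-visit gap
variable and the visit cap. `discretize()` maps a cohort onto a flat
vocabulary:

* one token per categorical level, one per continuous band, one per code;
* three special tokens: `<start>`, `<eov>` (end of visit), `<eor>` (end
  of record);
* missing continuous values produce *no* token — absence is the encoding
  of missingness, so the generator can learn informative missingness
  rather than having it imputed away.

Band edges default to per-variable quantile bands (20 by default;
`fit_bands()` computes them on the training split only), which bounds the
probability mass per band without assuming any distributional shape. The
gap variable uses a hybrid grid — one dedicated negative/overlap band for
admissions that start before the previous discharge, daily bands up to 7
days, weekly bands beyond — mirroring the tier boundaries of timestamp
reconstruction so that a gap band never straddles a tier.

Visit capping keeps the *earliest* `max_visits` visits; trajectory onset
is preserved and the rule is deterministic.

Rare diagnosis codes are collapsed before tokenisation:
`aggregate_codes()` replaces every code occurring fewer than `min_count`
times with the longest candidate prefix whose pooled rare-code count
reaches the threshold (shortest candidate as fallback), and records the
empirical distribution of full codes within each collapsed category,
stratified by gender, for later re-expansion.

## The sequence engine

The engine is a small pre-LayerNorm causal transformer written directly
in R matrix operations (the sizes involved make BLAS-backed base R
entirely adequate on one CPU core). One sequence position is one visit: a
multi-hot vector over the vocabulary. The layout is

```
<start> | labels | demographics | visit 1 | ... | visit k | <eor>
```

Condition labels get their own position *before* the demographics, so
demographics are generated conditionally on labels; this is what makes
conditionally generated cohorts demographically plausible (a dementia
cohort comes out old because the model has learned
P(age band | dementia label)).

Training minimises element-wise binary cross-entropy computed from raw
logits (numerically stable at extreme probabilities), with Adam, early
stopping on validation loss (patience 5), and the output bias initialised
at the marginal token log-odds so optimisation is spent on conditional
structure rather than marginal calibration. Desk-scale defaults are 2
layers, 64-dimensional embeddings, 4 heads, batch 64, learning rate 0.01,
at most 20 epochs — minutes on one core for a 2,000-patient cohort with a
vocabulary below 300. All computation is double precision; the
`mixed_precision` flag is accepted for config compatibility only.

Sampling is visit-by-visit. Within a visit, each banded variable is drawn
as a grouped categorical over its band tokens (with "no band" as the
missingness outcome), codes as independent Bernoulli draws, both after
constraint masking. Rules (`constraint_rules()`) are deterministic:
`forbid-token` zeroes a token, `forbid-co-occurrence` masks either side
of a pair once the other side is fully active, `require-if` forces its
consequent once the antecedent is active; a final repair pass iterates
require/forbid to a fixed point and reports contradictory rule sets as
errors. Generation is deterministic given `rng_seed`.

Two consequences of the one-position-per-visit design are worth stating
plainly. Within a visit, tokens are conditionally independent given the
history, so co-occurrence *lifts* that are not explained by patient
history are reproduced only at the product-of-marginals level; bigram R²
stays high because probabilities are dominated by the marginal spread,
but pairwise correlation between two banded variables of the same visit
(e.g. total and treatment length of stay) is attenuated to what the band
pairing plus joint reconstruction can carry. This is visible in the
correlation-difference matrix of the worked example and is the main cost
of the simpler visit-level layout.

## KDE reconstruction

Uniform sampling inside a band aligns formats but not distributions: a
log-normal length of stay resampled uniformly within quantile bands has a
visibly wrong shape. The reconstruction step therefore estimates, per
continuous variable and stratum (gender for statics, event type for visit
variables; strata under 30 observations fall back to pooled data), a
Gaussian-kernel CDF with the normal-reference bandwidth, evaluated
analytically on a grid (mean of normal CDFs — no numerical integration),
and differenced into subinterval masses. `sample_within_band()` then
draws a subinterval proportionally to its mass and a value uniformly
inside it, so every value stays inside its band while the within-band
shape follows the data. Grid resolution defaults to one unit of the
variable (1 year of age, 1 hour of stay, 1 day of gap), capped at 2,000
grid points.

For a correlated pair, the joint CDF (product-Gaussian kernel) is
evaluated on the two grids and converted to cell masses by
inclusion–exclusion; tiny negative numerical residues are clipped to zero
and the cells renormalised. Sampling restricts the cells to the band
rectangle. Degenerate cases are handled explicitly: constant variables
become point masses, zero-mass bands fall back to uniform draws (counted
and flagged), zero-mass rectangles fall back to independent marginal
draws.

Timestamps use two modes. In *weekly* mode (study-style cohorts) a start
week is sampled from a KDE grid stratified by the patient's total visit
count, a day of week from the empirical distribution, and visit `i`'s
week is the start week plus the cumulative gap weeks — making the
inter-visit week gaps of the output *identical* to the generated gap
values, by construction, for every record inside the calendar window
(cumulative weeks beyond the window clamp to its edge and are flagged).
In *admission* mode the first admission comes from the weekly path plus
an empirical start hour, and discharge/next-admission times follow a
three-tier rule on the stay or interval length: up to 24 hours, direct
addition (exact, so discharge − admission ≡ length of stay in tier 1);
1–7 days, whole days (round half up) with the time of day set to a
synthetic end hour; over 7 days, a week/day lookup against the configured
study window. Event-timing features absent from the schema (end hour, end
day of week) are sampled from training empirical tables; the end week is
derived from the admission week plus the stay in whole weeks rather than
sampled, which keeps long stays consistent with their admission dates.
Negative overlap intervals are passed through tier 1 and any resulting
start-order inversions are repaired by a stable sort.

Diagnosis codes collapsed at aggregation time are re-expanded by sampling
the stored per-stratum empirical tables (pooled table for unseen strata);
codes never aggregated pass through unchanged.

## Evaluation battery

* `summary_compare()` — per-variable mean/sd/median/IQR/range, percent
  female, visits per patient, days between visits, unique code counts.
* `correlation_fidelity()` — pairwise Pearson matrices over patient-visit
  rows and their difference.
* `code_frequency_r2()` — squared Pearson correlation of per-code
  relative frequencies (log10 by default; synthetic zeros floored at half
  the smallest nonzero synthetic frequency), plus the fraction of real
  codes retained.
* `bigram_r2()` — within-visit (unordered pair per visit) and sequential
  (ordered pair across consecutive visits) probabilities over the union
  support, compared as `max(0, cor)^2` — identical cohorts give exactly
  1, disjoint vocabularies 0.
* `conditional_occurrence()` — P(outcome code at any strictly later
  visit | index code) versus the never-index population.
* `conditional_cohort_check()` — prevalence triple
  (conditioned/unconditioned/real) and demographic plausibility of
  conditioned cohorts.
* `tstr_evaluate()` — gradient boosting (xgboost; depth 4, 200 trees,
  learning rate 0.1, single thread, fixed seed) trained on real,
  synthetic, and combined data, all evaluated on held-out real patients
  with precision/recall/F1 at threshold 0.5, PR AUC (average precision)
  and ROC AUC (rank statistic). Built-in label extractors cover a static
  condition label, an outcome code at a later visit, and a 30-day
  revisit.
* `attribution_rank_agreement()` — exact tree-path (TreeSHAP)
  attributions, mean absolute per feature, top-10 overlap and Spearman
  rank correlation; the test suite validates the ranking against
  exhaustive Shapley enumeration on a 4-feature model.
* `equal_opportunity()` — max–min true-positive-rate gap across
  subgroups at threshold 0.5 (groups without positives are excluded with
  a warning). The difference convention is used; multi-level groups
  aggregate by max − min.
* `coefficient_comparison()` — the same linear/binomial specification
  (optionally with a random intercept via lme4) fitted to both cohorts;
  paired estimates, 95% Wald intervals, sign agreement, and preservation
  of factor-level ordering.
* `prevalence_curves()` — condition prevalence by gender and age through
  a binned logistic smoother (a binomial GLM on age bins; a deliberate
  simplification of smooth additive models that keeps the fitted
  prevalences transparent).
* `temporal_fidelity()` — daily event counts, sample ACF/PACF to a lag
  bound, and the lag-7 contrast. The expected finding on any cohort with
  weekly utilisation structure: the real lag-7 peak is strong, the
  synthetic one attenuated, because start-week KDE sampling plus
  independent gap tokens wash out aggregate calendar structure even
  though per-record timestamps look right. Synthetic cohorts from this
  pipeline are not suitable for forecasting or seasonality analyses.

## The simulator as ground truth

`sim_config()` defaults define the reference study conditions used
throughout the tests: 2,000–2,500 patients over a 104-week window;
visit counts `1 + Poisson(2)` capped at 10; visit dates from week×day
cells weighted by a Monday-first intensity vector `(2,2,2,2,2,1,1)` and a
seasonal sinusoid of amplitude 0.3; ED/inpatient events 60/40; six
ICD-shaped condition families whose patient-level prevalence depends
logistically on age and gender; filler codes with per-visit prevalences
0.03–0.30 and three within-visit co-occurrence lifts (2–2.5); a
progression rule planting an outcome code after the index code with
probability 0.6 (the index never occurs in a final visit, so the
conditional-occurrence estimator is unbiased for 0.6, and the outcome
code has no other source); total/treatment length of stay as a bivariate
log-normal pair whose Gaussian-copula correlation is solved in closed
form to give Pearson r = 0.7; 2% overlapping episodes (negative
discharge-to-admission gaps); treatment length of stay absent on ED
visits (informative missingness) plus 5% missing at random. These values
were chosen once as a realistic desk-scale analogue of a mixed
emergency/inpatient administrative extract. `truth_check()` re-estimates
each parameter from a simulated cohort with three-standard-error
Monte-Carlo tolerances.

What the simulator does *not* emulate: real ICD semantics (codes are
synthetic identifiers shaped like ICD-10 strings), multi-morbidity
correlation beyond the configured lifts, care pathways spanning
facilities, drifting populations, or coding-practice artefacts. Passing
the battery on simulated data therefore demonstrates that the pipeline's
machinery is correct and calibrated, not that any particular clinical
dataset would be reproduced with the same fidelity.

## Numerical and design choices

* Tier boundaries are closed on the left tier ("up to 24 hours" includes
  exactly 24); integer-day conversion rounds half up.
* The two R² metrics share one convention (squared Pearson correlation,
  clamped at zero for anti-correlated vectors), with a log-scale switch.
* KDE bandwidths use the normal-reference rule per stratum; constant
  strata become point masses.
* Splits use floor-then-largest-remainder allocation, so 10 patients at
  (0.8, 0.1, 0.1) give 8/1/1 deterministically.
* Out-of-range continuous values clamp to the outer band with a counted
  warning; generation never emits more than one band token per variable
  by construction (grouped categorical sampling), and `detokenize`
  treats two active bands as an integrity error.
* Determinism: every stochastic entry point takes a seed; training and
  generation are reproducible under single-threaded BLAS.
* Problem sizes in the shipped tests — 2,500 simulated patients, a
  2-layer/64-dim engine for at most 20 epochs, 10,000-patient constrained
  generation, 20,000-value reconstruction checks — were chosen so the
  whole suite runs on a single CPU core in well under half an hour while
  leaving the Monte-Carlo tolerances meaningful.

## Known limitations

* Within-visit dependence beyond what patient history explains is not
  representable by the visit-level multi-hot design (see above); a
  token-level autoregression within visits would capture it at greater
  model and runtime cost.
* Aggregate temporal patterns (weekly/seasonal intensity of daily
  counts) are intentionally out of reach of the reconstruction step.
* Coefficient comparison reports Wald intervals; no small-sample or
  random-slope support beyond a single random intercept.
* No privacy assessment of any kind is included: nothing here measures or
  limits memorisation or disclosure risk.
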
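---
title: "Methods: the below-knee amputation risk index and its validation analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the below-knee amputation risk index and its validation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bkarisk)
```

## The risk index

`bkarisk` implements an additive point score for patients undergoing
non-traumatic below-knee amputation, intended to stratify one-year
mortality, morbidity and functional-independence risk. Four factor groups
contribute points:

| Factor | 0 points | 1 point | 2 points |
|---|---|---|---|
| Age | < 65 y | 65–79 y | > 79 y |
| Preoperative systemic disease | — | 1 per condition (max 6) | — |
| Postoperative mobilization | early (≤ 24 h) | late (> 24 h) | bedridden |
| Early complications | — | 1 each for hypoxia and metabolic disorder | — |

The comorbidity set is closed: COPD, hypertension, diabetes mellitus,
previous myocardial infarction, previous stroke, and previous lower
extremity infection. Diabetic foot infection and previous extremity
surgery are represented only insofar as they fall under "previous lower
extremity infection"; they are not separate scoring items. The total is
an integer in 0–12, and every integer in that range is attainable
(verified by exhaustive enumeration of all 2,304 input combinations in
the test suite). The score is monotone: worsening any single factor can
never lower it.

Age bands use whole years with half-open boundaries (< 65 → 0, 65–79
inclusive → 1, ≥ 80 → 2); no sub-year resolution is modelled. Functional
status uses the Katz activities-of-daily-living count (0–6 over bathing,
dressing, toileting, transferring, personal care, feeding). Only three
Katz anchors carry standard labels (6 = full independence, 4 = moderate,
≤ 2 = severe impairment); scores 3 and 5 are reported as `intermediate`
rather than being given an invented clinical label.

## Statistical procedures

The three validation procedures are implemented from first principles —
they are the analytical core of the package — and each is tested against
an independent oracle.

**Mann–Whitney U** (`mann_whitney()`). U counts pairwise wins of the
first group (ties half). The exact two-sided p-value is defined over the
permutation distribution of U across all `choose(n1+n2, n1)` labelings
of the pooled sample:

$$p = \Pr\left(\,|U - n_1 n_2/2| \ge |U_{obs} - n_1 n_2/2|\,\right),$$

which handles ties exactly (it conditions on the observed value
multiset). The distribution is computed by a shift/convolution dynamic
programme over doubled midranks rather than literal enumeration, so the
exact test remains feasible at cohort sizes of a few hundred; the test
suite verifies it against brute-force enumeration on small samples with
ties. The asymptotic path uses the normal approximation with the
standard tie-corrected variance

$$\sigma_U^2 = \frac{n_1 n_2}{12}\left((n+1) - \frac{\sum_g (t_g^3 - t_g)}{n(n-1)}\right)$$

and a 0.5 continuity correction, standard practice for small clinical
samples. `method = "auto"` uses the exact test up to `n1 + n2 = 14` and
the approximation beyond; `method = "exact"` may be forced up to
`n1 + n2 = 200`. The signed deviate `z` carries the sign of the first
group's mean-rank advantage and is always reported alongside the
non-negative U, because published follow-up tables for this kind of
index often print the signed z in a column labelled "U" (values such as
−3.85 are only interpretable as z).

**ROC/AUC** (`roc_auc()`). The empirical ROC is swept over all distinct
score thresholds; ties across classes produce diagonal segments, so the
trapezoidal area equals the pair-counting form
(concordant + ½·tied)/(n₊·n₋) and the identity AUC = U₊/(n₊·n₋) links
the ROC to the Mann–Whitney statistic across modules (both identities
are asserted to 1e-12 in the tests; exact bit equality of `auc` and
`1 - auc_complement` is not demanded because quotients like 1/3 and
1 − 2/3 differ in the last binary digit). The orientation of a clinical
score against an outcome can be genuinely ambiguous — a published AUC
near 0.09 for a score claimed to increase with mortality implies an
orientation convention that was never stated — so the direction is an
explicit argument, and results always carry both the requested AUC and
its complement.

**Spearman correlation** (`spearman_cor()`). The coefficient is the
Pearson correlation of midranks. For n ≤ 8 the two-sided p-value is
exact over all n! permutations; beyond that it uses
`t = r sqrt((n-2)/(1-r^2))` on n − 2 degrees of freedom. Interpretation
bands follow the conventional thresholds (negligible < 0.10 ≤ weak
< 0.40 ≤ moderate < 0.70 ≤ strong < 0.90 ≤ very strong); published band
edges touch, so the package uses half-open intervals closed on the left
to make the mapping total and unambiguous — 0.40 is "moderate", 0.70 is
"strong".

## Cohort I/O

Cohorts travel as strict CSV (RFC-4180, header required, columns of
`cohort_columns()`): booleans 0/1, mobilization as literal
`early|late|bedridden`, missing optional cells empty rather than zero.
Validation enforces the record invariants (adult age, closed
vocabularies, `days_to_death` present exactly for deceased patients, the
Katz tuple all-six-or-none) row by row, deterministically and
order-independently; strict mode refuses an invalid file, lenient mode
drops and itemizes bad rows. Round-trip identity (`read(write(c)) == c`)
is property-tested on random simulated cohorts.

## The synthetic-cohort generator

No patient-level data accompany the study this index derives from, so
the simulator is the package's source of analyzable cohorts. Its
generative model is deliberately the simplest structure consistent with
the reported cohort: risk inputs are drawn independently (mobilization
optionally per age band), death within one year is Bernoulli with

$$\mathrm{logit}\,\Pr(\text{death}) = \beta_0 + \beta_1 \cdot \text{score},$$

the day of death is uniform on 0–364, and the 3-month Katz score is a
latent linear response $\kappa_0 - \kappa_1\cdot\text{score} +
\mathcal N(0, \sigma)$ rounded and clamped to 0–6, recorded for every
patient alive at day 90 (the first `k` activities are marked
independent). These links are simulator conventions chosen to produce
the qualitative structure the analysis assumes (score ↑ ⇒ death ↑,
Katz ↓), not claims about any real cohort.

`paper_like_config()` fixes the defaults to the published cohort shape:
n = 30; age a truncated normal with mean 71.7 y and SD 7 y (the study
reports 71.7 ± 1.26 without stating whether the dispersion is an SD or
SEM; 7 y ≈ 1.26·√30 and is a realistic cohort SD, and the dispersion
remains a free parameter); comorbidity prevalences (DM 0.35, HTN 0.25,
limb infection 0.15, COPD 0.08, MI 0.08, stroke 0.06) giving ≈ 2/3 of
patients at least one condition and ≈ 1 mean point; age-band-specific
mobilization probabilities reproducing an ≈ 8/8/14 early/late/bedridden
split; hypoxia and metabolic-disorder probabilities of 0.3 each (≈ half
the cohort with ≥ 1 early complication); β₀ = −2.05, β₁ = 0.55 so that
mortality is ≈ 50% at the ≈ 3.7 mean score; κ₀ = 4.5, κ₁ = 0.9, σ = 1.0
giving severely impaired mean survivor Katz and a strongly negative
score–Katz association; secondary outcome probabilities 10/30, 11/30,
19/30. These values were fixed once from the reported cohort summaries.

All randomness flows from a single root seed through one RNG stream with
per-record draws in a fixed field order, so a config (seed included) is
a complete, bit-reproducible description of a cohort; the caller's RNG
state is saved and restored. What the simulator does **not** emulate:
correlation among comorbidities, age-dependent comorbidity burden,
death-time hazards that depend on the score (death day is uniform),
Katz component patterns other than "first k independent", and any
dependence of the secondary outcomes on the score. Passing tests
therefore demonstrate the correctness and calibration of the software
under this model, not the clinical validity of the index on real
patients.

## The analysis pipeline

`run_full_analysis()` scores the cohort, then:

* compares the total score across the two levels of each of the four
  outcomes (one-year survival, postoperative comorbidity, prosthetic
  usage, wound complications), reporting per-group n, median and
  quartiles plus U, z and p. Quartiles use linear interpolation between
  order statistics — small-n quartiles are convention-sensitive, so the
  report footer names the convention;
* computes the mortality ROC in the stated orientation (both AUCs are
  always printed);
* correlates the score with the 3-month Katz score after excluding
  patients who died before day 90 ("first three months" is
  operationalized as `days_to_death < 90`); patients alive at 3 months
  but lacking Katz data are excluded and counted separately, never
  imputed;
* decomposes the mean score per age band into its four mean components
  (an exact arithmetic identity, asserted in tests) together with
  early-mobilization, mortality and mean-Katz summaries.

Sections whose preconditions fail on a given cohort (a single-level
outcome, too little Katz data) are marked "not computable" instead of
failing the report. p-values are printed to 3 decimals with a "<0.001"
floor. No multiple-testing adjustment is applied across the four
comparisons, and the report says so; no time-to-event modelling is
performed because the outcome is a binary one-year status. Reports are
deterministic at the printed precision: the same cohort yields
byte-identical `report.txt`, `summary.json` and `scored_cohort.csv`.

## Problem sizes used in the test suite

Calibration properties are checked at the sizes where Monte-Carlo error
is informative: generative-model recovery (per-score death rates within
3 Monte-Carlo SEs of the configured logistic curve, null-model AUC
within 3 SEs of 0.5, strong-linkage Spearman ≤ −0.7) at n = 20,000;
type-I error of the assembled pipeline (fraction of exact p ≤ 0.05
under β₁ = 0) over 1,000 replicate 30-patient cohorts; oracle
equivalence of the statistical procedures over ≥ 100 (Mann–Whitney) and
≥ 1,000 (AUC, Spearman) randomized tied datasets.

## Known limitations

* The index weights are fixed by construction; the package deliberately
  offers no refitting or alternative weighting (a non-goal).
* The exact Mann–Whitney p-value is discrete and therefore conservative
  at conventional levels on heavily tied small samples; the type-I
  check accounts for this only through its Monte-Carlo tolerance.
* The simulator's independence assumptions (above) make it a test
  harness, not an epidemiological model; parameter-recovery results do
  not transfer to real cohorts.
* Figures-style plotting of cohort decompositions is out of scope; only
  the ROC object has a `plot()` method.
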
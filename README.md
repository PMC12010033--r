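# bkarisk

An R package for computing and validating an additive risk index for
patients undergoing non-traumatic below-knee amputation, aimed at
biostatisticians and clinical researchers who want a fully tested,
reproducible implementation of the scoring rule and of the nonparametric
analysis used to evaluate it — without access to any patient-level data.

## The index

Each patient receives integer points from four factor groups, summed to a
total score in 0–12:

* **Age band** — < 65 y: 0, 65–79 y: 1, > 79 y: 2.
* **Preoperative systemic disease** — 1 point per condition from the
  closed set {COPD, hypertension, diabetes mellitus, prior myocardial
  infarction, prior stroke, prior lower extremity infection} (0–6).
* **Postoperative mobilization** — early (≤ 24 h): 0, late (> 24 h): 1,
  bedridden: 2.
* **Early complications** — 1 point each for postoperative hypoxia and
  clinically actionable metabolic disorder (0–2).

Functional independence at 3 months is measured by the Katz ADL count
(0–6; 6 = full independence, ≤ 2 = severe impairment).

Validation of the index on a cohort uses three procedures implemented
here from first principles: the Mann–Whitney U test (exact permutation
p over all C(n₁+n₂, n₁) labelings, tie-aware, plus the tie- and
continuity-corrected normal approximation, with U and the signed deviate
z both reported), the empirical ROC with trapezoidal AUC (equal to the
pair-counting probability Pr(score₊ > score₋) + ½·Pr(tie), with an
explicit orientation argument and both AUCs always reported), and the
Spearman rank correlation (Pearson on midranks; exact permutation p for
n ≤ 8, t-approximation beyond) with qualitative interpretation bands
(|r| ≥ 0.70 is "strong").

Because no patient-level data are published for this kind of index, the
package includes a seeded synthetic-cohort simulator (logistic score →
one-year-death model, latent-linear score → Katz model) so that every
pipeline stage is testable end to end.

## Worked example

```r
library(bkarisk)

# one patient: 71 y, hypertension + diabetes, late mobilization, hypoxia
risk_score(71, c("hypertension", "diabetes_mellitus"), "late",
           hypoxia = TRUE, metabolic_disorder = FALSE)
#>   age_points comorbidity_points mobilization_points complication_points total
#> 1          1                  2                   1                   1     5

# a full synthetic cohort in the published cohort's shape
cohort <- simulate_cohort(paper_like_config(seed = 42))
report <- run_full_analysis(cohort, direction = "higher_score_positive")
print(report)
```

```
=== Below-knee amputation risk-score analysis ===
Cohort: n = 30, mean age = 70.4, mean score = 3.73, one-year mortality = 43.3%
Source: simulated(seed=42)

-- Score by outcome group (Mann-Whitney U) --
One-year survival status
  Survived  n=17  median 3.0  IQR 2.0-4.0
  Deceased  n=13  median 4.0  IQR 3.0-5.0
  U = 64.5, z = -1.950, p = 0.051 (normal_approx)
...

-- Mortality ROC --
Empirical ROC: died_within_1yr (13 positive, 17 negative), higher_score_positive
  AUC = 0.708 (opposite orientation: 0.292)

-- Functional independence --
Score vs 3-month Katz ADL
  analyzable n = 23 (excluded: 7 deaths before day 90, 0 without Katz data)
  Spearman r = -0.777 (strong), p = <0.001

-- Mean score by age band --
  under_65  n= 6  mean score 2.67 (age 0.00 + comorbidity 1.67 + mobilization 0.33 + complications 0.67)
            early mobilization 67%, mortality 33%, mean Katz 3.00
  ...
```

Reading the report: the deceased group carries the higher median score
and z is negative (the survivors' mean rank is lower), the score
discriminates one-year mortality with AUC 0.708 in the
higher-score-positive orientation, and the score is strongly negatively
correlated with 3-month functional independence (r = −0.777, "strong"
band) after excluding the 7 patients who died before day 90. The
age-band rows decompose each band's mean score exactly into its four
mean point components.

`write_analysis(report, "out/")` writes `scored_cohort.csv` (input
columns + the five score columns), `report.txt` (the tables above) and
`summary.json`; identical inputs give byte-identical files.

The same operations are available from a shell:

```sh
Rscript inst/cli/bka.R simulate --paper-like --seed 42 -o cohort.csv
Rscript inst/cli/bka.R validate cohort.csv
Rscript inst/cli/bka.R score cohort.csv -o scored.csv
Rscript inst/cli/bka.R analyze cohort.csv --direction higher -o report/
```

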
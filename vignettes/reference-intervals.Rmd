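---
title: "Establishing nonparametric hematology reference intervals in stratified cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Establishing nonparametric hematology reference intervals in stratified cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemaRI)
```

## The problem

A reference interval (RI) is the central 95% range — the 2.5th to 97.5th
percentile — of an analyte in a healthy reference population. Complete blood
count (CBC) results are interpreted against RIs, but hematology changes
substantially in pregnancy (plasma-volume expansion dilutes red cells and
platelets while leukocytes rise), and RIs transfer poorly across populations,
altitudes and instruments. Laboratories serving antenatal care therefore need
partitioned RIs: one per pregnancy trimester plus a non-pregnant comparison
group, each built from locally recruited, rigorously screened reference
subjects.

`hemaRI` implements that workflow end to end, following the CLSI/IFCC
nonparametric framework:

1. **Sample-size planning** — at least 120 reference subjects per partition,
   with the recruitment target inflated by the anticipated exclusion rate,
   `corrected = ceiling(base / (1 - rate))`.
2. **Eligibility screening** — serology (HIV, HBsAg, HCV, syphilis, CRP),
   parasitology, medical history, medication and substance use, obesity
   (BMI ≥ 30 kg/m², inclusive), hypertension (systolic > 140 or diastolic
   > 90 mmHg), specimen quality, and rules specific to the non-pregnant
   group (menstruation, breastfeeding, oral contraceptives; iron/folate
   supplementation is routine in pregnancy and exclusionary only for
   non-pregnant subjects).
3. **Outlier exclusion** — the Dixon/Reed one-third-range rule per analyte
   and partition.
4. **RI estimation** — rank-based percentile limits with distribution-free
   90% confidence intervals.
5. **Partition comparisons** — Kolmogorov–Smirnov normality checks,
   Mann–Whitney U and Kruskal–Wallis tests.
6. **Out-of-range (OOR) scoring** — how many subjects a manufacturer's
   interval would misclassify in the local population.

Because reference studies rarely deposit raw per-subject data, the package
also ships a synthetic cohort generator calibrated to published summary
tables, so the entire pipeline is exercised and tested without any external
data.

## The estimator

For a screened sample of size $n$, sorted ascending, the lower and upper
reference limits sit at the plotting-position ranks

$$ r_{low} = 0.025\,(n+1), \qquad r_{high} = 0.975\,(n+1), $$

clamped into $[1, n]$. Fractional ranks are resolved by linear interpolation
between the bracketing order statistics (rounding to the nearest integer
rank is available via `interpolate = FALSE`; which convention a given
published table used is usually unstated, and interpolation is the standard
companion of this rank formula).

Each limit carries a 90% confidence interval. The default is the
distribution-free order-statistic construction: with
$K \sim \mathrm{Binomial}(n, p)$ counting observations below the true
$p$-th percentile, `rank_ci_for_percentile()` finds the narrowest rank pair
$(l, u)$ with

$$ P(l \le K < u) \ge 0.90, $$

breaking width ties toward equal tail probabilities. At $n = 120$ and
$p = 0.025$ this yields the classic pair $(1, 7)$. The guaranteed coverage
is at least the nominal level (the construction is conservative because the
binomial is discrete). When no pair attains the confidence at the available
$n$ — below roughly $n = 90$ for the outer percentiles — the pipeline falls
back to a seeded percentile bootstrap (2,000 resamples of the limit
estimator); the method actually used is recorded per row in the output
(`ci_method`).

### Outlier screening

Before estimation, each analyte × partition sample passes the Dixon/Reed
screen: sort the data, and for each tail compute $D$, the gap between the
extreme and its nearest distinct neighbour, and $R$, the whole range. The
extreme is rejected when $D/R > 1/3$. Decisions made in this package:

* both tails are tested in each pass against the same $R$;
* the rule is re-applied until nothing is removed (capped at 10 passes),
  with single-pass screening available — published methods rarely state
  whether the rule was iterated, so both are exposed;
* values tied with a flagged extreme are removed with it (the ratio cannot
  distinguish them);
* samples below `min_n = 20` are returned unscreened and marked, because
  the rule degenerates on tiny samples (it flags an extreme of almost any
  3-point sample);
* a constant sample has $R = 0$ and nothing is removed.

The ratio is location- and scale-free, so screening is invariant under
affine transforms of the data. Its known weakness is masking: two gross
errors stacked close together in the same tail can hide each other. The
generator's defaults (below) make injected errors unambiguous, and the
operating characteristics quoted by the tests (sensitivity ≥ 90%, false
removals ≤ 2% at $n = 150$) hold for that regime of sporadic, well-separated
errors — not for adversarial clustered contamination.

### Comparisons

Between-partition location differences use rank tests throughout, because
most CBC analytes are non-normal: Mann–Whitney U for two groups (exact by
enumeration when the combined $n \le 14$ with no ties, otherwise the normal
approximation with tie-corrected variance and continuity correction) and
Kruskal–Wallis for the three trimesters (tie-corrected $H$, chi-square
approximation). Pairwise trimester p-values are reported without
multiplicity adjustment, matching common practice in RI studies; a
Bonferroni option exists but is off by default. The plain KS normality
check estimates the normal parameters from the data, which makes its
p-value conservative; the Lilliefors-corrected variant is available behind
`ks_corrected = TRUE` and off by default.

### Out-of-range scoring

`count_oor()` counts values strictly outside an interval (boundary values
are in range). The shipped per-limit OOR counts are reproduced with the
number of *enrolled* pregnant women (450) as the denominator — the printed
percentages (e.g. 86/450 = 19.1%) are only consistent with that choice, not
with the per-analyte post-screening counts — and `denominator_mode =
"per_analyte"` provides the alternative. One shipped count row violates
`below + above = total` in its source (the RBC row); the package enforces
conservation on everything it computes and keeps the printed per-limit
counts as inputs.

## The synthetic cohort generator

`generate_study()` emulates the structure of a four-partition reference
study: 150 recruits per trimester and non-pregnant group, 11.2% expected
ineligibility, and per-analyte values drawn from distributions calibrated to
the shipped per-partition quantile targets (median and the 2.5th/97.5th
percentiles for each of 19 CBC analytes).

**Calibration family.** Published intervals are often asymmetric about the
median, so `calibrate_distribution()` fits a three-parameter shifted
log-normal — solved in closed form from the quantile triple, reflected for
left skew — and short-circuits to a normal when the triple is symmetric.
Anchor-quantile residuals are at machine precision (tested against 1e-6).
This family is a modelling stand-in: the source tables report only that
most analytes were non-normal, not their shape. Cells whose printed triple
implies extreme skew (e.g. a third-trimester red-cell count with median
barely above the lower limit) produce correspondingly heavy simulated
tails; the package reproduces the printed numbers rather than reconciling
them.

**Defaults and why.**

* `n_per_partition = 150`, `ineligible_fraction = 0.112`: the source
  study's design (600 recruited, 533 eligible).
* Ineligibility reasons are drawn from a categorical distribution over
  serology (0.35), chronic history (0.25), transfusion/donation (0.15),
  obesity (0.15) and high blood pressure (0.10) — the published exclusion
  list, with weights chosen once as a plausible breakdown (the source gives
  no numeric split). Each reason sets the *screening field* that triggers
  it, so the screener genuinely re-detects it.
* `outlier_rate = 0.005` (~1 gross error per 150-subject cell): consistent
  with the per-analyte removals of roughly 1–5 per ~130 subjects seen in
  published trimester tables.
* `outlier_magnitude = 5` IQRs beyond the clean extremes: large enough
  that an injected error satisfies $D/R > 1/3$ by construction even with
  one error in each tail; same-tail errors share one displaced value so the
  tie rule removes them together. Lower-tail placements that would go
  negative are redirected upward (analytes are non-negative; generated
  values are likewise truncated at zero and rounded to each analyte's
  instrument precision).

**What the generator does not model**: correlations between analytes
(hemoglobin and hematocrit are simulated independently), gestational-week
dynamics within a trimester, measurement drift, or batch effects. Passing
tests on synthetic cohorts therefore demonstrate that the *procedures* are
correct under the stated marginal structure, not that the package's outputs
match any particular real population.

## Numerical and testing choices

* Round-trip calibration checks run 5 replicate cohorts of $n = 5{,}000$
  per partition and compare replicate-mean limits to the targets within 2%
  of the interval span; single draws at that $n$ have Monte-Carlo standard
  errors around 1% of span (far larger for the extreme-skew cells), so
  averaging keeps the check sharp without inflating the sample size.
  The leukocyte-recovery check similarly averages 5 cohorts of
  $n = 5{,}000$ against the 4.0–13.2 target (tolerance ±0.15).
* Coverage of the rank-binomial CIs is verified over 2,000 simulated
  cohorts of $n = 120$ (empirical rate ≥ 0.88, allowing Monte-Carlo error
  below the conservative construction).
* Type-I control of the comparison layer is verified over 500 null
  replicates at $\alpha = 0.05$ (accepted band 3–7%).
* All simulations are seeded; the pipeline itself is deterministic given
  `analysis_config(seed = )`, including bootstrap CIs, and a rerun with the
  same seed reproduces every output file byte for byte.

## Worked run

```{r, eval = FALSE}
cohort <- generate_study(cohort_config(random_seed = 42))
report <- run_pipeline(cohort, analysis_config(seed = 42))
report
write_tables(report, "ri-report")
```

The report bundle holds the participant flow, per-partition and pooled-group
RI tables, the normality and comparison tables, the OOR table and a
reproducibility manifest (seed, configuration hash, stage counts);
`write_tables()` renders each as CSV plus `manifest.json`.

## Limitations

* The nonparametric method is the only estimator provided — no Gaussian,
  robust (Horn) or Box–Cox transformed paths, and no a-posteriori
  partitioning statistics; partitions are taken as given.
* The Dixon/Reed screen shares the masking weakness of all
  nearest-gap rules; heavily contaminated data need a different screen.
* Synthetic calibration targets are taken from published summary tables,
  including their internal anomalies (one median printed outside its own
  interval is repaired to the printed mean in the calibration table, and
  count rows violating conservation are kept as printed inputs; both are
  flagged in the data documentation).
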
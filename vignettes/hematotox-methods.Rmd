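---
title: "Methods: CAR-HEMATOTOX risk stratification and its synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CAR-HEMATOTOX risk stratification and its synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hematotox)
```

## The clinical problem

BCMA-directed CAR T-cell therapy for relapsed/refractory multiple myeloma is
frequently complicated by hematological toxicity: deep and sometimes
prolonged cytopenias that begin with lymphodepleting chemotherapy, can
follow a biphasic course (recovery followed by a second dip), and predispose
to severe infections — which in turn dominate non-relapse mortality. The
CAR-HEMATOTOX (HT) score summarizes a patient's hematopoietic reserve (ANC,
hemoglobin, platelets) and inflammatory state (CRP, ferritin) *before*
lymphodepletion into 0–7 points; a score of 2 or more flags a high-risk
patient. This package implements the score, the toxicity and infection
endpoints it predicts, the survival statistics used to validate it, and a
synthetic cohort generator that emulates the study population.

## The score rubric

Each component contributes points from its own band: ANC ≤ 1.2 G/l,
hemoglobin ≤ 9.0 g/dl and CRP ≥ 3.0 mg/dl contribute one point each;
platelets contribute 2 points at ≤ 75 G/l and 1 point in (75, 175] G/l;
ferritin contributes 2 points at ≥ 2000 ng/ml and 1 point in [650, 2000).
Two numerical conventions are worth making explicit:

- the platelet bands are printed clinically as "≤ 75" and "76–175"; since
  platelet counts are reported as integers in G/l, the half-open bands
  (75, 175] reproduce the printed integer bands exactly while leaving no
  gap for non-integer values;
- ferritin 2000 belongs to the 2-point band, because the "≥ 2000" band is
  the explicitly closed one.

Labs are scored from the draw closest to the start of lymphodepletion
within a leniency window of 3 days *before* the start (ties break toward
the later draw). Values after the start of chemotherapy are never scored:
the score is a pre-treatment instrument. An alternative two-sided window is
available (`direction = "both"`) because some calculators accept labs a few
days after; the one-sided window is the default. Missing analytes are an
error under the default `strict` policy; the exploratory `zero_points`
policy scores them as zero points and flags the patient, since no
imputation scheme is part of the instrument.

## Trajectory endpoints

All longitudinal endpoints are computed on an integer daily grid anchored
at the CAR-T infusion (day 0). Between lab draws the last observation is
carried forward (LOCF); days before the first measurement are unknown and
never count toward any threshold. LOCF is the standard conservative
convention for inpatient labs — a neutropenic value stands until a
measurement shows recovery — and it makes the day counts reproducible,
which a statement like "days with ANC < 500/µl" alone does not. A
`measured`-days-only mode is provided as a sensitivity analysis.

The endpoints: cumulative severe-neutropenia days (ANC < 0.5 G/l, days
0–60, hence a value in [0, 61]); windowed severe flags (days 0–30 and
31–100); protracted severe (≥ 7 consecutive days < 0.5); profound
(any < 0.1 over days 0–100) and protracted profound (≥ 7 consecutive
days); prolonged (< 1.0 G/l on any day ≥ 21). Consecutive-day requirements
are evaluated as maximal runs on the LOCF grid, with unknown days breaking
a run.

The neutrophil-recovery phenotype is classified in a fixed precedence
order: **aplastic** if any run of ≥ 14 consecutive days has ANC < 0.5 G/l;
otherwise **intermittent** if some day shows recovery above 1.5 G/l
followed by a later dip below 1.0 G/l after day 21 (day ≥ 22, mirroring
"after day 21" literally; the prolonged flag, whose definition reads "≥ 21
days after", uses day ≥ 21); otherwise **quick**. Aplastic takes precedence
because the classes are mutually exclusive and aplasia is the clinically
dominant pattern; quick is defined negatively because sustained recovery is
the absence of the other two patterns. The intermittent rule only requires
recovery to precede the dip, not to precede day 21. With under 22 days of
observed follow-up a classification is still returned but marked
low-confidence.

Severe thrombocytopenia is a platelet count < 50 G/l; severe anemia is
hemoglobin < 8 g/dl *or* a packed red-cell transfusion inside the window —
a window with neither a measurement nor a transfusion is reported as not
evaluable (`NA`), which is deliberately distinct from `FALSE`.

## Infections

Infection events carry an onset day (day of the diagnostic test), a
category (bacterial / viral / fungal / clinical syndrome), a free-text
source and a 5-grade severity; severe means grade ≥ 3. Neutropenic fever
alone is not an infection event: the reader drops such rows and flags them.
Early infections are those with onset in days 0–90; a patient may
contribute several events but each per-patient flag counts once, while
descriptive tallies keep all events. Cumulative incidence of the first
qualifying event is one minus the Kaplan–Meier estimator per risk group,
with death before first infection treated as censoring at the death day —
this matches a log-rank comparison of the curves; a competing-risks
treatment of death is available through the same Aalen–Johansen machinery
used for mortality, with the usual caveat that censoring-at-death
overestimates absolute incidence when mortality differs between groups.

## Outcome statistics

- **ROC**: the AUC is the tie-corrected normalized Mann–Whitney statistic;
  the operating point maximizes Youden's J; the p-value against AUC = 0.5
  uses the tie-corrected normal approximation to U. Higher scores predict
  the positive class by construction, never auto-detected.
- **Kaplan–Meier**: product-limit estimator with Greenwood-variance
  intervals. The median is the smallest time with survival below 0.5; when
  the curve hits 0.5 exactly the midpoint to the next event time is used;
  a curve that never reaches 0.5 has an undefined ("not reached") median.
- **Log-rank**: hypergeometric expected counts; chi-square p by default,
  with an exact permutation mode (all group relabelings) for small
  samples.
- **Non-relapse mortality**: death without prior progression, competing
  with progression-related death, estimated by the Aalen–Johansen
  multi-state estimator (the event-free probability and the cause-specific
  incidences sum to one at every time); groups are compared by the
  cause-specific log-rank on the NRM hazard. One minus Kaplan–Meier is
  available via the same functions for sensitivity.
- **Cox**: partial likelihood with Efron tie handling (the default of the
  mainstream survival software) and Wald intervals, over five binary
  baseline indicators: eGFR ≥ 60 ml/min, LDH above the upper limit of
  normal, ECOG ≥ 2, bone-marrow plasma-cell infiltration > 50%, and
  high-risk HT class. Logistic regression uses the same covariates for the
  aplastic-phenotype and severe-infection endpoints; separation raises an
  error rather than returning an exploded estimate.
- **Group tests**: two-sided Mann–Whitney (exact enumeration when the
  combined n ≤ 12 and there are no ties, tie-corrected normal
  approximation otherwise) and Fisher's exact test, two-sided by summing
  hypergeometric probabilities no larger than the observed table's.
  No multiplicity adjustment is applied anywhere, matching how such
  cohort analyses are conventionally reported.

## The synthetic cohort generator

The generator exists so that every stage of the pipeline is exercisable
and testable without patient-level data. It emulates the *statistical
structure* the analysis assumes, not the biology:

- Two latent strata (55.8% low) drive the baseline labs: log-normal draws
  for ANC, platelets, CRP and ferritin and normal draws for hemoglobin,
  located at the published group medians (low: 2.95 G/l, 181 G/l,
  0.45 mg/dl, 86 ng/ml, 11.6 g/dl; high: 1.77, 63, 1.02, 811, 8.5). The
  scales are *calibrated, not estimated* — group medians and confidence
  intervals constrain but do not identify them — and are chosen so that
  the large majority of the high stratum scores ≥ 2. The recorded risk
  class is always recomputed from the generated labs by the rubric, so
  patients cross over between latent stratum and computed class (about
  3%); the realized crossover rate is attached to every cohort.
- The severe-neutropenia duration is negative-binomial with mean
  `2.6 + 2.48 × score` days (dispersion size 2), the slope being the
  published days-per-point association. A drawn duration of ≥ 14 days
  stays *continuous* — one uninterrupted run, hence an aplastic
  trajectory — with probability `plogis(1.2 + 0.22·score + 0.5·[BM > 50%])`,
  and is otherwise split into a first run and a later second severe dip.
  Keeping the phenotype assignment conditional on the drawn duration
  leaves the marginal duration distribution, and therefore the
  duration-on-score slope, untouched. Non-severe second dips (0.5–1.0
  G/l after day 21) occur with stratum probabilities 0.35/0.80, producing
  the intermittent phenotype. ANC is sampled daily through day 21 (the
  inpatient phase) and every 1–3 days thereafter to day 100; platelets
  and hemoglobin follow simple nadir-and-recovery curves sampled every
  3–4 days.
- Severe (grade ≥ 3) and any-grade infection indicators are Bernoulli with
  probabilities 0.40/0.58 in the high class and 0.05/0.23 in the low
  class. These published rates condition on the *computed* risk class, so
  the infection model is keyed to the class the rubric assigns (available
  at draw time), not to the latent stratum. Onset days over 0–90 are drawn
  with weight 1 + 6 on days with concurrent ANC < 0.5 G/l — equivalent,
  marginally, to an infection hazard elevated during neutropenia — and
  never postdate death. Severe events are predominantly bacterial; grade
  4–5 events occur only in the high class.
- Survival uses stratum-specific exponential hazards: progression rates
  back-calculated so that progression-free survival (the minimum of
  progression and NRM) has medians 14.9 and 5.4 months; NRM rates 0.0023
  and 0.021 per month solved from the competing-risks identity to give
  one-year NRM incidences near 2% and 13%; post-progression survival with
  a 4-month median so the high stratum's overall survival median lands
  near 10.5 months. The low stratum's "not reached" OS median is emulated
  by hazards that put the median far beyond follow-up, with administrative
  censoring at 12 months (the one-year analysis horizon). NRM causes are
  assigned 5:1:1 infection : CRS : cardiotoxicity.
- Covariates (ECOG, eGFR, LDH, marrow infiltration, prior BCMA therapy,
  CRS/ICANS grades, hospital days) and the response category are drawn
  from stratum-specific categorical/log-normal distributions matching the
  published group frequencies; ECOG ≥ 2 occurs only in the high stratum.

What the generator does *not* emulate: center-to-center heterogeneity,
calendar-time effects, correlated lab panels (each analyte is drawn
independently given the stratum), informative censoring, G-CSF effects on
the trajectory, or any CRS/ICANS pathophysiology (grades are plain
categorical draws). Pipeline results on synthetic cohorts therefore
demonstrate that the *computational machinery* reproduces the calibrated
population structure — they are not evidence about real patients, and
calibration targets recovered from the generator are a consistency check,
not a validation.

```{r calibration}
co <- simulate_cohort(1000, seed = 1)
calibration_report(co)
```

## Problem sizes and numerical choices

The test suite exercises the oracle-equivalence checks on 10,000 random
short series, the permutation oracles at n ≤ 12 (where full enumeration is
exact), regression parameter recovery on 200 replicates of n = 5000, and
the cohort-level reproduction on ten cohorts of n = 1000 — sizes at which
Monte-Carlo error is small relative to the stated tolerances while the
whole suite runs in a couple of minutes. Ties in ranks are handled by the
standard correction everywhere; the ROC direction is fixed, not inferred;
day windows are closed integer intervals; missing values are `NA`, never
zero, because zero is a legal ANC. Seeds control all randomness: the same
seed reproduces a cohort bitwise, including its CSV serialization.

## Known limitations

The LOCF convention can overstate the length of a severe run when sampling
is sparse around recovery (by up to the inter-draw gap); the measured-only
mode bounds this from the other side. The incidence curves censor at death
by design (see above). The Cox models make the usual proportional-hazards
assumption, which is not diagnosed beyond this caveat; no subdistribution
(Fine–Gray) regression is provided. Response categories are inputs, never
adjudicated; CRS/ICANS grades are recorded inputs, never computed.
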
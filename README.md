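# hematotox

Risk stratification of hematological toxicity, infection and survival after
BCMA-directed CAR T-cell therapy in relapsed/refractory multiple myeloma,
built around the **CAR-HEMATOTOX (HT) score** — the 0–7 point rubric over
pre-lymphodepletion labs used by treating physicians to identify patients at
risk of severe cytopenias and infections before chemotherapy starts.

The package is aimed at biostatisticians and clinical researchers analysing
CAR-T cohorts: it provides the score, the longitudinal neutropenia/cytopenia
endpoints, infection summaries with cumulative incidence, the survival and
regression machinery used to validate the score, and a calibrated synthetic
cohort generator so the entire pipeline runs and is testable without any
patient data.

## The score

One point for each of

| component | 1 point | 2 points |
|---|---|---|
| ANC | ≤ 1.2 G/l | — |
| hemoglobin | ≤ 9.0 g/dl | — |
| platelets | 76–175 G/l | ≤ 75 G/l |
| CRP | ≥ 3.0 mg/dl | — |
| ferritin | 650–2000 ng/ml | ≥ 2000 ng/ml |

computed from labs drawn at (or up to 3 days before) the start of
lymphodepleting chemotherapy. A total of **≥ 2 is high risk** (HT-high),
0–1 low risk (HT-low).

Downstream endpoints:

- cumulative days with ANC < 0.5 G/l over days 0–60 (carried-forward daily
  grid), plus protracted/profound/prolonged neutropenia flags and the
  **quick / intermittent / aplastic** neutrophil-recovery phenotypes;
- severe thrombocytopenia (platelets < 50 G/l) and severe anemia
  (Hb < 8 g/dl or transfusion) over days 0–30 and 31–100;
- infection events over days 0–90 on a 5-grade scale (severe = grade ≥ 3),
  with Kaplan–Meier-type cumulative incidence by risk group;
- Kaplan–Meier/log-rank PFS and OS, non-relapse mortality as an
  Aalen–Johansen competing-risks endpoint, multivariable Cox and logistic
  models over the standard five baseline indicators, ROC discrimination,
  Spearman correlation, Mann–Whitney and Fisher tests.

## Worked example

```r
library(hematotox)

# score a single lab profile
ht_score_components(anc = 1.1, hemoglobin = 8.4, platelets = 70,
                    crp = 3.6, ferritin = 890)
#>   points_anc points_hb points_plt points_crp points_ferritin total risk_class
#> 1          1         1          2          1               1     6       high

# a synthetic cohort emulating the study population
co <- simulate_cohort(500, seed = 42)
st <- ht_score(co)
st
#> CAR-HEMATOTOX scores
#>   scored: 500  (low 263 / high 237); unscoreable: 0
#>   score distribution (0-7):  144 119 41 80 74 33 9 0

risk <- risk_class(st)
met <- neutropenia_metrics(co)
g <- risk[met$patient_id]
median(met$severe_days_d0_60[g == "low"])   # 3 days
median(met$severe_days_d0_60[g == "high"])  # 9 days

infs <- summarize_infections(co)
#> Infections d0-90: 284 events in 207/500 patients (severe: 106)
# severe infections d0-90: high 40.1%, low 4.2%

nrm_analysis(co, risk)
#> Non-relapse mortality at 12 months:
#>   overall: 6.2%
#>   high: 8.9%
#>   low: 3.8%
#>   cause-specific log-rank p = 0.00781

sc <- st$scores$total[match(met$patient_id, st$scores$patient_id)]
ht_roc(sc, met$severe_days_d0_60 >= 14)
#> ROC: AUC = 0.821 (n+ = 87, n- = 413), p = 5.418e-22 vs AUC 0.5
#>   operating point (Youden): cutoff 2, sens 0.91, spec 0.62
```

The high-risk stratum carries the longer severe neutropenia (median 9 vs 3
days), the higher severe-infection rate (40% vs 4%), and the higher
non-relapse mortality, and a score cutoff of 2 discriminates the ≥ 14-day
severe-neutropenia endpoint with AUC ≈ 0.82 — the orderings the score is
designed to capture.

`run_pipeline()` executes everything end to end and writes a CSV/JSON
result bundle; `inst/scripts/ht-pipeline.R` is a thin command-line wrapper
(`simulate`, `score`, `hematotox`, `infections`, `run-all`).

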
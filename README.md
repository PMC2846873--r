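# reportlife

Hospital information systems accumulate clinical reports (laboratory
results, pathology, imaging, discharge letters) far faster than clinicians
can read them. How long does a report stay *useful*? `reportlife` answers
that question from the system's own audit logs: it turns raw
session/view/encounter extracts into per-view report ages and measures each
report class's **median life** — the age by which half of all views of that
class have occurred — together with the decay law of usage over time.

The package is written for clinical-informatics teams who have (or can
export) three tabular extracts from their record system:

1. **patients + report metadata** — report id/version, departmental source,
   availability timestamp, patient, producing encounter;
2. **access logs** — sessions (login, IP, user category) and report-view
   events with timestamps;
3. **patient encounters** — type (inpatient, outpatient, emergency,
   day-care, lab-result, radiology), admission/discharge times, inpatient
   main ICD-9-CM diagnosis.

Because such extracts are never public, the package ships a synthetic-cohort
generator with known ground truth that emulates all three — including
laboratory version streams, development-team sessions, sub-3-second spurious
views and realistic view-age distributions — so the full pipeline is
testable offline.

## The statistics at the core

* **Log preparation.** Development-team sessions are excluded; each view's
  maximum duration is bounded by the gap to the next request in the same
  session; views lasting ≤ 3 s are treated as mistaken and removed;
  laboratory report versions can be grouped into one logical report anchored
  at the first version's availability ("grouped versions") or analysed
  file-by-file ("all versions").
* **Context classification.** Each view is matched to the encounter it
  happened in (interval containment for inpatient stays, calendar-date
  equality otherwise) and classified relative to the report's producing
  encounter: *present* (same encounter), *last* (immediately preceding
  encounter, any type), *previous* (earlier), or *unmatched*.
* **Median life.** For a set of views with ages `t_i` (days since report
  availability), the median life is the sample median (quartiles by linear
  interpolation); summaries are stratified by department, encounter type,
  patient sex and age group, and ICD-9-CM chapter/section (sections with
  ≤ 20 views suppressed).
* **Aging model.** Views in a window are binned by age in months
  (1 month = 30.4375 d); `y(x)` is the fraction of views aged ≥ `x` months.
  Two families are fitted: exponential `y = a·e^(−bx)` (OLS on `(x, log y)`)
  and logarithmic `y = −c·ln(x) + d` (OLS on `(ln x, y)`), with R². The
  fitted decay doubles as a recency-based **relevance score**
  `a·e^(−b·age)` for ranking reports in a viewer GUI, or a threshold rule
  (highlight while age ≤ stratum median life).

## Worked example

```r
library(reportlife)

cohort <- generate_cohort(sim_config(n_patients = 2000, seed = 1))
cohort
#> Synthetic cohort:
#>   patients       2000 rows
#>   encounters     4916 rows
#>   reports       15359 rows
#>   sessions       7257 rows
#>   views          8630 rows

prep <- prepare_views(cohort$sessions, cohort$views, cohort$reports)
sprintf("mistaken views removed: %d (%.1f%%)",
        prep$summary$n_mistaken_removed, prep$summary$pct_mistaken)
#> "mistaken views removed: 180 (2.1%)"

views <- classify_views(prep$views, cohort$encounters)
stratified_median_life(views, "creation_encounter_type")[1:3]
#>       stratum n_views median_life        p25      p75 dispersion_ratio
#> 1: lab-result       9   151.96417 0.04611111 456.7936         9906.367
#> 2:  radiology       4    59.64266 0.15776910 174.9976         1109.201
#> 3: outpatient    4768    40.84373 0.15922164 213.9794         1343.909
```

The 2.1% removal rate recovers the generator's configured 2.2% spurious-view
rate; the outpatient median life (40.8 d here) reflects the default
exponential-mixture age law. Fitting the aging model on 200,000 ages drawn
from a mixture with survival `0.5826·e^(−0.12x)` recovers the generating
parameters:

```r
ages <- generate_view_ages(200000, a = 0.5826, b = 0.12, seed = 1)
fit_exponential(bin_view_ages(ages * 30.4375))
#> Aging fit (exponential): y = 0.5881 * exp(-0.1214 x)   R^2 = 1.000  (44 points)

relevance_score(c(2, 40), median_life_days = 15)
#>    score highlight
#> 1:     1      TRUE
#> 2:     0     FALSE
```

A 2-day-old report of a class with a 15-day median life is highlighted; a
40-day-old one is downgraded.

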
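---
title: "Measuring the longevity of clinical reports from audit logs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the longevity of clinical reports from audit logs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reportlife)
```

## The problem

Integrated hospital record systems collect thousands of new clinical
reports per day. Screen space, archive tiers and clinicians' attention are
all scarce, so it matters greatly whether a given report class is consumed
within hours (a coagulation panel during an emergency admission) or over
years (a pathology report anchoring oncological follow-up). `reportlife`
estimates this **report longevity** from the system's own access logs: every
view event, joined to the viewed report's availability timestamp, yields a
*report age at view*; the distribution of those ages per report class is the
object of study.

Two summaries are produced. The **median life** of a class is the age by
which half of its views have occurred — the sample median of per-view ages,
with quartiles for dispersion. The **aging model** describes the whole decay
curve: with views binned by age in months, the fraction `y(x)` of views aged
at least `x` months is fitted by an exponential `y = a·e^(−bx)` and a
logarithmic `y = −c·ln(x) + d` family, compared by R².

## The pipeline and its assumptions

**Preparation.** The record system cannot measure reading time directly, so
the duration of a view is bounded by the gap to the *next* request in the
same session; the final event of a session has no bound and is kept as a
valid view (exclusion is only defined for measurably short views). Views
whose bound does not exceed 3 seconds are treated as mistaken (a misclick or
double click) and removed — the boundary itself, exactly 3.0 s, is removed,
reading "did not take more than three seconds" literally. Development-team
sessions are removed wholesale before anything else. Laboratory systems
resend reports as findings accrue; in the information-centric **grouped
versions** mode all versions sharing a group key count as one report whose
age anchor is the *first* version's availability (when is the information
first accessible?), while the file-centric **all versions** mode ages each
version from its own availability. The per-view timestamp, not the latest
view of a group, defines the age; the alternative reading of "maximum date
of the view" is not taken (it would make ages depend on future views).

**Context classification.** The system does not record where the viewing
clinician was working. The viewing encounter is inferred by date
comparison: an inpatient stay matches any calendar day of its closed
admission–discharge interval, every other encounter type matches on
calendar-date equality. Where both match — an emergency visit converting to
an admission on the same day — the interval (inpatient) encounter wins, then
the latest-starting one; ward activity therefore dominates admission-day
classification. When nothing matches, *no assumption is made* and the view
is left `unmatched` (excluded from setting crosstabs, retained and flagged
elsewhere). Relative to the report's producing encounter a matched view is
`present` (same encounter), `last` (the producing encounter is the
patient's immediately preceding encounter, of any type, before the viewing
encounter's start — "immediately preceding" meaning no other encounter
starts strictly between them), or `previous` (earlier still). A report
whose producing encounter starts after the view is an integrity error; one
whose producing encounter is concurrent with (started inside) the viewing
encounter is `unmatched`.

**Estimation.** Medians and quartiles use linear interpolation between
order statistics (R's default type-7 quantile); no convention was inherited,
so the ubiquitous one was chosen. Empty strata raise a classed
`empty-stratum` condition rather than returning NaN. ICD-9-CM strata are
restricted to reports produced in inpatient encounters (only those carry a
main diagnosis); section-level strata with 20 or fewer views are
suppressed as unstable. Patient age is computed at the report's
availability date — the report's clinical moment — and the age bins are
child 0–12, teenager 13–19, young adult 20–34, adult 35–54, old adult
55–69, senior 70+; exactly 70, unassigned in the source binning, goes to
senior. The usage-evolution metric "views per user per 10,000 encounters"
is computed as `(views ÷ distinct users) ÷ encounters × 10,000`, the only
reading consistent with the metric's name (the source formula is not
machine-readable); treat cross-system comparisons of this metric with care.

**Aging model.** One month is 30.4375 days throughout. `y(x)` is the
*complementary* cumulative fraction of views aged at least `x` months — the
printed decay equations tend to zero, which a cumulative fraction cannot,
so the complementary reading is the coherent one. The age grid starts at
`x = 1` (the logarithmic family is undefined at 0); views in the first
month are captured by the complement at `x = 1`, and views older than the
last bin simply remain in every bin. The exponential family is fitted by
ordinary least squares on `(x, log y)` with R² on the log scale, matching
spreadsheet trend-line behaviour; a direct nonlinear least-squares
refinement (`method = "nls"`) is available and falls back to the log-linear
optimum on exact data, where Gauss–Newton cannot iterate. Points with
`y ≤ 0` cannot be log-transformed and are dropped with a warning; fewer
than three surviving points is an error, not a fit.

**Relevance scoring.** In model mode the score of a report aged `t` is the
fitted `a·e^(−bt)` clipped to `[0, 1]` — the estimated share of its class's
views still to come — and a report is highlighted while its age is below
the model-implied median life `ln(2a)/b` (0 when `a ≤ 0.5`: more than half
of all views happen within the first month). In threshold mode a report is
highlighted exactly while its age does not exceed its stratum's empirical
median life. Ranking sorts by highlight, then score, then recency, with the
report id as a deterministic tie-break.

## What the synthetic generator emulates — and what it does not

`sim_config()` + `generate_cohort()` realise a stated world: per-patient
encounter histories (multi-day inpatient stays, single-day encounters of
the other types, non-overlapping per patient), report groups produced
inside their encounters, laboratory sources emitting several versions per
group, and views placed at *group availability + a sampled age*. The
view-age law is configurable per stratum (department keys override
encounter-type keys, then a default):

* the **mixture** law puts mass `1 − a` on same-day views and an
  exponential tail with rate `b` per month on the rest, so the survival
  fraction at `x` months is exactly `a·e^(−bx)` — the functional form the
  aging model fits. The same-day mass is spread over the first six hours
  after availability; exact zero offsets would stack distinct views on one
  timestamp and get them falsely removed as sub-3-second views, while the
  monthly survival values are unaffected;
* the **log-normal** law fixes a true median in days (`sdlog = 1.0` by
  default). The spread was fixed a priori so that the sample-median
  standard error at 20,000 views is ≈ 0.9%, comfortably inside the 2%
  recovery band the test suite demands. Real view-age dispersion is much
  wider (observed interquartile ranges imply `sdlog ≈ 3`), so a green
  recovery test certifies the estimator and the pipeline plumbing, not the
  generator's realism.

Contamination is injected at configurable rates: spurious double-click
views (a duplicate request 0.5–3 s before a real one, default 2.2% of all
views) and development-team sessions with their own views (default 0.6% of
sessions — the documented dev-session count against the session volume the
study system implies). Default encounter-type and department mixes follow
the study hospital's published volumes; counts per patient/encounter/group
are `1 + Poisson` draws (or fixed counts for degenerate test worlds).

Deliberately **not** modelled: clinical report content; per-user
behavioural heterogeneity (sessions are a stand-in — one login per patient,
one session per login-day — because no inter-arrival model is published);
views that cluster inside later encounters (ages are drawn from the
configured law regardless of where the patient is, so `last`/`previous`
views are rarer than in real logs); truncation at the end of the
observation window (views may fall after the simulated span so that the
age law stays exact).

Randomness is split per table *and* per variable via seeds derived from the
master seed, with draws ordered by patient; identical configurations are
byte-reproducible, and enlarging `n_patients` appends new patients without
re-randomising existing rows.

## Numerical and degenerate-input choices

* All timestamps are normalised to UTC at load; the 3-second rule and
  same-day matching are therefore immune to timezone and DST artefacts.
* Duration inference sorts events by wall clock before differencing, so
  negative gaps cannot arise from ordering; an explicit session-end bound
  earlier than the last request is flagged invalid, excluded and logged,
  and every raw view ends in exactly one of kept / removed-mistaken /
  removed-invalid.
* Identical request timestamps yield zero durations (removed by the
  3-second rule), not errors.
* Version groups spanning several patients, encounters ending before they
  start, views preceding their report's availability, and reports produced
  after their own view all raise classed integrity errors.
* Validation collects schema violations exhaustively with row numbers;
  only a missing required column aborts immediately.

## Known limitations

* The encounter-setting analysis is as good as the date-matching heuristic;
  encounters missing from the extract silently become `unmatched` views.
* Median-life strata are not tested for differences (no hypothesis testing
  is performed, mirroring the descriptive design).
* The ICD-9-CM lookup ships numeric chapters and sections at standard
  rubric granularity but keeps E codes as a single supplementary section.
* The relevance score is a population summary per report class; it does not
  model per-user or per-patient relevance.

Every number quoted above (the 2.2% removal rate, the recovery tolerances,
the fitted parameters) is recomputed by the test suite in
`tests/testthat/` and by `scripts/acceptance.R`; nothing is asserted that
the code does not itself measure.
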
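Package: reportlife
Title: Median Life and Aging Models for Clinical Report Usage Logs
Version: 0.1.0
Authors@R:
    person("VPR", "Analytics", email = "vpr-analytics@example.org",
           role = c("aut", "cre"))
Description: Analyses hospital-information-system audit logs to measure for
    how long clinical reports remain in use. Turns raw session/view/encounter
    extracts into analysis-ready view logs (development-session exclusion,
    dwell-time inference, sub-3-second mistaken-view filtering, report-version
    grouping), infers the hospital-encounter context of every view and its
    relation to the report's producing encounter (concomitant, last,
    previous), computes stratified median-life summaries with quartiles,
    usage-evolution metrics and creation-by-view crosstabs, and fits
    exponential and logarithmic report-aging models over monthly age bins,
    exposing the fitted decay as a recency-based relevance score for report
    ranking. A synthetic-cohort generator with known ground truth stands in
    for the hospital's database extracts so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
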
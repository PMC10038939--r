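Package: aqua12
Title: Quality Scoring and Reliability Analysis for Adverse Drug Reaction Reports
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Scores the completeness of hospital adverse drug reaction (ADR)
    reports with the AQUA-12 rubric: seven data elements scored 0-2 (0-1 for
    the medication timeline and management elements) for a maximum total of
    12, with quality categories Excellent/Good/Moderate/Poor and a
    high-quality threshold of 10. Provides the accompanying evaluation
    procedures used by an ADR review committee: inter-rater reliability of
    total scores as Cronbach's alpha (the two-way consistency,
    average-measures intraclass correlation) with Feldt F-based confidence
    intervals, discrepancy flagging between assessors, contingency-table
    association tests (Pearson chi-square and two-sided Fisher exact),
    descriptive cohort summaries, a multi-rater synthetic-data generator for
    validation studies, and CSV/JSON input-output with a small command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
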
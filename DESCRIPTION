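Package: huassess
Title: Adaptive Health Utility Elicitation for End-Stage Kidney Disease
    Transplant Decisions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Adaptive elicitation engines for the standard gamble, time
    trade-off, and visual analog scale, with chained anchor states and
    life-table-driven time-trade-off horizons, aimed at preference
    assessment for end-stage kidney disease transplant decisions
    (hemodialysis, transplantation with an HCV-unexposed kidney, and
    transplantation with an HCV-viremic kidney).  Includes a behavioral
    model of simulated respondents, a moment-matching calibrator and
    seeded synthetic-cohort generator emulating a dialysis-clinic study
    population, rank-based and internal-consistency statistics for
    knowledge-change and utility analyses, permuted-block randomization
    with exemplar-clip selection, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
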
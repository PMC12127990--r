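Package: signtrack
Title: Sign- and Goal-Tracking Phenotyping from Eye-Gaze Dwell Times
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for phenotyping human participants as sign-trackers,
    intermediates or goal-trackers from eye-tracking data collected during
    Pavlovian conditioning. Computes area-of-interest dwell times over a
    configurable analysis window, derives the gaze index
    (CS dwell minus reward dwell over total dwell), performs rank-based
    tertile classification with Tukey outlier flagging, and runs the
    associated statistical battery: Pearson chi-squared on the sex by
    phenotype table, pooled-variance t-test with Cohen's d, and a mixed
    2x2 ANOVA (CS type within, sex between) with partial eta squared.
    Includes a seeded synthetic cohort generator so the full pipeline is
    reproducible without access to raw gaze recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
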
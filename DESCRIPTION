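Package: motiveprofiles
Title: Trait-State Profile Similarity for Momentary Eating-Motive Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing dispositional (trait) and in-the-moment
    (state) eating-motive profiles collected with event-contingent ecological
    momentary assessment (EMA). Aggregates event-level state ratings to
    person-level profiles, computes four profile-similarity indices (overall
    similarity by the double-entry intraclass correlation, shape by the Pearson
    correlation, scatter by the raw variance difference, and elevation by the
    raw mean difference) at the group and participant level, runs per-motive
    paired comparisons with Cohen's d effect sizes and descriptive banding,
    simulates seeded synthetic cohorts with the statistical structure such
    studies assume, and renders a static person-by-motive data-matrix
    visualization as SVG.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tibble,
    readr,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
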
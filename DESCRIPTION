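Package: smdscorecard
Title: Quality Evaluation and Scorecards for Synthetic Medical Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the seven quality criteria for synthetic medical
    data -- Congruence, Coverage, Constraint, Completeness, Compliance,
    Comprehension, and Consistency -- from feature embeddings, paired
    grayscale images, and tabular records. Individual metrics (Frechet
    distance, k-nearest-neighbour precision/recall manifolds, Vendi and
    determinantal diversity scores, convex-hull coverage, declarative
    constraint auditing, k-anonymity/l-diversity/t-closeness, subgroup
    stability) are normalized against configurable calibrations,
    aggregated into per-criterion scores with good/moderate/low labels,
    and assembled into a structured, validated scorecard document
    rendered as canonical JSON or Markdown. Seeded fixture generators
    with planted ground truth make every metric testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite,
    yaml,
    png
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
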
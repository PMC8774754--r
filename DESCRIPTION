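Package: axosym
Title: Axonemal Asymmetry Scoring for Ciliary TEM Cross-Sections
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies axonemal asymmetry in transmission electron
    micrographs of respiratory ciliary cross-sections. Fits the axonemal
    circumference (circle or ellipse) through the nine A-tubule centers,
    classifies each peripheral doublet as rotated when its B-tubule lies
    outside the fitted curve, and calls a per-section symmetry break when
    more than three doublets are rotated. Aggregates section calls into
    per-patient asymmetry percentages and modified BEAT-PCD ultrastructural
    defect classes (Class 1 / Class 2). Includes a synthetic 9+2 axoneme
    generator with TEM-like image rendering and ground-truth labels, an
    annular matched-filter ring detector that recovers doublet coordinates
    from images, and a cohort stage that ingests patient tables and reports
    group summaries, ranges and between-group overlap.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    jsonlite,
    minpack.lm,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
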
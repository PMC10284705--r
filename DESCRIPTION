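Package: stampr
Title: Longitudinal Immune-Phenotype Analysis of Arrayed Skin Microtumours
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for longitudinal analysis of arrayed skin microtumour
    time-lapse imaging: a ground-truthed synthetic cohort and image generator,
    tumour segmentation and cross-day tracking, median radial T-cell profiles
    and infiltration statistics, rule-based tumour immune-phenotype (TIP)
    classification (inflamed / excluded / desert with cohort-referenced
    thresholds), calcium and propidium-iodide influx indices for cytotoxicity,
    Markov transition analysis of phenotype timelines with a shuffle null,
    trajectory-class clustering, and per-tumour Kaplan-Meier survival with
    log-rank comparisons.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    cluster,
    jsonlite,
    stats,
    survival,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
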
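Package: rsvpcar
Title: Cross-Subject ERP Brain-Computer Interface Analysis with
    Correlation Analysis Rank
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: End-to-end analysis pipeline for cross-subject event-related
    potential (ERP) brain-computer interfaces built on rapid serial visual
    presentation (RSVP) spellers. Provides a synthetic multi-subject EEG
    cohort generator with subject-specific P300 morphology and 1/f noise,
    ERP preprocessing (zero-phase band-pass filtering, decimation, epoching
    with baseline correction, channel selection), coherent averaging,
    inter-subject ERP similarity statistics (angle cosine with threshold
    matching, Pearson correlation), the Correlation Analysis Rank (CAR)
    donor-selection algorithm for assembling cross-subject training sets,
    shrinkage-regularized linear discriminant classification with AUC
    evaluation against a random-donor baseline, and speller-level symbol
    accuracy and information transfer rate computation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    MASS,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
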
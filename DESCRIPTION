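Package: afburden
Title: Atrial Fibrillation Burden Quantification from Per-Minute Wearable Rhythm Streams
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying atrial fibrillation (AF) burden and its
    progression from per-minute rhythm epoch streams recorded by wrist-worn
    photoplethysmography (PPG) devices, with a synchronized ambulatory Holter
    stream as the reference. Implements quality gating and contextual fusion
    of per-epoch AF probabilities, extraction of a five-dimensional set of
    spatiotemporal AF-burden features (episode frequency, duration, temporal
    clustering, circadian variability, tachycardia burden), a composite
    weighted burden score with Youden-index cutoff selection, and a full
    method-agreement suite (MAE, correlation battery, R-squared, ICC(A,1),
    Wilson intervals, ROC/PR curves, Kruskal-Wallis tests). A seeded
    synthetic-cohort generator produces paired wearable/Holter epoch streams
    with circadian episode onsets, mixed episode durations, motion-artifact
    masking and classifier noise, so the whole pipeline can be exercised
    end to end without patient data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), pROC, optparse, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
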
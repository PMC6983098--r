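Package: affectselect
Title: Cost-Constrained Wrapper Feature Selection for Emotion
    Classification from ECG and Thoracic Bioimpedance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tool-chain for classifying emotional state (neutral, sadness,
    disgust) from wearable electrocardiogram (ECG) and thoracic electrical
    bioimpedance (TEB) recordings. Implements the full feature-extraction
    pipeline (anti-aliasing and interpolated-FIR band filters, breath and
    pulse event estimators, piecewise-constant rate/amplitude streams, and
    14 summary statistics yielding 84 named features every 10 s), a
    least-squares diagonal quadratic classifier with leave-one-subject-out
    validation, an operations-per-second cost model of the deployed
    pipeline, and a genetic-algorithm wrapper feature selector under a
    computational budget that compares standard design-error fitness
    (SDEO) with a nested k-fold fitness (KFBEO) aimed at better
    generalization across subjects. A synthetic-data module emulates both
    raw biosignals and tabular feature datasets with subject-level random
    effects so the whole chain can be exercised without the original
    recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    e1071,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
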
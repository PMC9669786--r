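Package: bowelsound
Title: Simulation, Detection and Acoustic Analysis of Neonatal Bowel Sounds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for long-term abdominal sound monitoring studies in neonates.
    Generates ground-truth-annotated synthetic abdominal audio (bowel-sound
    bursts, speech and friction confounders, heartbeat and incubator noise for
    control sites) together with cohort manifests; extracts MFCC features;
    detects and classifies sound events with a deterministic spectral-energy
    baseline or a small convolutional-recurrent (CNN + bi-GRU) frame
    classifier; computes the five per-minute acoustic parameters of bowel
    sounds (rate, duration, amplitude, dominant frequency, interval) with
    loess-smoothed time curves; and runs the cohort-level statistical layer
    (site specificity controls, feeding-group comparisons, two-cohort
    contrasts, and paired phototherapy self-comparisons).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    graphics,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
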
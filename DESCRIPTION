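Package: torsade
Title: Proarrhythmia Biomarkers and Risk Stratification for the
    Methoxamine-Sensitized Rabbit Model of Torsades de Pointes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying torsades de pointes (TdP) proarrhythmia
    risk from rabbit ECG recordings: R-peak detection by a derivative
    threshold, ectopic RR cleaning with linear interpolation, a
    rabbit-specific QT rate correction, 30-difference short-term variability
    of QTc, Lomb-Scargle heart-rate variability in the LF and HF bands,
    amplitude-aware permutation entropy and an SVD-based information-exergy
    index of baseline ECG irregularity, arrhythmia event classification
    (single and multiple ectopic beats, bigeminy, TdP) with inducibility
    rules, and risk-stratification statistics (sensitivity/specificity,
    quadrant classifier, two-sample proportion test, Grubbs outlier test,
    Friedewald LDL). A seeded synthetic cohort generator produces rabbit-like
    beat series and waveforms with ground truth for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
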
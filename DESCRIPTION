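Package: swersp
Title: Event-Related Spectral Perturbation Analysis of Swallowing EEG
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools to characterize sensorimotor cortical activity during
    swallowing from multichannel EEG. Provides a synthetic cohort generator
    with controllable event-related desynchronization (ERD), EDF input and
    output, a preprocessing chain (resampling, zero-phase band-limiting,
    robust channel rejection with spatial interpolation, epoching, common
    average reference), Morlet-wavelet event-related spectral perturbation
    (ERSP) with single-trial full-epoch and pre-stimulus baseline
    corrections, band-level biomarkers (event-related oscillation, event-
    related index, hemispheric lateralization index), and a nonparametric
    statistical battery (Lilliefors, Levene, Kruskal-Wallis, Mann-Whitney
    with Cliff's delta, Wilcoxon signed-rank with rank-biserial correlation,
    chi-square) for group comparisons.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    nortest,
    car,
    yaml,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
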
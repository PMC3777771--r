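Package: megrsn
Title: Resting-State-Network Phase Lag Index Connectivity for Source-Space MEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A longitudinal functional-connectivity pipeline for source-space
    magnetoencephalography (MEG). Band-filters, downsamples and epochs per-ROI
    source time series, computes phase lag index (PLI) connectivity matrices
    from Hilbert-transform instantaneous phases, restricts connectivity to
    literature-defined resting-state networks (default mode, left/right
    frontoparietal, executive control) over a 78-region cortical atlas, anchors
    neuropsychological domain scores to baseline group statistics, and tests
    pre/post change with Wilcoxon signed-rank statistics under per-band false
    discovery rate control, followed by post-hoc Kendall tau correlations
    between connectivity change and cognitive change. Includes a coupled
    narrowband-oscillator cohort simulator with controlled pairwise phase lags,
    zero-lag instantaneous mixing as a volume-conduction surrogate, and
    injected connectivity-cognition relationships for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
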
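Package: timbresim
Title: Modeling Perceptual Similarity of Short Music Clips from Timbre Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modeling the perceived similarity of very short music
    clips (hundreds of milliseconds) from low-level acoustic features. Provides
    parametric synthesis of genre-structured stimulus sets and a reference
    corpus, simulation of the constrained free-sorting paradigm, extraction of
    timbre descriptors (gammatone/ERB spectral statistics, energy-modulation
    and zero-crossing measures) and MFCC/delta-MFCC medians, five feature
    normalization schemes including test-set and corpus rank transforms,
    pairwise absolute-difference design matrices, partial least-squares
    regression via the SIMPLS algorithm with cross-validated component
    selection, bootstrap percentile-interval feature selection over clip
    resampling, and a train/test generalization grid with correlation-based
    R-squared reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    graphics,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
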
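Package: fpvseeg
Title: Frequency-Tagging Analysis of Fast Periodic Visual Stimulation EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for fast-periodic-visual-stimulation (FPVS) oddball EEG
    experiments: construction of periodic stimulation sequences with an
    embedded category-change oddball, a seeded generator of synthetic
    multichannel EEG recordings with known injected periodic responses,
    a preprocessing chain (zero-phase band-pass and notch filtering,
    downsampling, trigger-based segmentation, regression-based blink
    removal, bad-channel interpolation, common-average referencing,
    integer-cycle cropping and epoch averaging), frequency-domain
    quantification of tagged responses (baseline-subtracted amplitude,
    signal-to-noise ratio and neighbour-bin z-scores), harmonic chunk
    summation, and group-level statistics (Benjamini-Hochberg FDR maps
    across electrodes, region-of-interest contrasts and a two-way
    repeated-measures ANOVA with Greenhouse-Geisser correction).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    yaml
Suggests:
    testthat (>= 3.0.0),
    car,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
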
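Package: expo4dct
Title: Virtual 4DCT with Exponential-Weighted Phase Reconstruction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale virtual 4DCT system for studying temporal
    gating-window weighting in respiration-correlated CT. Simulates a
    moving digital phantom under programmable respiratory waveforms,
    acquires time-stamped parallel-beam sinograms, retrospectively sorts
    projections into breathing phases, and reconstructs each phase by
    temporally weighted filtered backprojection using either the
    conventional cosine-squared gating weight or an exponential-sharpened
    (EXPO) weight. Includes the helical acquisition temporal budget
    (visibility length, transit time, breathing-period and pitch
    conditions, gating-window widening), derivative images (MIP, minIP,
    average CT), and quantitative evaluation via FWHM residual motion
    blur, difference maps and ROI noise statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    pracma,
    yaml,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
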
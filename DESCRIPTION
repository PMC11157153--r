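Package: massShiftR
Title: Mass Shift Detection and PTM Pattern Inference for True Mass Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects and quantifies mass shifts of a protein of interest in
    charge-free (true) intact-protein mass spectra, such as those produced by
    individual ion mass spectrometry, and decomposes each shift into candidate
    post-translational modification (PTM) patterns by bounded integer
    programming. Envelopes are located by sliding a fixed-size window across
    the centroided spectrum and fitting constant-width Gaussians whose quality
    is assessed with a chi-square goodness-of-fit test; accepted envelopes are
    quantified by the area under the fitted curve, aligned across samples by
    mass binning, and explained by PTM count vectors under three objective
    functions (fewest modifications, smallest mass error, or both combined)
    with enumeration of the k best solutions. A synthetic-spectrum generator
    with beta-distributed basal, vertical and horizontal noise channels and
    benchmark harnesses allow every stage to be evaluated without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    minpack.lm,
    mzR,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
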
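Package: spotbench
Title: Detection and Benchmarking of Fluorescent Subcellular Spots
Version: 0.1.0
Authors@R: person("spotbench", "developers", role = c("aut", "cre"),
    email = "spotbench@example.org")
Description: A suite of eleven detectors for small bright fluorescently
    labeled subcellular objects (vesicles, P-bodies, synaptic boutons) in
    single-channel microscope images: band-pass filtering, feature point
    detection, h-dome morphological reconstruction, kernel density
    estimation, local comparison, local enhancement filtering, granulometric
    morphometry, multiscale wavelet products, SourceExtractor-style
    background clipping, sub-pixel Gaussian localization, and top-hat
    filtering.  Includes object- and pixel-level precision/recall/F-score
    evaluation against mask or point references, exhaustive grid-search
    parameter tuning, a synthetic benchmark-scene generator with exact
    ground truth (focal stacks, dose plates, empty frames), cross-method
    similarity analysis, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    clue,
    png,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
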
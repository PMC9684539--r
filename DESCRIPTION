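Package: wipid
Title: Insect Species Identification from Wing Interference Patterns
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for species-level identification of insects (tsetse flies,
    Glossina spp.) from the structural colours of their wings. Wing
    interference patterns (WIPs) are thin-film interference colours displayed
    by transparent wing membranes against a dark background; they are stable
    within species and differ between species. The package provides a
    physics-based synthetic WIP image generator (thin-film reflectance over
    parametric membrane-thickness maps, CIE colorimetric integration to sRGB),
    dataset management with stratified k-fold cross-validation, compact
    convolutional network architectures (DarkNet-9/14, a reduced MobileNet,
    ResNet-18) with an in-package training engine, a bag-of-features SVM
    baseline, hierarchical taxonomic evaluation (genus, species complex,
    species/subspecies) with confusion matrices, and an image-perturbation
    robustness suite with traffic-light scoring.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    png,
    e1071,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
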
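Package: pipmorph
Title: Outline Morphometrics and Balanced Discriminant Inference for
    Grapevine Pips
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Elliptical Fourier analysis of grape pip (seed) outlines and
    downstream inference on domestication history. Provides two-landmark
    (Bookstein) registration of closed contours, elliptical Fourier
    decomposition with harmonic-power calibration, principal component
    morphospaces, correlation-distance UPGMA clustering of cofactor group
    means with multiscale-bootstrap AU node support, balanced-resampling
    linear discriminant ensembles with leave-one-out cross-validation and
    a shuffled-label null, posterior-probability and vote-proportion
    filtering curves, and a two-stage (wild/domesticated then cofactor)
    classification of archaeological pip assemblages. A synthetic outline
    generator reproduces the statistical structure of a modern reference
    collection so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    MASS,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
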
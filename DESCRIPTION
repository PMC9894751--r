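Package: nemaglide
Title: Steering of Gliding Filaments by Passive Nematic Defects
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how half-integer defects in a passive two-dimensional
    nematic steer an active fluid of gliding filaments. Provides generators for
    multi-defect director fields (free, random and disc-confined), extraction of
    director fields from fluorescence-style images by the structure-tensor method,
    topological defect detection and orientation from the Q tensor, a stochastic
    simulator of self-propelled particles torqued toward the local director,
    a Q-tensor streamline predictor seeded at +1/2 defects, rod tracking and
    block-matching optical flow, and quantitative read-outs such as the
    velocity-director order parameter, image correlation, defect exit-direction
    bias, chiral loop detection with enclosed topological charge, and
    edge-current statistics under circular confinement.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    tiff,
    EBImage
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
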
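Package: headswivel
Title: Euler-Angle Decomposition of Ribosomal 30S Head Swivel and Tilt
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies rigid-body motion of the small ribosomal subunit head
    domain from crystallographic or simulated coordinate models. Implements
    least-squares (Kabsch) superposition of phosphate-atom cores, construction
    of orthonormal marker frames, calibration of a pure-swivel rotation axis
    from reference structure pairs, and intrinsic z-x-z Euler-angle
    decomposition of head orientation into net swivel, tilt, and tilt
    direction. Also provides per-residue displacement decomposition into
    swivel and tilt vector components, atom-level distance and contact
    measurements (head-body gate contacts, codon-anticodon hydrogen-bond
    distances, mRNA path kink angles, nearest-phosphate searches), and a
    seedable pseudo-ribosome generator so every stage can be validated by
    parameter recovery without downloading deposited structures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
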
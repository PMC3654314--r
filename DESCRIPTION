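Package: psdred
Title: Data Reduction for Rotation-Method Single-Crystal Diffraction on a
    Curved Position-Sensitive Detector
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Reduces rotation-scan image frames from a curved large-area
    position-sensitive neutron detector to a Lorentz-corrected reflection
    intensity list.  Provides the detector-channel to diffraction-angle
    transforms, a synthetic frame simulator with Ewald-sphere spot
    prediction, two-dimensional peak search with relocating
    center-of-gravity boxes, cross-frame spot integration, UB-matrix
    auto-indexing (vector-minimum, two- and three-reflection, Monte-Carlo),
    Bravais-lattice assignment with least-squares cell refinement,
    instrument calibration fits against a standard NaCl crystal, peak
    quality classification and SHELX-style export.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, tools
Suggests: testthat (>= 3.0.0), optparse, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
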
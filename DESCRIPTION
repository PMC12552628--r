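Package: dynscatter
Title: Matrix-Based Imaging Through Dynamic Scattering Media
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Forward simulation and covariance-matrix reconstruction for
    isoplanatic imaging through rapidly varying (dynamic) scattering media.
    Generates random-phase-screen speckle point spread functions and renders
    short-exposure frame stacks in incoherent and coherent (holographic)
    modalities; reconstructs the hidden object and the per-frame scattering
    PSFs from the covariance of the measured frames by CLASS-type iterative
    Fourier phase retrieval, exploiting the commutativity of convolution that
    maps dynamic scattering of a static object onto the static-medium
    reflection-matrix problem. Includes off-axis hologram demodulation and
    Fresnel transfer-function propagation between the scattering-layer and
    object planes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tiff,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
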
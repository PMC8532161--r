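Package: gelrelax
Title: NMR Relaxometry Analysis of Starch-Sugar Confectionery Gels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Fast field cycling (FFC) and time-domain NMR relaxometry
    analysis of water dynamics in starch-sugar confectionery gels. Fits
    nuclear magnetic relaxation dispersion (NMRD) profiles with a composite
    spin-lattice relaxation model combining a log-Gaussian-distributed
    rotational (BPP-type) contribution with two Torrey-type translational
    contributions for more-mobile and less-mobile proton pools, using a
    two-stage protocol that shares spin densities across temperatures.
    Includes CPMG T2 decomposition by discrete multi-exponential fitting and
    regularized inverse Laplace transformation, synthetic-data generators
    emulating the FFC and CPMG acquisitions, a low-frequency authenticity
    discriminant, and closed-form product-quality metrics (CIELAB color
    change, texture profile descriptors).
License: MIT + file LICENSE
Encoding: UTF-8
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    pracma,
    jsonlite,
    yaml,
    withr,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
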
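Package: cortimech
Title: Organ of Corti Micromechanics: Coupled Fluid-Structure Modelling and
    OCT Vibrometry Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Finite-element modelling of the passive micromechanics of the
    excised gerbil organ of Corti mounted in a two-compartment microfluidic
    chamber, together with the measurement-side analysis chain used with
    optical-coherence-tomography (OCT) vibrometry. Builds radial sections of
    the organ of Corti from anatomic landmarks and longitudinally graded
    material properties, assembles planar frame structures with Rayleigh
    damping, couples them to an incompressible inviscid fluid through a
    discrete Laplace operator, and solves static and frequency-domain
    responses. Measurement-side tools include subpixel normalized
    cross-correlation displacement estimation, two-angle beam decomposition of
    complex motion, elliptical-motion summaries, basilar-membrane volume
    compliance and contact stiffness, and deformation-ratio metrics.
    Stiffness ratios of the tectorial membrane and Deiters cell relative to
    the hair bundle and outer hair cell are inferred by model parameter
    sweeps matched to measured deformation ratios. Synthetic two-angle scan
    and speckle-image generators make every stage testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
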
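Package: valvetwin
Title: Lumped-Parameter Digital Twin of a Heart-Valve Pulse Duplicator
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale reduced-order model of bioprosthetic aortic heart
    valve testing in a commercial pulse duplicator. Implements
    Holzapfel-Gasser-Ogden anisotropic hyperelastic leaflet constitutive
    models with collagen fiber dispersion, biaxial plane-stress response and
    material-parameter fitting; three-element Windkessel driving and loading
    circuits as an ODE system; a zero-dimensional valve surrogate with
    opening-fraction dynamics and a Bernoulli effective-orifice pressure-flow
    law; hydrodynamic validation metrics (normalized waveform discrepancy
    norms, stroke volume, forward-flow pressure difference, peak Reynolds
    number, ensemble statistics); and a seeded generator of synthetic
    pulse-duplicator experiments with cycle-to-cycle variability, sensor
    noise, low-pass filtering and leaflet flutter on the projected dynamic
    valve area signal.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    signal,
    minpack.lm,
    pracma,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
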
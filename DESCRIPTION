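Package: tendonscale
Title: Multiscale Tendon Mechanics, Organization Imaging, and ECM Stress
    Transmission Modeling
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for multiscale analysis of tendon mechanics and
    organization. Computes nonlinear cyclic-mechanics metrics (equilibrium
    stress, dynamic modulus, hysteresis, laxity, tan-delta) from tensile test
    records; fits a Gaussian fiber-recruitment model of strain stiffening;
    implements a fibrous-matrix hyperelastic constitutive law and an
    axisymmetric finite-element simulation of cell contraction with power-law
    displacement-decay analysis; quantifies collagen fiber and nuclear
    organization from polarized-light and second-harmonic-generation images
    (circular standard deviation, realignment transition, nuclear aspect
    ratio, F-actin fraction); and provides the backward stepwise multiple
    regression workflow (outlier rule, Pearson screen, tolerance gate,
    Durbin-Watson) linking macroscale and microscale variables. A synthetic
    data module generates all inputs with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    Matrix,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    lmtest
Config/testthat/edition: 3
RoxygenNote: 7.3.3
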
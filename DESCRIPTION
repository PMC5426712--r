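Package: sascov
Title: Ensemble Mean and Covariance of Small-Angle Scattering Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analytic theory and numerical tools for the ensemble statistics of
    small-angle X-ray/neutron scattering (SAS) profiles. Computes the exact
    Debye-formula intensity of an atomic structure, and, for a thermal ensemble
    in which every atom undergoes independent isotropic Gaussian displacement,
    the exact ensemble-average intensity and the second-order analytic
    covariance and correlation between profile points. Also provides numerical
    mean/covariance/confidence bands from explicit conformer sets (multi-model
    PDB ensembles), information-content diagnostics of the profile correlation
    matrix (mutual information, correlation bandwidth), synthetic structure
    generators with Monte-Carlo and quadrature oracles, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    pracma,
    stats,
    utils,
    graphics
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
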
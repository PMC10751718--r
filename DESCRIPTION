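Package: fanocavity
Title: Condensed-History Electron Transport and the Fano Cavity Test in
    Magnetic Fields
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale condensed-history Monte Carlo simulator for
    electron transport in uniform external magnetic fields, together with
    the Fano cavity consistency test used to validate charged-particle
    transport in heterogeneous detector geometries. Provides relativistic
    electron kinematics, gyroradius-based step-size restriction, an
    analytic multi-region geometry engine (nested boxes and cylinders
    with per-region density), a density-proportional isotropic Fano
    source, per-region dose tallies with history-by-history type-A
    uncertainties, and sweep/reporting tools for studying how the
    magnetic step-size fraction, region density and electron energy
    control the agreement between simulated and analytic Fano dose.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
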
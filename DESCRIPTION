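Package: activegel
Title: Competing Instabilities of Thin Active Nematic Elastomer Sheets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multiscale modelling toolkit for thin extensile active nematic
    elastomers such as crosslinked microtubule-kinesin networks. Provides
    linear-stability analysis of the competition between the in-plane bend
    instability and out-of-plane Euler-like buckling, an enzyme-kinetics map
    from molecular composition (ATP, motor clusters, passive crosslinkers,
    filament length) to coarse-grained mechanical parameters, forward phase
    diagram prediction with numerical phase-boundary tracing, exact spectral
    integration of the linearized overdamped dynamics, a blurriness image
    statistic that classifies instability direction from widefield
    fluorescence images, Bayesian (MCMC) estimation of the kinetic ratios
    from phase-diagram observations, and seeded synthetic-data generators
    for every pipeline input.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    tiff,
    jsonlite,
    yaml
Config/testthat/edition: 3
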
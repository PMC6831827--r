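Package: jiptandem
Title: Idealized Modelling and SAXS Analysis of the JIP3/4 RH1-LZI Tandem
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds idealized all-alpha dimer models of the N-terminal
    RH1-LZI tandem of the JIP3/JIP4 motor adaptors from annotated sequence
    regions and confronts them with small-angle X-ray scattering (SAXS)
    data. Provides region bookkeeping on annotated sequences (ungapped
    identities, heptad registers, average masses), Crick-parameterized
    coiled-coil and four-helix-bundle builders, Debye-formula forward
    scattering, Guinier and dimensionless Kratky analyses, pair-distance
    distributions by direct summation and by regularized indirect Fourier
    transform, Porod-volume mass estimates, Kirkwood bead-model
    hydrodynamics, simulation of beamline-like SAXS curves with
    counting-statistics noise, rigid-body refinement against SAXS data
    with flexible linkers, and ensemble selection of radius-of-gyration
    distributions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    rlang,
    seqinr,
    stats,
    tibble,
    tools,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
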
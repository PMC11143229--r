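Package: snfassembly
Title: Silk Nanofibril Assembly Analysis from Plasmon-Enhanced Infrared
    Spectra, AFM Morphometry and Molecular Configurations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying silk nanofibril (SNF) assembly on
    graphene plasmonic infrared sensors. Converts gated transmittance to
    extinction, extracts Delta-Extinction against an asymmetric-weight
    envelope baseline, deconvolves the amide I band (1600-1700 cm-1) into
    constrained beta-sheet / random-coil / turn Gaussian components with
    ensemble uncertainty, measures rod heights and band-filtered length
    distributions from AFM height maps of graphene nanoribbons, and
    computes intermolecular contact numbers, hydrogen bonds, beta-strand
    assignment and strand-axis nematic order from multi-chain
    configurations. A synthetic-data module emulates every instrument
    output (coupled plasmon-vibration oscillator spectra, stage presets
    keyed to assembly temperature and duration, rod-on-nanoribbon AFM
    images, ordered and disordered chain sets) so the full pipeline is
    testable without measured data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    Matrix,
    bio3d,
    igraph,
    jsonlite,
    minpack.lm,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
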
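Package: lhcakin
Title: Kinetic and Spectral Analysis of Far-Red Chlorophyll Antenna Complexes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and fitting of time-resolved fluorescence (TCSPC) and
    transient-absorption surfaces from pigment-protein complexes: global
    analysis by variable projection yielding decay-associated spectra (DAS)
    and lifetimes, conversion to sequential-scheme evolution-associated
    spectra (EADS), and constrained two-branch target analysis that estimates
    the fraction of chlorophyll-f-containing complexes in a mixed ensemble.
    Also provides pigment-extract spectral unmixing to per-complex
    stoichiometries, multi-Gaussian deconvolution of low-temperature
    absorption bands, and steady-state utilities (0-0 transition estimation,
    Stokes shifts, thermal gaps, excitation densities), together with a
    synthetic-data generator producing realistic fixtures for all of the
    above.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma,
    minpack.lm,
    deSolve,
    yaml
Suggests: testthat (>= 3.0.0), jsonlite, withr, Matrix
Config/testthat/edition: 3
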
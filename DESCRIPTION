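Package: fretarch
Title: In-Situ Architecture of Receptor Dimers from Single-Molecule FRET
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantitative inference chain for determining the in-situ
    architecture of ligand-mediated receptor dimers from single-molecule
    ALEX-FRET, applied to the (MET:InlB)2 complex. Simulates and corrects
    alternating-laser-excitation intensity traces (leakage, direct
    excitation, detection and excitation-balance factors), converts FRET
    efficiencies to donor-acceptor distances via Forster theory, predicts
    inter-dye distances on candidate dimer structures with grid-based
    accessible-volume simulations, models shot-noise-limited photon
    ratio histograms (photon distribution analysis), computes structural
    descriptors (domain angle, radius of gyration, RMSD, solvent-accessible
    surface and interface areas), estimates receptor cluster densities from
    single-molecule localization data (NeNA precision, temporal linking,
    DBSCAN), and scores competing dimer models against measured distances.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    graphics,
    jsonlite,
    minpack.lm,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
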
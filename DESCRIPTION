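Package: poregate
Title: Hydrophobic Gating and Pi-Helix Annotation of Ion-Channel Pore Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Structural analysis toolkit for annotating tetrameric ion-channel
    pore models as open or non-conductive. Detects backbone hydrogen bonds and
    classifies alpha/pi-helical patterns and helical defects, fits the pore
    axis and computes HOLE-style radius profiles, converts axial water number
    densities into hydration free-energy profiles, post-processes 1D potentials
    of mean force (window averaging, reference shifting, barrier extraction),
    builds register-shifted (pi-helix) models by gapped-alignment backbone
    threading, clusters ligand poses by RMSD cutoff, and evaluates drug
    ionization and membrane-partition arithmetic. Ships synthetic generators
    (ideal helices, C4 toy channels, Boltzmann-distributed water fields, noisy
    PMF windows, planted pose ensembles) so every stage is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
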
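Package: cryodose
Title: Radiation-Damage Assessment for Dose-Fractionated Cryo-EM Density Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify electron-beam radiation damage in single-particle
    cryo-EM reconstructions of metalloproteins. Reads and writes MRC/CCP4 volumes
    and PDB-style atomic models; simulates dose-fractionated frame stacks of a
    metal-cluster-containing complex with a parametric damage process (occupancy
    decay, ADP inflation, directed coordinate drift, disulfide cleavage); sums
    frame subsets into low-dose maps; locates metals and light atoms by peak
    finding and metal-density subtraction; refines cluster geometry in real space
    under progressively tightened distance restraints; and reports damage metrics
    (bond integrity, occupancy proxies, distance elongation, Fourier shell
    correlation resolution, Rosenthal-Henderson B-factors) against accumulated
    dose, with fluence-to-Gray conversion.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
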
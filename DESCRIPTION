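Package: helixlat
Title: Helical Lattice Analysis of Heteropolymeric Protein Filaments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Screw-operator algebra and lattice analysis for helical protein
    filaments assembled from more than one subunit species. Implements
    symmetry reduction of a 1-start helical lattice under a multi-strand
    species register pattern (minimal label periods, out-of-register strands,
    pseudo-strand steps, species-pair contact types), n-start strand family
    geometry and helical net diagrams, construction of 3D filament models
    from monomer coordinates by screw operators, geometric inter-subunit
    contact analysis (hydrogen-bond and salt-bridge counting, tail-core
    contact shells), and a forward rigid-body model of filament bending with
    per-subunit motion reports. Includes a synthetic-data generator that
    builds toy two-species archaellum-like filaments so that every analysis
    stage can be exercised without external structure downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    jsonlite,
    seqinr,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
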
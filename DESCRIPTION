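Package: ferrotopo
Title: Topology and Energetics of Peptide-Bound Iron-Sulfur Clusters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing why the CXXCXXC heptapeptide that encloses
    the Fe4S4 cluster of bacterial ferredoxins adopts a right-handed fold.
    Builds Cartesian models of a heptapeptide fused to an idealized
    iron-sulfur cubane from backbone and side-chain torsions, exhaustively
    enumerates a torsion grid with geometric and Lennard-Jones screens,
    classifies fold handedness by a topology angle, censuses backbone
    amide-to-sulfur hydrogen bonds with discrete distance/angle cutoffs,
    and estimates electrostatic peptide-cluster stabilization by comparing
    charged against uncharged clusters.  A survey mode scans experimental
    PDB/mmCIF structures for cluster-binding CXXCXXC motifs, and a
    synthetic-fixture generator makes every input needed for offline
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
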
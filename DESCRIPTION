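Package: coroneneFractals
Title: Topological Indices, Graph Entropy and Hueckel Spectral Descriptors
    for Coronene Fractals
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Generates the molecular graphs of three families of
    two-dimensional coronene fractals (zigzag hexagonal, armchair hexagonal
    and rectangular) by substituting a 24-carbon coronene unit at every
    vertex of a benzenoid template and fusing neighbouring units along a
    shared rim bond.  Computes modified reverse degree-based topological
    indices with a tunable shift parameter k, index-weighted graph entropy
    in bits together with structural and bond information content, Hueckel
    adjacency-spectrum energetics (total pi-electron energy, HOMO-LUMO gap,
    spectral diameter, delocalization energy, Kekule structure counts and
    Herndon resonance energy) and linear structure-property regression
    models that predict spectral properties from the indices and entropies.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, igraph
Suggests: testthat (>= 3.0.0), jsonlite, optparse, withr
Config/testthat/edition: 3
biocViews: Cheminformatics, GraphAndNetwork, MathematicalBiology
RoxygenNote: 7.3.3
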
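Package: bindsig
Title: Graph-Based Structural Signatures for Protein-Ligand Binding
    Affinity Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts the binding affinity of protein-small molecule
    complexes, expressed as -log10(Kd|Ki), from cutoff-scanning
    graph-based structural signatures: cumulative pairwise-distance
    distributions per pharmacophore-type pair, computed within the
    binding pocket and across the protein-ligand interface, concatenated
    with physicochemical descriptors of the ligand.  A Gaussian-process
    regressor maps signatures to affinity.  Includes PDBbind-style index
    parsing and train/test split protocols, scoring-function evaluation
    statistics (Pearson, Spearman, regression residual SD, Fisher r-to-z
    and F-test comparisons), a synthetic toy-complex generator for fully
    offline testing, and a command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    ChemmineOB,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    kernlab,
    jsonlite,
    optparse
Config/testthat/edition: 3
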
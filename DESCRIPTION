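Package: ligsel
Title: Ligand-Guided Model Selection and Allosteric Binding-Site Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for ligand-guided selection of GPCR homology models and
    mapping of allosteric binding sites from docking poses. Clusters positive
    allosteric modulators with circular 2D fingerprints, Tanimoto similarity,
    average-linkage trees and the Kelley-Gardner-Sutcliffe cluster-count
    penalty; assembles DUD-style property-matched, topology-dissimilar decoy
    sets; scores ranked docking tables with BEDROC/RIE early-recognition
    enrichment and applies model shortlisting rules; computes per-residue
    structural interaction fingerprints (SIFt) from protein-ligand complexes,
    aggregates them into binding-site profiles with hotspot calling, and maps
    residues onto GPCRdb class C generic numbers. Includes synthetic-data
    generators (ranked screens with controlled early enrichment, toy binding
    pockets with planted interactions, compound libraries with controlled
    property distributions) so that every stage can be exercised and validated
    without commercial modelling or docking software.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    ChemmineR,
    ChemmineOB,
    dplyr,
    generics,
    ggplot2,
    igraph,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
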
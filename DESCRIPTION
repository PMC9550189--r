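Package: karyevol
Title: Ancestral Karyotype Reconstruction and Chromosome Rearrangement Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying chromosome evolution on a dated phylogeny at
    synteny-block resolution. Simulates block-level genome evolution by
    inversion, fusion and fission with full ground truth; reconstructs
    ancestral chromosome fragments from per-species orthology maps by
    phylogeny-weighted adjacency scoring; computes exact signed-permutation
    reversal distances (Hannenhalli-Pevzner) and typed parsimony scenarios;
    calls evolutionary breakpoint regions and multispecies homologous synteny
    blocks with breakpoint-reuse classification; and provides the window-based
    enrichment statistics (gene density and length, repeat density, TAD and
    chromatin-compartment association) and branch-rate tests used in
    comparative studies of mammalian karyotype evolution.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    IRanges,
    S4Vectors,
    methods,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    knitr
Config/testthat/edition: 3
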
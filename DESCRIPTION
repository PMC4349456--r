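Package: funcdisc
Title: Gene Neighborhood Analysis for Transcriptional Regulator Function
    Discovery
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts the metabolic area regulated by a prokaryotic
    transcriptional regulator from genomic context. Homologs of a query
    regulator are selected across genomes by bidirectional best-hit
    Smith-Waterman similarity, the gene neighborhood around each homolog
    is extracted, and enzymes (EC numbers), their reaction metabolites
    and metabolic pathways are ranked by how many neighborhoods they
    recur in. Includes a seeded synthetic-pangenome generator with a
    planted conserved gene cluster for download-free end-to-end testing,
    deterministic HTML/JSON reports, and Hill-equation least-squares
    fitting of fluorescence-anisotropy titrations to estimate
    regulator-operator and effector-modulated dissociation constants.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
biocViews: ComparativeGenomics, FunctionalPrediction, Alignment,
    Pathways, Software
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'binding.R'
    'homology.R'
    'context.R'
    'datastore.R'
    'fixtures.R'
    'funcdisc-package.R'
    'report.R'
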
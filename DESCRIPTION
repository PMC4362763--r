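Package: CNVconverge
Title: Pathway Convergence Analysis of De Novo CNVs in Systematically
    Phenotyped Cohorts
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Links de novo copy-number variants (CNVs) in an ontology-phenotyped
    patient cohort to commonly perturbed molecular pathways, and tests whether
    patients sharing a perturbed pathway converge phenotypically. Provides
    ontology propagation over HPO/MPO-like DAGs, exon-aware CNV-to-gene mapping,
    hypergeometric gene-set enrichment with BH-FDR (including an
    ortholog/category-restricted mouse-knockout engine), co-expression and
    protein-protein interaction network clustering tests with degree-matched
    permutation nulls, a CNVR-randomisation bait-network extension test,
    Goodall3 frequency-weighted phenotype similarity with
    contributing/non-contributing convergence tests, multi-method candidate gene
    intersection, and a seeded synthetic-data generator with planted
    pathway-phenotype causal structure for calibration and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    igraph,
    S4Vectors,
    IRanges,
    GenomicRanges,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
biocViews: CopyNumberVariation, GeneSetEnrichment, NetworkInference, Software
RoxygenNote: 7.3.3
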
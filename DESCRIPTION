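Package: hdacPerturb
Title: Multi-Omic Analysis of HDAC Inhibitor Perturbation Experiments
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for multiplexed (TMT) perturbation proteomics
    of histone deacetylase (HDAC) inhibitor treated cell line panels.
    Computes replicate-filtered vehicle-relative log2 fold changes from
    reporter abundance matrices, counts and classifies regulated proteins
    across cell-line-by-drug condition groups (universal versus
    cell-type-specific effectors), screens for co-regulation against anchor
    proteins such as HDACs, scores kinase activities from phosphosite shifts
    by kinase-substrate enrichment analysis (KSEA) and ranks candidate
    kinases by motif score and co-regulation, classifies transcript-protein
    concordance into a nine-group scheme, calls thermal engagement from
    proteome integral solubility alteration (PISA) assays in matched cell
    and lysate arms, and performs hypergeometric over-representation
    analysis with Benjamini-Hochberg control. A seeded synthetic-data
    generator with planted ground truth makes every stage testable without
    raw mass-spectrometry data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'hdacPerturb-package.R'
    'AllGenerics.R'
    'AllClasses.R'
    'quant.R'
    'concordance.R'
    'coregulation.R'
    'enrichment.R'
    'io.R'
    'kinase.R'
    'regulation.R'
    'pisa.R'
    'simulate.R'
    'pipeline.R'
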
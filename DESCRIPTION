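Package: ProteoPersist
Title: Functional Persistence and Phylum Redundancy in Longitudinal Gut
    Metaproteomes
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for longitudinal metaproteomic analysis of host-associated
    microbial communities. Starting from per-individual protein sequence
    databases, filtered peptide-spectrum-match tables and orthology/taxonomy
    annotations, the package clusters proteins into groups at a sequence
    identity threshold, applies a unique/distinct-peptide identification rule,
    distributes shared-peptide spectral counts by spectral balancing, infers
    phylum-stratified metabolic modules from KEGG Orthology coverage, and
    computes persistence, functional-redundancy, functional-influence and
    sample-similarity statistics. A synthetic cohort generator with known
    ground truth makes the whole pipeline testable without raw mass
    spectrometry data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    S4Vectors,
    IRanges,
    SummarizedExperiment,
    mclust,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Proteomics, MassSpectrometry, Metagenomics, Microbiome, Software
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'ProteoPersist-package.R'
    'annotation.R'
    'balancing.R'
    'grouping.R'
    'io.R'
    'modules.R'
    'persistence.R'
    'pipeline.R'
    'simulate.R'
    'utils.R'
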
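Package: apaSwitch
Title: Poly(A)-Site Calling and Temperature-Dependent Alternative
    Polyadenylation Switch Detection from 3' End Sequencing
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing alternative polyadenylation (APA) from
    3' end sequencing read data. Provides poly(A)-site (PAS) calling by
    greedy clustering of per-read cleavage positions, sequence-based
    removal of internal-priming artifacts and of sites lacking a
    polyadenylation signal, rule-based 3'UTR extension and gene
    assignment, negative-binomial differential PAS usage between two
    condition groups with tiered proximal/distal pair selection and
    class I/II switch labelling, differential gene expression calling,
    quantification of enhancer-reporter activity from two-channel flow
    cytometry event tables, and a synthetic-data generator with planted
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    SummarizedExperiment,
    rtracklayer,
    edgeR,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr,
    withr
Config/testthat/edition: 3
biocViews: Transcriptomics, AlternativePolyadenylation, Sequencing,
    DifferentialExpression, Software
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'apaSwitch-package.R'
    'utils.R'
    'simulate.R'
    'calling.R'
    'filters.R'
    'assign.R'
    'diffusage.R'
    'gating.R'
    'pipeline.R'
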
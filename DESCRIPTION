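Package: regprior
Title: Prioritization of Candidate Transcriptional Regulators from
    Epigenomic and Coexpression Evidence
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies candidate transcriptional regulators of a target
    gene by dissecting its locus into cis-regulatory elements (CREs) from
    histone-mark and DNase accessibility evidence, counting predicted
    transcription-factor binding sites in those elements with
    exact-p-value position weight matrix scanning (the "Bumscore"),
    correlating regulator and target expression, and combining binding,
    coexpression and promoter accessibility into a rank-product composite
    score with explicit candidate-selection rules. Also provides
    ChIP-peak-to-TSS target assignment, differential-expression crosstabs,
    CPM normalization and expression filters, and Fisher-exact geneset
    enrichment. A synthetic-data module generates loci with planted
    regulators so that every stage of the pipeline can be validated
    against known ground truth without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    edgeR,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: Transcription, GeneRegulation, MotifAnnotation, Epigenetics,
    ChIPSeq, Software
RoxygenNote: 7.3.3
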
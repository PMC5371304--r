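Package: cirrnet
Title: Coding and Non-Coding Gene Regulatory Network Analysis of Liver Cirrhosis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of a coding/non-coding regulatory
    network workflow for liver cirrhosis and hepatocellular carcinoma:
    quantile normalization and lncRNA identifier harmonization for
    microarray expression, small RNA-seq read quality control and TPM
    quantification, empirical-Bayes moderated-t differential expression
    with Benjamini-Hochberg FDR, TF-miRNA-mRNA and lncRNA-miRNA-mRNA
    network construction from promoter binding sites and target tables,
    shared-miRNA ceRNA inference with protein-protein interaction
    overlay and immune-response flagging, hypergeometric GO enrichment,
    and two-contrast overlap analysis. A seeded synthetic-data generator
    with planted differential expression, planted regulatory edges and a
    planted enriched term provides a fully self-contained benchmark.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    withr,
    igraph,
    Biostrings,
    S4Vectors,
    IRanges,
    GenomicRanges
Suggests:
    testthat (>= 3.0.0),
    limma
Config/testthat/edition: 3
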
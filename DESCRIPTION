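Package: noncpg
Title: Context-Stratified Clustering of Non-CpG DNA Methylomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing non-CpG (CHG/CHH) DNA methylation across
    tissues and individuals from bisulfite cytosine-level calls. Provides
    strand-aware trinucleotide (CNN) context annotation against a reference
    genome, depth and "commonly methylated" (non-zero in every sample) site
    filtering, per-context methylation matrices, from-scratch agglomerative
    hierarchical clustering of samples (complete, UPGMA and WPGMA linkage,
    Euclidean distance), a dendrogram composition score that quantifies
    tissue-driven versus individual-driven clustering (individual triads,
    same-individual tissue pairs, tissue-pure clusters, outliers), duplicate
    concordance and genomic-feature summaries, and a seeded synthetic
    multi-tissue multi-individual methylome generator with context-specific
    tissue-lineage and individual effects and binomial read sampling.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    data.table,
    jsonlite,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    ape,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
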
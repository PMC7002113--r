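Package: srnapipe
Title: Discovery and Community Analysis of Small Noncoding RNAs from
    Metatranscriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Classifies assembled transcripts from strand-specific
    (meta)transcriptomic data against a metagenome annotation into
    intergenic and antisense small noncoding RNAs (sRNAs), applies
    noncoding, homology, coverage and contig-edge filters, quantifies
    expression with contig-abundance normalization, performs a
    negative-binomial Wald test for differential expression with
    Benjamini-Hochberg FDR control, and provides community analytics:
    weighted-vote contig taxonomy, antisense/target overlap geometry,
    cross-replicate expression correlation, upstream region extraction,
    and sRNA-target interaction density summaries. A synthetic-community
    generator produces fully ground-truthed inputs for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    jsonlite,
    methods,
    rtracklayer,
    stats,
    tools,
    utils
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
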
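Package: tcgtscope
Title: Transposable-Element-Driven Regulatory Activity from Transcript,
    Peak and Methylation Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects and characterizes transposable-element (TE) driven
    regulatory activity in transcriptome, ChIP peak, expression and CpG
    methylation data. Calls transpochimeric gene transcripts (TcGTs, i.e.
    transcripts initiating inside an LTR and splicing into an annotated
    gene), aggregates them and tests per-subfamily hypergeometric
    enrichment; curates RepeatMasker-style repeat annotation (fragment
    reassembly, LTR/internal merging into full-length ERVs, solo-LTR
    flagging, exon exclusion); assigns ChIP peaks to TE subfamilies with
    genomic-size-corrected binomial enrichment, replicate consensus peaks
    and 50-kb gene-proximity Fisher tests; TMM-normalizes gene+TE count
    matrices and clusters TE loci into temporal expression patterns;
    averages RRBS CpG methylation per TE locus and compares locus sets;
    post-processes gapped multiple alignments into trimmed signal
    profiles; and scores cross-species TE locus conservation and KRAB
    zinc finger protein fingerprint similarity. A seeded synthetic-data
    generator emits a fully self-consistent toy dataset with planted
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    Biostrings,
    rtracklayer,
    edgeR,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
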
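Package: methCompare
Title: Comparative Analysis of Bisulfite-Sequencing Methylomes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparative whole-genome bisulfite sequencing (BS-seq)
    analysis across cell lines: per-cytosine methylation calling with
    CG/CHG/CHH context classification and a read-level bisulfite
    non-conversion filter; cross-line conservation, flanking-motif and
    strand-symmetry statistics; 1-kb-window differential methylation with
    permutation-based FDR; bisulfite-aware heterozygous SNP calling;
    allele-specific expression and allele-specific methylation testing with
    read-backed phasing; and a screen correlating methylation changes at
    transcription-factor binding sites with expression changes of their
    target genes. A seeded synthetic-data generator produces diploid
    genomes, methylomes, aligned bisulfite reads, RNA allele counts and
    expression tables with planted truth, so every stage has a
    parameter-recovery test.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: DNAMethylation, DifferentialMethylation, Epigenetics,
    Sequencing, SNP
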
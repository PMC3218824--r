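test_that("exact tests match brute-force enumeration for all n <= 20", {
    for (n in c(1L, 5L, 12L, 20L)) {
        for (p in c(0.5, 0.3, 0.85, 0, 1)) {
            for (k in 0:n) {
                expect_equal(binomTwoSided(k, n, p),
                             enumBinomTwoSided(k, n, p),
                             tolerance = 1e-12,
                             label = sprintf("binom k=%d n=%d p=%g", k, n, p))
            }
        }
    }
    ## hypergeometric upper tail against enumeration
    for (N in c(8L, 15L, 20L)) {
        for (K in c(3L, N %/% 2)) {
            for (nd in c(2L, 5L)) {
                for (k in 0:min(K, nd)) {
                    expect_equal(hyperUpperTail(k, K, nd, N),
                                 enumHyperUpper(k, K, nd, N),
                                 tolerance = 1e-12)
                }
            }
        }
    }
    ## worked values
    expect_equal(binomTwoSided(10, 10, 0.5), 2 / 2^10, tolerance = 1e-12)
    expect_equal(binomTwoSided(12, 14, 0.5), 2 * (91 + 14 + 1) / 2^14,
                 tolerance = 1e-12)
    expect_equal(binomTwoSided(5, 10, 0.5), 1, tolerance = 1e-12)
    expect_equal(hyperUpperTail(4, 10, 4, 20), 210 / 4845,
                 tolerance = 1e-12)
    expect_equal(hyperUpperTail(0, 10, 4, 20), 1)
    ## agrees with the stock implementation away from ties
    for (k in c(0L, 3L, 9L))
        expect_equal(binomTwoSided(k, 12, 0.5),
                     binom.test(k, 12, 0.5)$p.value, tolerance = 1e-10)
})

test_that("SNP caller applies the coverage, main-fraction and balance rules", {
    ## 10 reads at a non-C position showing 5 A / 5 G -> heterozygous
    g <- tinyGenome(c(c1 = paste0(strrep("T", 9), "A", strrep("T", 10))))
    rd <- mkReads("c1", rep(7L, 10), rep(c("W", "C"), 5),
                  c(rep("TTATTTT", 5), rep("TTGTTTT", 5)))
    snp <- callSnps(rd, g, minCov = 8L)
    expect_equal(nrow(snp), 1L)
    expect_equal(snp$pos, 10L)
    expect_setequal(c(snp$allele1, snp$allele2), c("A", "G"))
    expect_equal(snp$coverage, 10L)
    expect_equal(snp$count1 + snp$count2, 5)   # strand-averaged

    ## 8 reads 7 A / 1 G: unbalanced, not heterozygous
    rd2 <- mkReads("c1", rep(7L, 8), rep(c("W", "C"), 4),
                   c(rep("TTATTTT", 7), "TTGTTTT"))
    expect_equal(nrow(callSnps(rd2, g, minCov = 8L)), 0L)
    aud <- callSnps(rd2, g, minCov = 8L, audit = TRUE)
    expect_true(aud$unbalanced)

    ## C/T alleles at a genomic C: conversion-ambiguous, never called
    gc <- tinyGenome(c(c1 = paste0(strrep("A", 9), "C", strrep("A", 10))))
    rdc <- mkReads("c1", rep(7L, 12), rep(c("W", "C"), 6),
                   rep(c("AACAAAA", "AACAAAA", "AATAAAA", "AATAAAA"), 3))
    expect_equal(nrow(callSnps(rdc, gc, minCov = 8L)), 0L)
    audc <- callSnps(rdc, gc, minCov = 8L, audit = TRUE)
    expect_equal(nrow(audc), 1L)
    expect_equal(nrow(callSnps(rdc, gc, minCov = 8L)), 0L)
    audc <- callSnps(rdc, gc, minCov = 8L, audit = TRUE)
    expect_true(all(audc$c_ambiguous_excluded))
    expect_true(all(audc$low_main_fraction))
})

test_that("SNP caller recovers planted heterozygous sites on clean reads", {
    study <- defaultStudy()
    snps <- callSnps(study$reads[, readCols], study$genome)
    truthKey <- paste(study$snps$chrom, study$snps$pos)
    callKey <- paste(snps$chrom, snps$pos)
    expect_gte(mean(callKey %in% truthKey), 0.95)      # precision
    callable <- !study$snps$at_cg
    expect_gte(mean(truthKey[callable] %in% callKey), 0.75)
    ## the C/T-at-C class is structurally uncallable
    expect_equal(sum(truthKey[!callable] %in% callKey), 0L)
})

test_that("exonic SNP mapping respects exons and the RNA floor", {
    study <- defaultStudy()
    genes <- study$annotations$genes
    b <- S4Vectors::mcols(genes)$blocks[[1]]
    cn <- as.character(GenomicRanges::seqnames(genes))[1]
    exonPos <- as.integer(b[1, "start"] + 5L)       # inside first exon
    intronPos <- as.integer(b[1, "end"] + 50L)      # inside first intron
    snps <- data.frame(chrom = cn, pos = c(exonPos, intronPos),
                       allele1 = "A", allele2 = "T",
                       count1 = 5, count2 = 5, coverage = 20L)
    rna <- data.frame(chrom = cn, pos = c(exonPos, exonPos, intronPos,
                                          intronPos),
                      allele = c("A", "T", "A", "T"),
                      count = c(6L, 2L, 10L, 10L))
    ex <- mapExonicSnps(snps, rna, genes)
    expect_equal(nrow(ex), 1L)                       # intron SNP absent
    expect_equal(ex$pos, exonPos)
    expect_equal(ex$rna_major, 6L)
    expect_equal(ex$rna_minor, 2L)
    ## below the 4-read floor the SNP is dropped
    rna$count <- c(2L, 1L, 0L, 0L)
    expect_equal(nrow(mapExonicSnps(snps, rna, genes)), 0L)
})

test_that("gene-level ASE test matches the printed threshold behaviour", {
    mk <- function(gene, major, minor)
        data.frame(gene_id = gene, chrom = "c1", pos = 1L,
                   major_allele = "A", minor_allele = "T",
                   rna_major = major, rna_minor = minor,
                   multi_gene = FALSE)
    ase <- aseTest(rbind(mk("g1", 10L, 0L), mk("g2", 5L, 5L)), q = 0.5)
    expect_equal(ase$p_value[ase$gene_id == "g1"], 0.001953125,
                 tolerance = 1e-9)
    expect_equal(ase$p_value[ase$gene_id == "g2"], 1)
    ## 10/0 clears the 0.0027 cutoff quoted for a 1% FDR; 12/2 does not
    expect_lt(binomTwoSided(10, 10, 0.5), 0.0027)
    expect_gt(binomTwoSided(12, 14, 0.5), 0.0027)
    ## per-gene sums across SNPs
    two <- aseTest(rbind(mk("g3", 6L, 1L), mk("g3", 6L, 1L)), q = 0.5)
    expect_equal(two$major_total, 12L)
    expect_equal(two$n_snps, 2L)
})

test_that("BH calibration keeps the null false-positive rate in check", {
    set.seed(5)
    exonic <- data.frame(gene_id = sprintf("g%04d", 1:600),
                         chrom = "c1", pos = seq_len(600),
                         allele1 = "A", allele2 = "T")
    cfg <- simulationConfig(rnaDepth = 100L)
    rna <- simulateRnaCounts(exonic, data.frame(gene_id = character(0),
                                                bias = numeric(0)), cfg)
    key <- paste(rna$chrom, rna$pos, rna$allele)
    n1 <- rna$count[match(paste("c1", exonic$pos, "A"), key)]
    es <- data.frame(gene_id = exonic$gene_id, chrom = "c1",
                     pos = exonic$pos, major_allele = "A",
                     minor_allele = "T",
                     rna_major = pmax(n1, 100L - n1),
                     rna_minor = pmin(n1, 100L - n1),
                     multi_gene = FALSE)
    ase <- aseTest(es, q = 0.01)
    expect_lte(mean(ase$significant), 0.015)
    thr <- calibrateThreshold(ase$p_value, 0.01)
    expect_true(all(ase$p_value[ase$significant] <= thr))
})

test_that("imprinted-gene enrichment decreases with more significant hits", {
    universe <- sprintf("g%02d", 1:40)
    imprinted <- universe[1:8]
    pvals <- vapply(0:8, function(k) {
        sig <- c(imprinted[seq_len(k)],
                 setdiff(universe, imprinted)[seq_len(10 - k)])
        imprintedEnrichment(sig, imprinted, universe)$p_value
    }, numeric(1))
    expect_true(all(diff(pvals) < 0))
    expect_equal(pvals[1], 1, tolerance = 1e-9)
    expect_error(imprintedEnrichment("g01", "zz", universe), "testable")
})
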
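test_that("read segregation assigns by allele and skips ambiguity", {
    g <- tinyGenome(c(c1 = paste0(strrep("T", 9), "A", strrep("T", 10))))
    snp <- data.frame(chrom = "c1", pos = 10L, allele1 = "A",
                      allele2 = "G")
    rd <- mkReads("c1", c(rep(7L, 10), 15L), "W",
                  c(rep("TTATTTT", 5), rep("TTGTTTT", 5), "TTTTT"))
    grp <- segregateReads(rd, snp)
    expect_length(grp$group1, 5L)
    expect_length(grp$group2, 5L)
    expect_length(grp$unassigned, 0L)    # the last read doesn't cover
    ## Crick reads cannot distinguish a G allele from converted A
    rdCrick <- mkReads("c1", rep(7L, 2), "C", c("TTGTTTT", "TTATTTT"))
    expect_length(segregateReads(rdCrick, snp)$unassigned, 2L)

    ## a sequencing-error base joins neither group
    rdE <- mkReads("c1", 7L, "W", "TTCTTTT")
    expect_length(segregateReads(rdE, snp)$group1, 0L)
    expect_equal(segregateReads(rdE, snp)$unassigned, 1L)

    ## C allele observed as C/T by a Watson read is ambiguous
    snpC <- data.frame(chrom = "c1", pos = 10L, allele1 = "C",
                       allele2 = "A")
    rdW <- mkReads("c1", c(7L, 7L), c("W", "C"),
                   c("TTTTTTT", "TTTTTTT"))
    gC <- segregateReads(rdW, snpC)
    ## W read's T is conversion-ambiguous; Crick T matches neither allele
    expect_setequal(gC$unassigned, c(1L, 2L))
    expect_length(gC$group1, 0L)
    expect_length(gC$group2, 0L)
})

test_that("double binomial test is symmetric and exact", {
    ## degenerate extremes
    expect_equal(asmTest(10L, 10L, 0L, 10L), 0)
    expect_equal(asmTest(0L, 10L, 10L, 10L), 0)
    ## similar groups are far from significant
    expect_gt(asmTest(8L, 10L, 7L, 10L), 0.5)
    ## identical counts give the maximal-likelihood outcome
    expect_gte(asmTest(5L, 10L, 5L, 10L), binomTwoSided(5, 10, 0.5))
    ## symmetry under label swap (property over a grid)
    set.seed(2)
    for (i in 1:50) {
        n1 <- sample(1:15, 1); n2 <- sample(1:15, 1)
        k1 <- sample(0:n1, 1); k2 <- sample(0:n2, 1)
        expect_equal(asmTest(k1, n1, k2, n2), asmTest(k2, n2, k1, n1))
    }
})

test_that("site-level scan recovers planted ASM with controlled errors", {
    ## count-level simulation: planted gap 0.8 vs equal-probability nulls
    set.seed(8)
    n <- 12L
    nSig <- 300L
    k1 <- rbinom(nSig, n, 0.9)
    k2 <- rbinom(nSig, n, 0.1)
    p <- asmTest(k1, rep(n, nSig), k2, rep(n, nSig))
    expect_gte(mean(p.adjust(p, "BH") <= 0.05), 0.9)   # sensitivity
    ## truly-equal sites alone are rarely flagged
    kn1 <- rbinom(1000, n, 0.5); kn2 <- rbinom(1000, n, 0.5)
    pn <- asmTest(kn1, rep(n, 1000), kn2, rep(n, 1000))
    expect_lte(mean(p.adjust(pn, "BH") <= 0.05), 0.05)
})

test_that("asmScan + phasing reconstruct planted allele patterns", {
    cfg <- cleanConfig(genomeLength = 3e4, nGenes = 6L, snpRate = 8e-3,
                       coverage = 60, readLength = 100L,
                       asmFraction = 0.5, nDmr = 0L, nConservedDmr = 0L,
                       nMotifs = 1L, sitesPerMotif = 1L, motifEffects = -2)
    study <- cachedStudy("asmDense", cfg)
    rd <- study$reads[, readCols]
    snps <- callSnps(rd, study$genome)
    asm <- asmScan(rd, snps, study$genome)
    expect_gt(nrow(asm), 20)
    tk <- with(study$truth$asm_sites, paste(chrom, pos, strand))
    ak <- paste(asm$chrom, asm$pos, asm$strand)
    isTruth <- ak %in% tk
    well <- pmin(asm$total1, asm$total2) >= 10
    expect_gt(sum(isTruth & well), 5)
    expect_gte(mean(asm$significant[isTruth & well]), 0.9)
    ## equal-probability candidates stay mostly unflagged
    expect_lte(mean(asm$significant[!isTruth]), 0.05)
    ## the reported fraction matches the flags
    expect_equal(attr(asm, "fraction_significant"), mean(asm$significant))

    ## phasing: alleles reconstruct all-methylated vs all-unmethylated
    sigSites <- asm[isTruth & well & asm$significant, ]
    snp <- snps[snps$pos == sigSites$snp_pos[1], ][1, ]
    cg <- study$sites[study$sites$context3 == "CG", ]
    ph <- phaseMethylation(rd, snp, cg, study$genome)
    linked <- ph[!is.na(ph$frac1) & !is.na(ph$frac2) &
                 paste(ph$chrom, ph$pos, ph$strand) %in% tk, ]
    expect_gt(nrow(linked), 0)
    oneZero <- all(linked$frac1 == 1 & linked$frac2 == 0) ||
        all(linked$frac1 == 0 & linked$frac2 == 1)
    expect_true(oneZero)
    ## pooled, unphased levels sit near one half at those sites
    pooled <- callMethylation(rd, study$genome)
    pt <- methTable(pooled)
    i <- match(paste(linked$chrom, linked$pos, linked$strand),
               paste(pt$chrom, pt$pos, pt$strand))
    lev <- (pt$meth / pt$total)[i]
    expect_true(all(lev > 0.2 & lev < 0.8))
})

test_that("gene-level enrichment flags dense ASM genes only", {
    ## 12/12 significant at a global rate of 0.14: the mir663-style cluster
    tab <- data.frame(gene_id = c("dense", "sparse", "tiny"),
                      n_tested = c(12L, 12L, 2L),
                      n_significant = c(12L, 1L, 2L))
    res <- geneAsmEnrichment(tab, globalRate = 0.14, q = 0.05)
    expect_equal(nrow(res), 2L)                       # tiny excluded
    expect_equal(res$p_value[res$gene_id == "dense"], 0.14^12,
                 tolerance = 1e-9)
    expect_true(res$enriched[res$gene_id == "dense"])
    expect_false(res$enriched[res$gene_id == "sparse"])
    expect_equal(geneAsmEnrichment(data.frame(gene_id = "g",
                                              n_tested = 5L,
                                              n_significant = 0L),
                                   0.2)$p_value, 1)
    ## null simulation: few genes flagged
    set.seed(9)
    nt <- rep(20L, 200L)
    ns <- rbinom(200, nt, 0.1)
    null <- geneAsmEnrichment(data.frame(gene_id = sprintf("g%d", 1:200),
                                         n_tested = nt,
                                         n_significant = ns), 0.1)
    expect_lte(mean(null$enriched), 0.05)
})
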
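test_that("generation is deterministic and structurally valid", {
    cfg <- simulationConfig(seed = 12)
    g1 <- simulateGenome(cfg)
    g2 <- simulateGenome(cfg)
    expect_identical(as.character(g1$genome), as.character(g2$genome))
    genes <- g1$annotations$genes
    expect_equal(length(genes), 20L)
    lens <- setNames(Biostrings::width(g1$genome), names(g1$genome))
    for (i in seq_along(genes)) {
        b <- S4Vectors::mcols(genes)$blocks[[i]]
        expect_true(all(b[, "end"] <= lens[as.character(
            GenomicRanges::seqnames(genes))[i]]))
        expect_true(all(b[, "start"] < b[, "end"]))
    }
    ## every simulated 3' intron boundary ends in AG on the coding strand
    raw <- as.character(g1$genome[[1]])
    for (i in seq_along(genes)) {
        b <- S4Vectors::mcols(genes)$blocks[[i]]
        st <- as.character(GenomicRanges::strand(genes))[i]
        if (nrow(b) < 2) next
        for (e in 2:nrow(b)) {
            if (st == "+") {
                acc <- substr(raw, b[e, "start"] - 1L, b[e, "start"])
                expect_equal(acc, "AG")
            } else {
                acc <- substr(raw, b[e - 1L, "end"] + 1L,
                              b[e - 1L, "end"] + 2L)
                expect_equal(acc, "CT")   # reverse complement of AG
            }
        }
    }
    ## same seed, same SNP truth; snpRate 0 leaves haplotypes identical
    d1 <- simulateDiploid(g1$genome, cfg)
    d2 <- simulateDiploid(g1$genome, cfg)
    expect_identical(d1$snps, d2$snps)
    d0 <- simulateDiploid(g1$genome, simulationConfig(seed = 12,
                                                      snpRate = 0))
    expect_identical(as.character(d0$hap1), as.character(d0$hap2))
})

test_that("SNP counts follow the configured rate within Poisson bounds", {
    cfg <- simulationConfig(seed = 3, snpRate = 1e-3)
    g <- simulateGenome(cfg)
    d <- simulateDiploid(g$genome, cfg)
    L <- sum(Biostrings::width(g$genome))
    expected <- L * 1e-3
    expect_lt(abs(nrow(d$snps) - expected), 4 * sqrt(expected))
    ## never on N, biallelic, configured C/G fraction approximately
    expect_true(all(d$snps$ref != d$snps$alt))
    expect_equal(mean(d$snps$at_cg), 0.15, tolerance = 0.12)
})

test_that("methylation probabilities reproduce the planted structure", {
    ## TACAG mean 0.22 within +/-0.02 at >= 1000 sites (larger genome)
    cfg <- simulationConfig(seed = 4, genomeLength = 6e5, nGenes = 30L)
    st <- cachedStudy("meth600k", cfg, reads = FALSE)
    tac <- st$sites$is_tacag
    expect_gte(sum(tac), 1000)
    expect_lt(abs(mean(st$probs[[1]][tac, 1]) - 0.22), 0.02)

    ## fully symmetric configuration shares dyad probabilities exactly
    cfgS <- simulationConfig(seed = 5, symmetricFraction = 1)
    gS <- simulateGenome(cfgS)
    mS <- simulateMethylomes(gS$genome, gS$annotations, cfgS)
    s <- mS$sites
    plus <- which(s$context3 == "CG" & s$strand == "+")
    i <- match(paste(s$chrom[plus], s$pos[plus] + 1L, "-"),
               paste(s$chrom, s$pos, s$strand))
    ok <- !is.na(i)
    ## exclude planted overrides (binding sites shift individual strands)
    p1 <- mS$probs[[1]][plus[ok], 1]; p2 <- mS$probs[[1]][i[ok], 1]
    expect_gt(mean(p1 == p2), 0.95)

    ## ASM genes separate the alleles by the configured gap
    st2 <- defaultStudy()
    tk <- with(st2$truth$asm_sites, paste(chrom, pos, strand))
    idx <- match(tk, paste(st2$sites$chrom, st2$sites$pos,
                           st2$sites$strand))
    expect_true(all(st2$probs[[1]][idx, 1] - st2$probs[[1]][idx, 2] >= 1))
})

test_that("read simulation obeys the planted probabilities and coverage", {
    ## probability-1 CG sites: every overlapping W read shows C;
    ## probability-0 sites show T (clean reads)
    study <- defaultStudy()
    m <- callMethylation(study$reads[, readCols], study$genome)
    tab <- methTable(m)
    key <- paste(tab$chrom, tab$pos, tab$strand)
    skey <- paste(study$sites$chrom, study$sites$pos, study$sites$strand)
    pooled <- rowMeans(study$probs[[1]])
    i <- match(key, skey)
    ones <- which(study$probs[[1]][i, 1] == 1 &
                  study$probs[[1]][i, 2] == 1)
    expect_true(all(tab$meth[ones] == tab$total[ones]))
    zeros <- which(pooled[i] == 0)
    expect_true(all(tab$meth[zeros] == 0))
    ## mean position depth within 10% of the coverage parameter (each
    ## strand-specific cytosine site sees half the reads)
    L <- sum(Biostrings::width(study$genome))
    expect_lt(abs(nrow(study$reads) * 75 / L - 30), 3)
    expect_lt(abs(mean(tab$total) - 15), 1.5)
    ## byte-identical reads from the same config
    cfgT <- cleanConfig(genomeLength = 2e4, nGenes = 3L, nMotifs = 1L,
                        sitesPerMotif = 1L, motifEffects = -2)
    g <- simulateGenome(cfgT)
    d <- simulateDiploid(g$genome, cfgT)
    mm <- simulateMethylomes(g$genome, g$annotations, cfgT)
    r1 <- simulateBsReads(list(hap1 = d$hap1, hap2 = d$hap2), mm$sites,
                          mm$probs[[1]], cfgT)
    r2 <- simulateBsReads(list(hap1 = d$hap1, hap2 = d$hap2), mm$sites,
                          mm$probs[[1]], cfgT)
    expect_identical(r1, r2)
})

test_that("non-conversion and error knobs leave detectable traces", {
    cfg <- simulationConfig(seed = 6, genomeLength = 2e4, nGenes = 3L,
                            nMotifs = 1L, sitesPerMotif = 1L,
                            motifEffects = -2,
                            nonConversionRate = 0.2, errorRate = 0)
    g <- simulateGenome(cfg)
    d <- simulateDiploid(g$genome, cfg)
    mm <- simulateMethylomes(g$genome, g$annotations, cfg)
    rd <- simulateBsReads(list(hap1 = d$hap1, hap2 = d$hap2), mm$sites,
                          mm$probs[[1]], cfg)
    frac <- mean(isNonconverted(rd[, readCols], g$genome))
    ## most unconverted reads carry >= 3 non-CG cytosines and are caught
    expect_gt(frac, 0.1)
    expect_lt(frac, 0.25)
    m <- callMethylation(rd[, readCols], g$genome)
    expect_gt(attr(m, "nonconverted"), 0)
})

test_that("RNA counts and expression encode the planted effects", {
    cfg <- simulationConfig(rnaDepth = 60L)
    snps <- data.frame(gene_id = rep(c("g1", "g2"), each = 2),
                       chrom = "c1", pos = 1:4,
                       allele1 = "A", allele2 = "T")
    rna <- simulateRnaCounts(snps, data.frame(gene_id = "g1", bias = 1),
                             cfg)
    a1 <- rna$count[rna$allele == "A"]
    expect_equal(a1[1:2], c(60L, 60L))       # bias 1: minor allele 0
    ## balanced genes: two-sided binomial significant ~5% of the time
    set.seed(10)
    big <- data.frame(gene_id = sprintf("g%03d", 1:600), chrom = "c1",
                      pos = 1:600, allele1 = "A", allele2 = "T")
    cfg100 <- simulationConfig(rnaDepth = 100L)
    r <- simulateRnaCounts(big, data.frame(gene_id = character(0),
                                           bias = numeric(0)), cfg100)
    n1 <- r$count[match(paste(big$pos, "A"), paste(r$pos, r$allele))]
    pv <- binomTwoSided(n1, rep(100L, 600), 0.5)
    ## exact expected rejection rate of the discrete test at alpha 0.05
    exact <- sum(dbinom(0:100, 100, 0.5) *
                 (binomTwoSided(0:100, rep(100L, 101), 0.5) < 0.05))
    se <- sqrt(exact * (1 - exact) / 600)
    expect_lt(abs(mean(pv < 0.05) - exact), 3 * se)
    expect_lt(abs(mean(pv < 0.05) - 0.05), 0.04)

    ## noiseless repressive motif: methylation and expression at r = -1
    cfgE <- simulationConfig(seed = 11, exprNoiseSd = 0, nMotifs = 1L,
                             sitesPerMotif = 10L, motifEffects = -2)
    g <- simulateGenome(cfgE)
    mm <- simulateMethylomes(g$genome, g$annotations, cfgE)
    expr <- simulateExpression(
        S4Vectors::mcols(g$annotations$genes)$name, g$annotations$tfbs,
        mm$truth$tfbs_meth, g$motifs, cfgE)
    gi <- match(S4Vectors::mcols(g$annotations$tfbs)$gene, rownames(expr))
    dm <- mm$truth$tfbs_meth[, 2] - mm$truth$tfbs_meth[, 1]
    de <- log2(expr[gi, 2] + 1) - log2(expr[gi, 1] + 1)
    expect_equal(unname(cor(dm, de)), -1, tolerance = 1e-9)
})

test_that("configuration validation rejects impossible requests", {
    expect_error(simulationConfig(genomeLength = 5e3), "10 kb")
    expect_error(simulationConfig(aseBias = 1.5), "in \\[0,1\\]")
    expect_error(simulationConfig(nMotifs = 5L, sitesPerMotif = 10L,
                                  motifEffects = rep(-1, 5)),
                 "exceed")
    expect_error(simulationConfig(nonsense = 1), "unknown config")
    ## too many genes for the genome: capacity error
    expect_error(simulateGenome(simulationConfig(
        genomeLength = 1.2e4, nGenes = 10L, nMotifs = 1L,
        sitesPerMotif = 1L, motifEffects = -1)), "capacity")
})
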
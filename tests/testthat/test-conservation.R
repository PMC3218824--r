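test_that("level binning uses the printed integer edges", {
    expect_equal(as.character(categorizeLevel(0.50, 5L, "CG")), "medium")
    expect_equal(as.character(categorizeLevel(0.33, 5L, "CG")), "low")
    expect_equal(as.character(categorizeLevel(0.67, 5L, "CG")), "high")
    expect_equal(as.character(categorizeLevel(0, 0L, "nonCG")), "none")
    expect_equal(as.character(categorizeLevel(0.31, 3L, "nonCG")), "high")
    expect_equal(as.character(categorizeLevel(0.30, 3L, "nonCG")), "low")
})

test_that("self-comparison is diagonal with conserved fraction one", {
    study <- defaultStudy()
    set.seed(11)
    m <- simulateSiteCounts(study$sites, rowMeans(study$probs[[1]]), 30)
    cs <- conservationContingency(m, m, "CG")
    expect_equal(concordantFraction(cs), 1)
    expect_equal(sum(cs@observed) - sum(diag(cs@observed)), 0)
    ## marginals of expected equal marginals of observed (exact)
    expect_equal(rowSums(cs@expected), rowSums(cs@observed))
    expect_equal(colSums(cs@expected), colSums(cs@observed))
})

test_that("independent lines give folds near one; shared lines do not", {
    study <- defaultStudy()
    cg <- study$sites$context3 == "CG"
    sites <- study$sites[cg, ]
    drawMix <- function(n) ifelse(runif(n) < 0.25, rbeta(n, 1, 9),
                                  rbeta(n, 9, 1))
    set.seed(21)
    mA <- simulateSiteCounts(sites, drawMix(nrow(sites)), 30)
    mB <- simulateSiteCounts(sites, drawMix(nrow(sites)), 30)
    cs <- conservationContingency(mA, mB, "CG")
    tol <- 3 / sqrt(cs@expected)
    expect_true(all(abs(cs@fold - 1) <= tol))
    ## shared probabilities concentrate the diagonal
    p <- drawMix(nrow(sites))
    m1 <- simulateSiteCounts(sites, p, 30)
    m2 <- simulateSiteCounts(sites, p, 30)
    cs2 <- conservationContingency(m1, m2, "CG")
    expect_gt(concordantFraction(cs2), concordantFraction(cs))
    expect_gt(cs2@fold["low", "low"], 1)
})

test_that("planted conserved-high non-CG sites are recovered as TACAG", {
    cfg <- cleanConfig(nConservedHighNonCg = 300L)
    study <- cachedStudy("consHigh", cfg, reads = FALSE)
    set.seed(31)
    mA <- simulateSiteCounts(study$sites, rowMeans(study$probs[[1]]), 30)
    mB <- simulateSiteCounts(study$sites, rowMeans(study$probs[[2]]), 30)
    cls <- conservationClasses(mA, mB)
    expect_gt(nrow(cls$conserved_high), 100)
    expect_gt(nrow(cls$unmethylated), 1000)
    ## fold enrichment of the (high, high) cell exceeds one
    cs <- conservationContingency(mA, mB, "nonCG")
    expect_gt(cs@fold["high", "high"], 1)
    ## flank matrix of the recovered class reads TACAG around the site
    pfm <- buildFlankPfm(cls$conserved_high, study$genome, k = 5L)
    cons <- pfmConsensus(pfm)
    expect_equal(unname(cons[as.character(-2:2)]),
                 c("T", "A", "C", "A", "G"))
    ## recovery: nearly every planted site is classified conserved-high,
    ## and the class stays TACAG-dominated despite the background
    ## Beta(0.5,15) tail that is genuinely conserved-high as well
    tk <- with(study$truth$conserved_high_sites, paste(chrom, pos, strand))
    rk <- with(cls$conserved_high, paste(chrom, pos, strand))
    expect_gte(mean(tk %in% rk), 0.95)
    expect_gte(tacagFraction(cls$conserved_high, study$genome), 0.8)
    expect_equal(tacagFraction(study$truth$conserved_high_sites,
                               study$genome), 1.0)
})

test_that("flank matrices recover background composition on random sites", {
    study <- defaultStudy()
    set.seed(41)
    nonCg <- study$sites[study$sites$context3 != "CG", ]
    sites <- nonCg[sample(nrow(nonCg), 3000), ]
    pfm <- buildFlankPfm(sites, study$genome, k = 5L)
    ## offset 0 is all C by construction
    expect_equal(unname(pfm@counts["C", "0"]), pfm@nSites)
    ## distant offsets approximate genome base composition
    comp <- table(strsplit(as.character(study$genome[[1]]), "")[[1]])
    comp <- comp[c("A", "C", "G", "T")] / sum(comp)
    ## strand-oriented flanks mix plus and minus, so compare to the
    ## strand-symmetrized composition
    sym <- (comp + rev(comp)) / 2
    obs <- pfm@counts[, "-5"] / pfm@nSites
    se <- sqrt(sym * (1 - sym) / pfm@nSites)
    expect_true(all(abs(obs - sym) <= 4 * se + 0.02))
    expect_error(buildFlankPfm(sites[0, ], study$genome), "empty")
})

test_that("splice profile peaks at acceptor offset -3 and tracks levels", {
    study <- defaultStudy()
    set.seed(51)
    m <- simulateSiteCounts(study$sites, rowMeans(study$probs[[1]]), 30)
    prof <- spliceSiteProfile(m, study$annotations$genes, study$genome,
                              side = "3p")
    peak <- prof$offset[which.max(prof$n_chg)]
    expect_equal(peak, -3L)
    expect_true(all(prof$n_chg[prof$offset %in% -10:-4] <=
                    prof$n_chg[prof$offset == -3]))
    ## elevated TACAG acceptors push the -3 high fraction above the
    ## gene-body CHG average
    bodyAvg <- spliceVsGeneBody(m, study$annotations$genes)
    chg <- methTable(m)
    chg <- chg[chg$context3 == "CHG" & chg$total >= 4, ]
    expect_gt(prof$frac_high[prof$offset == -3],
              mean(chg$meth / chg$total > 0.3))
    ## an all-unmethylated methylome has zero high fraction everywhere
    tab <- methTable(m)
    m0 <- Methylome(tab$chrom, tab$pos, tab$strand, tab$context3,
                    tab$dinuc, tab$is_tacag, 0L, tab$total)
    prof0 <- spliceSiteProfile(m0, study$annotations$genes, study$genome,
                               side = "3p")
    expect_true(all(prof0$frac_high == 0, na.rm = TRUE))
})

test_that("alternative exons show reduced methylation; none yields NA", {
    study <- defaultStudy()
    set.seed(61)
    m <- simulateSiteCounts(study$sites, rowMeans(study$probs[[1]]), 30)
    ec <- exonClassMethylation(m, study$annotations$genes,
                               study$annotations$alt_exons)
    alt <- ec[ec$exon_class == "alternative", ]
    int <- ec[ec$exon_class == "interior", ]
    if (alt$n_cg >= 20)
        expect_lt(alt$cg_level, int$cg_level)
    none <- exonClassMethylation(m, study$annotations$genes, NULL)
    expect_true(is.na(none$cg_level[none$exon_class == "alternative"]))
})

test_that("dyad symmetry: shared strands beat independent strands", {
    cfgShared <- cleanConfig(symmetricFraction = 1)
    cfgIndep <- cleanConfig(symmetricFraction = 0)
    sShared <- cachedStudy("symShared", cfgShared, reads = FALSE)
    sIndep <- cachedStudy("symIndep", cfgIndep, reads = FALSE)
    set.seed(71)
    mS <- simulateSiteCounts(sShared$sites,
                             rowMeans(sShared$probs[[1]]), 30)
    mI <- simulateSiteCounts(sIndep$sites, rowMeans(sIndep$probs[[1]]), 30)
    symS <- symmetryAnalysis(mS, sShared$genome, "CG",
                             binarizeThreshold = 0.3)
    symI <- symmetryAnalysis(mI, sIndep$genome, "CG",
                             binarizeThreshold = 0.3)
    expect_gt(symS@fold["yes", "yes"], 1)
    expect_gt(symS@fold["yes", "yes"], symI@fold["yes", "yes"])
    ## independent strands: all folds within 3 SE of 1
    tol <- 3 / sqrt(symI@expected)
    expect_true(all(abs(symI@fold - 1) <= tol))
    ## a fully methylated methylome is fully symmetric
    tab <- methTable(mS)
    m1 <- Methylome(tab$chrom, tab$pos, tab$strand, tab$context3,
                    tab$dinuc, tab$is_tacag, tab$total, tab$total)
    sym1 <- symmetryAnalysis(m1, sShared$genome, "CG")
    expect_equal(concordantFraction(sym1), 1)
})

test_that("CHG dyads pair palindromic sites only and strata subset", {
    study <- defaultStudy()
    set.seed(81)
    m <- simulateSiteCounts(study$sites, rowMeans(study$probs[[1]]), 30)
    all <- symmetryAnalysis(m, study$genome, "CHG")
    low <- symmetryAnalysis(m, study$genome, "CHG", stratum = "low")
    expect_equal(all@n, low@n)
    expect_lte(all@observed["yes", "yes"], all@n)
})
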
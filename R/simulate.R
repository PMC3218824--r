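## Synthetic-data generator: diploid genomes with gene models, CpG
## islands and TF binding sites; per-allele per-cytosine methylation
## probabilities with planted DMRs, allele-specific methylation and
## methylation-sensitive motifs; aligned bisulfite reads; RNA allele
## counts and expression tables. Every planted feature is returned as
## truth so downstream stages have parameter-recovery tests.

#' Simulation configuration
#'
#' Returns the default configuration, optionally overridden. Defaults
#' encode the statistical structure the analyses target: bimodal CG
#' methylation (0.25 Beta(1,9) + 0.75 Beta(9,1)), low non-CG methylation
#' (Beta(0.5,15)) with elevated TACAG sites (Beta(2.2,7.8), mean 0.22),
#' 77% of CG dyads sharing one methylation probability across strands,
#' and one-chromosome-methylated/one-unmethylated allele-specific genes.
#'
#' @param ... Name-value overrides of the defaults listed below.
#' @return A validated list of class \code{SimulationConfig}.
#' @export
simulationConfig <- function(...) {
    cfg <- list(
        seed = 1L,
        genomeLength = 1e5, nChroms = 1L, gcContent = 0.41,
        nGenes = 20L, exonsPerGene = c(3L, 6L), exonSize = c(80L, 200L),
        intronSize = c(200L, 600L), geneGap = c(1200L, 2000L),
        promoterCpgFraction = 0.6, tacagAcceptorFraction = 0.7,
        altExonFraction = 0.15,
        snpRate = 1e-3, snpCgFraction = 0.15,
        readLength = 75L, coverage = 30,
        nonConversionRate = 0.005, errorRate = 0.002,
        cgMixWeightLow = 0.25, cgBetaLow = c(1, 9), cgBetaHigh = c(9, 1),
        nonCgBeta = c(0.5, 15), tacagBeta = c(2.2, 7.8),
        symmetricFraction = 0.77, lineJitterSd = 0.03,
        lineNames = c("lineA", "lineB", "lineC"),
        nDmr = 6L, dmrSize = 1000L, dmrEffect = 0.4,
        nConservedDmr = 3L, conservedDmrLevels = c(0.80, 0.45, 0.22),
        nConservedHighNonCg = 0L, nUnconservedNonCg = 150L,
        highNonCgBeta = c(8, 2),
        asmFraction = 0.15, asmHighProb = 1, asmLowProb = 0,
        aseFraction = 0.15, aseBias = 0.9, rnaDepth = 50L,
        nMotifs = 3L, sitesPerMotif = 6L, motifEffects = c(-2, 2, 0),
        exprBaseMean = 5, exprBaseSd = 1, exprNoiseSd = 0.25,
        altExonMethScale = 0.5
    )
    over <- list(...)
    bad <- setdiff(names(over), names(cfg))
    if (length(bad))
        .stopf("unknown config fields: %s", paste(bad, collapse = ", "))
    cfg[names(over)] <- over
    probs <- c("gcContent", "promoterCpgFraction", "tacagAcceptorFraction",
               "altExonFraction", "snpCgFraction", "nonConversionRate",
               "errorRate", "cgMixWeightLow", "symmetricFraction",
               "asmFraction", "aseFraction", "asmHighProb", "asmLowProb",
               "aseBias")
    for (p in probs)
        if (cfg[[p]] < 0 || cfg[[p]] > 1)
            .stopf("%s must be in [0,1]", p)
    if (cfg$genomeLength < 1e4) .stopf("genomeLength must be >= 10 kb")
    if (cfg$nMotifs * cfg$sitesPerMotif > cfg$nGenes)
        .stopf("requested %d binding sites exceed %d genes (one site per gene)",
               cfg$nMotifs * cfg$sitesPerMotif, cfg$nGenes)
    if (length(cfg$motifEffects) != cfg$nMotifs)
        .stopf("motifEffects must have length nMotifs")
    class(cfg) <- "SimulationConfig"
    cfg
}

## write a string into a raw genome vector at 1-based positions
.plant <- function(s, at, what) {
    s[at + seq_len(nchar(what)) - 1L] <- charToRaw(what)
    s
}

#' Simulate a genome with gene models and regulatory annotation
#'
#' Generates random sequence at the configured GC content, lays down
#' multi-exon genes whose introns end in canonical AG acceptors (a
#' configurable fraction carries the full TACAG acceptor, putting a
#' CHG-context C at acceptor offset -3), rewrites a fraction of promoters
#' as CpG islands, and plants one transcription-factor binding site (an
#' 8-mer containing two CpGs) upstream of each selected gene.
#'
#' @param config A \code{\link{simulationConfig}}.
#' @return List: \code{genome} (\code{DNAStringSet}), \code{annotations}
#'   (list of \code{GRanges}: genes with \code{blocks}, promoters,
#'   cpg_islands, alt_exons, tfbs, exons, introns), \code{motifs}
#'   (data.frame motif_id, tf_name, effect).
#' @export
simulateGenome <- function(config) {
    set.seed(config$seed)
    pC <- config$gcContent / 2; pA <- (1 - config$gcContent) / 2
    nChrom <- config$nChroms
    Lc <- floor(config$genomeLength / nChrom)
    chromNames <- paste0("chr", seq_len(nChrom))
    seqs <- list()
    geneRows <- list(); blockList <- list()
    islRows <- list(); altRows <- list()
    geneCount <- 0L
    genesPerChrom <- ceiling(config$nGenes / nChrom)
    for (ci in seq_len(nChrom)) {
        s <- charToRaw(paste(sample(.BASES, Lc, replace = TRUE,
                                    prob = c(pA, pC, pC, pA)),
                             collapse = ""))
        cursor <- 1500L
        nHere <- min(genesPerChrom, config$nGenes - geneCount)
        for (g in seq_len(nHere)) {
            nEx <- sample(config$exonsPerGene[1]:config$exonsPerGene[2], 1L)
            exLen <- sample(config$exonSize[1]:config$exonSize[2], nEx,
                            replace = TRUE)
            inLen <- sample(config$intronSize[1]:config$intronSize[2],
                            max(nEx - 1L, 0L), replace = TRUE)
            span <- sum(exLen) + sum(inLen)
            if (cursor + span + 500L > Lc)
                .stopf("gene %d does not fit: genome capacity exceeded",
                       geneCount + 1L)
            start0 <- cursor
            bs <- integer(nEx); be <- integer(nEx)
            p <- start0
            for (e in seq_len(nEx)) {
                bs[e] <- p; be[e] <- p + exLen[e]
                p <- be[e] + if (e < nEx) inLen[e] else 0L
            }
            strand <- sample(c("+", "-"), 1L)
            ## canonical splice signals on the coding strand
            for (e in seq_len(nEx - 1L)) {
                if (strand == "+") {
                    s <- .plant(s, be[e] + 1L, "GT")          # donor
                    acc0 <- bs[e + 1L]                         # acceptor
                    if (runif(1) < config$tacagAcceptorFraction)
                        s <- .plant(s, acc0 - 4L, "TACAG")
                    else
                        s <- .plant(s, acc0 - 4L, "GGCAG")
                } else {
                    s <- .plant(s, bs[e + 1L] - 1L, "AC")      # donor (rc)
                    acc0 <- be[e]                              # acceptor (rc)
                    if (runif(1) < config$tacagAcceptorFraction)
                        s <- .plant(s, acc0 + 1L, "CTGTA")
                    else
                        s <- .plant(s, acc0 + 1L, "CTGCC")
                }
            }
            geneCount <- geneCount + 1L
            gid <- sprintf("gene%03d", geneCount)
            geneRows[[geneCount]] <- data.frame(
                chrom = chromNames[ci], start0 = start0, end0 = be[nEx],
                name = gid, strand = strand)
            blockList[[geneCount]] <- cbind(start = bs, end = be)
            ## alternative (cassette) interior exons
            if (nEx >= 3L) {
                alt <- which(runif(nEx - 2L) < config$altExonFraction) + 1L
                for (e in alt)
                    altRows[[length(altRows) + 1L]] <- data.frame(
                        chrom = chromNames[ci], start0 = bs[e], end0 = be[e])
            }
            cursor <- be[nEx] +
                sample(config$geneGap[1]:config$geneGap[2], 1L)
        }
        seqs[[ci]] <- s
    }
    genes <- do.call(rbind, geneRows)
    ## CpG islands over a fraction of promoters, strictly upstream of the
    ## TSS so the rewrite never touches gene-body splice signals
    cpg <- runif(nrow(genes)) < config$promoterCpgFraction
    for (i in which(cpg)) {
        ci <- match(genes$chrom[i], chromNames)
        tss <- if (genes$strand[i] == "+") genes$start0[i] else
            genes$end0[i] - 1L
        if (genes$strand[i] == "+") {
            a <- max(tss - 520L, 0L); b <- max(tss - 20L, 1L)
        } else {
            a <- min(tss + 21L, Lc - 2L); b <- min(tss + 521L, Lc - 1L)
        }
        w <- b - a
        ## CG-rich rewrite: interleave CG dinucleotides with GC-rich bases
        island <- character(w)
        u <- runif(w)
        island <- sample(c("C", "G", "A", "T"), w, replace = TRUE,
                         prob = c(0.3, 0.3, 0.2, 0.2))
        at <- which(u < 0.15 & seq_len(w) < w)
        island[at] <- "C"; island[at + 1L] <- "G"
        seqs[[ci]] <- .plant(seqs[[ci]], a + 1L,
                             paste(island, collapse = ""))
        islRows[[length(islRows) + 1L]] <- data.frame(
            chrom = genes$chrom[i], start0 = a, end0 = b)
    }
    ## TF binding sites: one per selected gene, upstream of the TSS
    nSites <- config$nMotifs * config$sitesPerMotif
    motifIds <- sprintf("M%03d", seq_len(config$nMotifs))
    tfNames <- sprintf("TF%d", seq_len(config$nMotifs))
    consensus <- vapply(seq_len(config$nMotifs), function(m)
        paste0(paste(sample(c("A", "T"), 2L, replace = TRUE),
                     collapse = ""), "CG",
               paste(sample(c("A", "T"), 2L, replace = TRUE),
                     collapse = ""), "CG"), character(1))
    siteGenes <- sample(nrow(genes), nSites)
    tfbsRows <- list()
    for (k in seq_len(nSites)) {
        m <- (k - 1L) %/% config$sitesPerMotif + 1L
        gi <- siteGenes[k]
        ci <- match(genes$chrom[gi], chromNames)
        if (genes$strand[gi] == "+") {
            a <- genes$start0[gi] - 180L
        } else {
            a <- genes$end0[gi] + 172L
        }
        seqs[[ci]] <- .plant(seqs[[ci]], a + 1L, consensus[m])
        tfbsRows[[k]] <- data.frame(
            chrom = genes$chrom[gi], start0 = a, end0 = a + 8L,
            name = paste0(motifIds[m], ":", tfNames[m]), score = 0.05,
            strand = genes$strand[gi], gene = genes$name[gi])
    }
    genome <- DNAStringSet(vapply(seqs, rawToChar, character(1)))
    names(genome) <- chromNames
    geneGr <- GRanges(genes$chrom, IRanges(genes$start0 + 1L, genes$end0),
                      strand = genes$strand)
    mcols(geneGr)$name <- genes$name
    mcols(geneGr)$blocks <- blockList
    tss <- ifelse(genes$strand == "+", genes$start0 + 1L, genes$end0)
    promoters <- GRanges(genes$chrom,
                         IRanges(pmax(tss - 1000L, 1L), tss + 1000L),
                         strand = genes$strand)
    mcols(promoters)$name <- genes$name
    islands <- if (length(islRows)) {
        d <- do.call(rbind, islRows)
        GRanges(d$chrom, IRanges(d$start0 + 1L, d$end0))
    } else GRanges()
    altEx <- if (length(altRows)) {
        d <- do.call(rbind, altRows)
        GRanges(d$chrom, IRanges(d$start0 + 1L, d$end0))
    } else GRanges()
    tfd <- do.call(rbind, tfbsRows)
    tfbs <- GRanges(tfd$chrom, IRanges(tfd$start0 + 1L, tfd$end0),
                    strand = tfd$strand)
    mcols(tfbs)$name <- tfd$name
    mcols(tfbs)$score <- tfd$score
    mcols(tfbs)$gene <- tfd$gene
    exons <- reduce(.exonRanges(geneGr), ignore.strand = TRUE)
    introns <- GenomicRanges::setdiff(
        reduce(granges(geneGr), ignore.strand = TRUE), exons,
        ignore.strand = TRUE)
    list(genome = genome,
         annotations = list(genes = geneGr, promoters = promoters,
                            cpg_islands = islands, alt_exons = altEx,
                            tfbs = tfbs, exons = exons, introns = introns),
         motifs = data.frame(motif_id = motifIds, tf_name = tfNames,
                             effect = config$motifEffects,
                             consensus = consensus))
}

#' Simulate a diploid individual
#'
#' Places biallelic heterozygous SNPs uniformly at the configured rate.
#' A configurable fraction sits on genomic C/G positions as C>T (G>A)
#' substitutions -- the class that bisulfite conversion makes structurally
#' uncallable; the remainder are A<>T substitutions at A/T positions,
#' which bisulfite chemistry leaves fully distinguishable on both
#' strands. Never placed on N.
#'
#' @param genome A \code{DNAStringSet} (haplotype 1 / reference).
#' @param config A \code{\link{simulationConfig}}.
#' @return List: \code{hap1}, \code{hap2} (\code{DNAStringSet}s),
#'   \code{snps} (data.frame chrom, pos, ref, alt, at_cg).
#' @export
simulateDiploid <- function(genome, config) {
    set.seed(config$seed + 101L)
    raws <- .genomeRaw(genome)
    snpRows <- list()
    hap2 <- raws
    for (cn in names(raws)) {
        s <- raws[[cn]]
        L <- length(s)
        n <- rbinom(1L, L, config$snpRate)
        if (n == 0L) next
        nCg <- round(n * config$snpCgFraction)
        poolCg <- which(s == .rawC | s == .rawG)
        poolAt <- which(s == .rawA | s == .rawT)
        posCg <- sort(sample(poolCg, min(nCg, length(poolCg))))
        posAt <- sort(sample(poolAt, min(n - length(posCg), length(poolAt))))
        pos <- sort(c(posCg, posAt))
        ref <- rawToChar(s[pos])
        refv <- strsplit(ref, "")[[1]]
        alt <- chartr("ACGT", "TTAA", ref)
        altv <- strsplit(alt, "")[[1]]
        hap2[[cn]][pos] <- charToRaw(alt)
        snpRows[[cn]] <- data.frame(chrom = cn, pos = pos, ref = refv,
                                    alt = altv,
                                    at_cg = refv %in% c("C", "G"))
    }
    snps <- if (length(snpRows)) do.call(rbind, snpRows) else
        data.frame(chrom = character(0), pos = integer(0),
                   ref = character(0), alt = character(0),
                   at_cg = logical(0))
    rownames(snps) <- NULL
    h2 <- DNAStringSet(vapply(hap2, rawToChar, character(1)))
    names(h2) <- names(genome)
    list(hap1 = genome, hap2 = h2, snps = snps)
}

#' Simulate per-allele methylation probability maps for three cell lines
#'
#' Draws a shared base probability per reference cytosine (CG sites from
#' the bimodal Beta mixture, with a configured fraction of CG dyads
#' sharing one probability across strands; non-CG sites from a low-mean
#' Beta; TACAG sites from an elevated Beta), adds per-line jitter, then
#' plants: conserved highly methylated non-CG (TACAG) sites; line-specific
#' ("unconserved") methylated non-CG sites; pairwise DMR windows (one
#' line's CG probabilities shifted down by the configured effect);
#' conserved DMR windows (the three lines set to spaced CG levels so all
#' three pairwise ratios are outliers); allele-specific methylation genes
#' (allele 1 at \code{asmHighProb}, allele 2 at \code{asmLowProb} over
#' gene-body CG sites); and per-line binding-site methylation levels (all
#' CG cytosines of a TFBS set to one uniform draw per line, on a 0.01
#' grid).
#'
#' @param genome A \code{DNAStringSet}.
#' @param annotations Annotation list from \code{\link{simulateGenome}}.
#' @param config A \code{\link{simulationConfig}}.
#' @return List: \code{sites} (cytosine table), \code{probs} (per line, a
#'   two-column matrix of allele-1/allele-2 probabilities per site), and
#'   \code{truth} (dmrs, asm_genes, conserved_high_sites,
#'   unconserved_sites, tfbs_meth).
#' @export
simulateMethylomes <- function(genome, annotations, config) {
    set.seed(config$seed + 202L)
    sites <- cytosineSites(genome)
    n <- nrow(sites)
    key <- .siteKey(sites$chrom, sites$pos, sites$strand)
    isCg <- sites$context3 == "CG"
    ## base probabilities, shared across lines and alleles
    base <- numeric(n)
    drawCg <- function(m) {
        low <- runif(m) < config$cgMixWeightLow
        ifelse(low, rbeta(m, config$cgBetaLow[1], config$cgBetaLow[2]),
               rbeta(m, config$cgBetaHigh[1], config$cgBetaHigh[2]))
    }
    ## CG dyads: plus C at i paired with minus C at i+1
    plusCg <- which(isCg & sites$strand == "+")
    partner <- match(.siteKey(sites$chrom[plusCg], sites$pos[plusCg] + 1L,
                              "-"), key)
    hasP <- !is.na(partner)
    dy <- cbind(plusCg[hasP], partner[hasP])
    shared <- runif(nrow(dy)) < config$symmetricFraction
    pDyad <- drawCg(nrow(dy))
    base[dy[shared, 1]] <- pDyad[shared]
    base[dy[shared, 2]] <- pDyad[shared]
    indiv <- c(dy[!shared, ], setdiff(which(isCg), as.vector(dy)))
    base[indiv] <- drawCg(length(indiv))
    nonCg <- which(!isCg)
    base[nonCg] <- rbeta(length(nonCg), config$nonCgBeta[1],
                         config$nonCgBeta[2])
    tac <- which(sites$is_tacag)
    base[tac] <- rbeta(length(tac), config$tacagBeta[1],
                       config$tacagBeta[2])
    lineNames <- config$lineNames
    nLine <- length(lineNames)
    ## per-line jitter; shared dyads receive one draw per dyad so strand
    ## sharing stays exact
    perLine <- lapply(seq_len(nLine), function(l) {
        jit <- rnorm(n, 0, config$lineJitterSd)
        jit[dy[shared, 2]] <- jit[dy[shared, 1]]
        pmin(pmax(base + jit, 0), 1)
    })
    ## planted conserved highly methylated non-CG sites (TACAG class)
    chIdx <- sample(tac, min(config$nConservedHighNonCg, length(tac)))
    pHigh <- rbeta(length(chIdx), config$highNonCgBeta[1],
                   config$highNonCgBeta[2])
    for (l in seq_len(nLine)) perLine[[l]][chIdx] <- pHigh
    ## line-specific methylated non-CG sites
    pool <- setdiff(which(!isCg & !sites$is_tacag), chIdx)
    unIdx <- sample(pool, min(config$nUnconservedNonCg, length(pool)))
    unLine <- rep_len(seq_len(nLine), length(unIdx))
    for (l in seq_len(nLine)) {
        perLine[[l]][unIdx] <- 0
        perLine[[l]][unIdx[unLine == l]] <- 0.8
    }
    ## allele-specific methylation genes (gene-body CG sites)
    genes <- annotations$genes
    asmPick <- sample(length(genes),
                      round(config$asmFraction * length(genes)))
    asmGenes <- mcols(genes)$name[asmPick]
    sgr <- GRanges(sites$chrom, IRanges(sites$pos, width = 1L))
    inAsm <- overlapsAny(sgr, granges(genes)[asmPick],
                         ignore.strand = TRUE) & isCg
    ## DMR windows on the 1-kb grid, avoiding ASM genes and binding sites
    lens <- .chromLengths(genome)
    winCand <- do.call(rbind, lapply(names(lens), function(cn)
        data.frame(chrom = cn,
                   start0 = seq(0L, lens[[cn]] - 1L, by = config$dmrSize))))
    wgr <- GRanges(winCand$chrom,
                   IRanges(winCand$start0 + 1L,
                           winCand$start0 + config$dmrSize))
    cgCount <- rep(0L, nrow(winCand))
    hit <- findOverlaps(sgr[isCg], wgr, ignore.strand = TRUE)
    tab <- table(subjectHits(hit))
    cgCount[as.integer(names(tab))] <- as.integer(tab)
    avoid <- overlapsAny(wgr, granges(genes)[asmPick],
                         ignore.strand = TRUE) |
        overlapsAny(wgr, annotations$tfbs, ignore.strand = TRUE)
    elig <- which(cgCount >= 10L & !avoid)
    nWant <- config$nDmr + config$nConservedDmr
    pick <- sample(elig, min(nWant, length(elig)))
    dmrPick <- pick[seq_len(min(config$nDmr, length(pick)))]
    consPick <- setdiff(pick, dmrPick)
    dmrLine <- rep_len(seq_len(nLine), length(dmrPick))
    inWin <- function(w) which(isCg & sites$chrom == winCand$chrom[w] &
                               sites$pos > winCand$start0[w] &
                               sites$pos <= winCand$start0[w] +
                                   config$dmrSize)
    for (k in seq_along(dmrPick)) {
        idx <- inWin(dmrPick[k])
        l <- dmrLine[k]
        perLine[[l]][idx] <- pmax(perLine[[l]][idx] - config$dmrEffect, 0)
    }
    for (w in consPick) {
        idx <- inWin(w)
        for (l in seq_len(nLine))
            perLine[[l]][idx] <- config$conservedDmrLevels[l]
    }
    ## binding-site methylation: one level per site per line (0.01 grid)
    tfbs <- annotations$tfbs
    tfbsMeth <- matrix(round(runif(length(tfbs) * nLine), 2L),
                       length(tfbs), nLine,
                       dimnames = list(mcols(tfbs)$gene, lineNames))
    siteHit <- findOverlaps(sgr, granges(tfbs), ignore.strand = TRUE)
    for (l in seq_len(nLine))
        perLine[[l]][queryHits(siteHit)[isCg[queryHits(siteHit)]]] <-
            tfbsMeth[subjectHits(siteHit)[isCg[queryHits(siteHit)]], l]
    ## alternative exons: scaled-down methylation in every line
    if (length(annotations$alt_exons)) {
        inAlt <- overlapsAny(sgr, annotations$alt_exons,
                             ignore.strand = TRUE)
        for (l in seq_len(nLine))
            perLine[[l]][inAlt] <- perLine[[l]][inAlt] *
                config$altExonMethScale
    }
    ## assemble per-allele matrices; ASM genes separate the alleles
    probs <- lapply(seq_len(nLine), function(l) {
        m <- cbind(a1 = perLine[[l]], a2 = perLine[[l]])
        m[inAsm, "a1"] <- config$asmHighProb
        m[inAsm, "a2"] <- config$asmLowProb
        m
    })
    names(probs) <- lineNames
    dmrs <- rbind(
        if (length(dmrPick))
            data.frame(chrom = winCand$chrom[dmrPick],
                       start0 = winCand$start0[dmrPick],
                       type = "pairwise", line = lineNames[dmrLine]),
        if (length(consPick))
            data.frame(chrom = winCand$chrom[consPick],
                       start0 = winCand$start0[consPick],
                       type = "conserved", line = NA_character_))
    list(sites = sites, probs = probs,
         truth = list(
             dmrs = dmrs,
             asm_genes = asmGenes,
             asm_sites = sites[inAsm, c("chrom", "pos", "strand")],
             conserved_high_sites = sites[chIdx,
                                          c("chrom", "pos", "strand")],
             unconserved_sites = data.frame(
                 sites[unIdx, c("chrom", "pos", "strand")],
                 line = lineNames[unLine]),
             tfbs_meth = tfbsMeth))
}

#' Sample a Methylome directly from a probability map
#'
#' Shortcut past read simulation for analyses that only need per-site
#' counts: per site, the read total is Poisson(\code{coverage}) (or
#' exactly \code{coverage} when \code{sample = FALSE}) and the methylated
#' count Binomial(total, p) (or \code{round(p * total)}, exact when p is
#' on the 1/total grid).
#'
#' @param sites Cytosine table (from \code{\link{simulateMethylomes}}).
#' @param prob Per-site methylation probability (e.g. the allele average
#'   of one line's matrix).
#' @param coverage Mean (or exact) per-site read depth.
#' @param sample Draw counts stochastically (default) or deterministically.
#' @return A \code{\linkS4class{Methylome}}.
#' @export
simulateSiteCounts <- function(sites, prob, coverage, sample = TRUE) {
    n <- nrow(sites)
    total <- if (sample) rpois(n, coverage) else rep(as.integer(coverage), n)
    meth <- if (sample) rbinom(n, total, prob) else
        as.integer(round(prob * total))
    keep <- total > 0L
    Methylome(sites$chrom[keep], sites$pos[keep], sites$strand[keep],
              sites$context3[keep], sites$dinuc[keep],
              sites$is_tacag[keep], meth[keep], total[keep])
}

#' Simulate aligned bisulfite reads from a diploid methylome
#'
#' Reads are emitted post-alignment: fixed length, ungapped, plus-strand
#' orientation. Each read picks an allele uniformly, a bisulfite strand
#' uniformly (W reads on plus-strand cytosines, C reads on minus-strand
#' cytosines via plus-strand G positions), converts each unmethylated
#' cytosine (Bernoulli per-site probability from the map; positions absent
#' from the map are unmethylated), leaves a fraction of reads entirely
#' unconverted (so the non-conversion filter has true positives), and
#' applies uniform substitution errors.
#'
#' @param haplotypes List with \code{hap1}, \code{hap2}
#'   (\code{DNAStringSet}s).
#' @param sites Cytosine table of the reference.
#' @param probMatrix Two-column per-site probability matrix (alleles) for
#'   one cell line.
#' @param config A \code{\link{simulationConfig}}.
#' @param seedOffset Stage offset added to \code{config$seed}.
#' @return Read \code{data.frame} (\code{\link{readBsReads}} schema) plus
#'   a truth column \code{allele}.
#' @export
simulateBsReads <- function(haplotypes, sites, probMatrix, config,
                            seedOffset = 303L) {
    set.seed(config$seed + seedOffset)
    rl <- config$readLength
    hapChars <- lapply(haplotypes, .genomeRaw)
    out <- list()
    for (cn in names(haplotypes$hap1)) {
        L <- length(hapChars$hap1[[cn]])
        nReads <- round(L * config$coverage / rl)
        start0 <- sample.int(L - rl + 1L, nReads, replace = TRUE) - 1L
        allele <- sample(2L, nReads, replace = TRUE)
        isW <- sample(c(TRUE, FALSE), nReads, replace = TRUE)
        unconv <- runif(nReads) < config$nonConversionRate
        ## per-strand probability lookup vectors for each allele
        sel <- sites$chrom == cn
        pp <- matrix(0, L, 2L); pm <- matrix(0, L, 2L)
        sp <- sites$pos[sel]; ss <- sites$strand[sel]
        pp[sp[ss == "+"], 1L] <- probMatrix[sel, 1L][ss == "+"]
        pp[sp[ss == "+"], 2L] <- probMatrix[sel, 2L][ss == "+"]
        pm[sp[ss == "-"], 1L] <- probMatrix[sel, 1L][ss == "-"]
        pm[sp[ss == "-"], 2L] <- probMatrix[sel, 2L][ss == "-"]
        ## base matrix, read per column
        M <- matrix(as.raw(0), rl, nReads)
        for (a in 1:2) {
            cols <- which(allele == a)
            if (!length(cols)) next
            h <- hapChars[[a]][[cn]]
            M[, cols] <- h[outer(seq_len(rl), start0[cols], "+")]
        }
        P <- matrix(0, rl, nReads)
        posM <- outer(seq_len(rl), start0, "+")
        for (a in 1:2) {
            cw <- which(allele == a & isW)
            if (length(cw)) P[, cw] <- pp[cbind(as.vector(posM[, cw]),
                                                a)]
            cc <- which(allele == a & !isW)
            if (length(cc)) P[, cc] <- pm[cbind(as.vector(posM[, cc]),
                                                a)]
        }
        U <- matrix(runif(rl * nReads), rl, nReads)
        convertible <- !matrix(unconv, rl, nReads, byrow = TRUE)
        wcol <- matrix(isW, rl, nReads, byrow = TRUE)
        convW <- wcol & convertible & M == .rawC & U >= P
        convC <- !wcol & convertible & M == .rawG & U >= P
        M[convW] <- .rawT
        M[convC] <- .rawA
        err <- matrix(runif(rl * nReads) < config$errorRate, rl, nReads)
        if (any(err)) {
            idx <- match(as.integer(M[err]),
                         as.integer(charToRaw("ACGT")))
            shift <- sample(3L, sum(err), replace = TRUE)
            M[err] <- charToRaw("ACGT")[(idx - 1L + shift) %% 4L + 1L]
        }
        seqs <- vapply(seq_len(nReads), function(j) rawToChar(M[, j]),
                       character(1))
        out[[cn]] <- data.frame(
            read_id = sprintf("%s_r%06d", cn, seq_len(nReads)),
            chrom = cn, start0 = start0,
            strand = ifelse(isW, "+", "-"),
            bs_strand = ifelse(isW, "W", "C"),
            seq = seqs, allele = allele)
    }
    df <- do.call(rbind, out)
    rownames(df) <- NULL
    df
}

#' Simulate RNA allele counts at exonic SNPs
#'
#' For each exonic SNP of an allele-specifically expressed gene, allele-1
#' RNA counts are Binomial(depth, bias); other genes use bias 0.5.
#'
#' @param exonicSnps \code{data.frame} with gene_id, chrom, pos, allele1
#'   (haplotype-1 base), allele2.
#' @param aseGenes \code{data.frame} with gene_id, bias.
#' @param config A \code{\link{simulationConfig}}.
#' @param seedOffset Stage offset added to \code{config$seed}.
#' @return \code{data.frame}: chrom, pos, allele, count (long format).
#' @export
simulateRnaCounts <- function(exonicSnps, aseGenes, config,
                              seedOffset = 404L) {
    set.seed(config$seed + seedOffset)
    bias <- aseGenes$bias[match(exonicSnps$gene_id, aseGenes$gene_id)]
    bias[is.na(bias)] <- 0.5
    n1 <- rbinom(nrow(exonicSnps), config$rnaDepth, bias)
    rbind(data.frame(chrom = exonicSnps$chrom, pos = exonicSnps$pos,
                     allele = exonicSnps$allele1, count = n1),
          data.frame(chrom = exonicSnps$chrom, pos = exonicSnps$pos,
                     allele = exonicSnps$allele2,
                     count = config$rnaDepth - n1))
}

#' Simulate a gene-by-line expression table
#'
#' Baseline log2 expression is Gaussian per gene; genes targeted by a
#' binding site of motif m are shifted so that
#' log2(expr + 1) = base + effect_m * site methylation + noise,
#' making the planted methylation-expression relation exactly linear on
#' the log2(x + 1) scale (exact sign recovery at zero noise).
#'
#' @param geneNames Character vector of all gene ids.
#' @param tfbs TFBS \code{GRanges} (with \code{name}, \code{gene}).
#' @param tfbsMeth Per-site-by-line methylation matrix (truth from
#'   \code{\link{simulateMethylomes}}).
#' @param motifs Motif table from \code{\link{simulateGenome}}.
#' @param config A \code{\link{simulationConfig}}.
#' @param seedOffset Stage offset added to \code{config$seed}.
#' @return Expression matrix (genes x lines), non-negative.
#' @export
simulateExpression <- function(geneNames, tfbs, tfbsMeth, motifs, config,
                               seedOffset = 505L) {
    set.seed(config$seed + seedOffset)
    nLine <- length(config$lineNames)
    base <- rnorm(length(geneNames), config$exprBaseMean, config$exprBaseSd)
    log2e <- matrix(base, length(geneNames), nLine,
                    dimnames = list(geneNames, config$lineNames))
    motifOf <- sub(":.*$", "", mcols(tfbs)$name)
    eff <- motifs$effect[match(motifOf, motifs$motif_id)]
    gi <- match(mcols(tfbs)$gene, geneNames)
    for (k in seq_along(tfbs))
        log2e[gi[k], ] <- log2e[gi[k], ] + eff[k] * tfbsMeth[k, ]
    log2e <- log2e + matrix(rnorm(length(log2e), 0, config$exprNoiseSd),
                            nrow(log2e))
    pmax(2 ^ log2e - 1, 0)
}

#' Run the full synthetic study
#'
#' Generates genome and annotation, diploid haplotypes with truth SNPs,
#' three-line per-allele methylation probability maps with all planted
#' features, bisulfite reads for the first line, exonic-SNP RNA allele
#' counts (with planted allele-specifically expressed genes) and the
#' expression table.
#'
#' @param config A \code{\link{simulationConfig}}.
#' @param reads Simulate bisulfite reads for line 1 (default \code{TRUE};
#'   the slowest step).
#' @return List with components genome, annotations, motifs, hap1, hap2,
#'   snps, sites, probs, truth, reads, rnaCounts, expression. \code{truth}
#'   gains \code{ase_genes} (gene_id, bias) and \code{exonic_snps}.
#' @export
simulateStudy <- function(config = simulationConfig(), reads = TRUE) {
    gen <- simulateGenome(config)
    dip <- simulateDiploid(gen$genome, config)
    meth <- simulateMethylomes(gen$genome, gen$annotations, config)
    ## truth exonic SNPs and planted ASE genes
    ex <- .exonRanges(gen$annotations$genes)
    sgr <- GRanges(dip$snps$chrom, IRanges(dip$snps$pos, width = 1L))
    hits <- findOverlaps(sgr, ex, ignore.strand = TRUE)
    exonic <- data.frame(
        gene_id = mcols(gen$annotations$genes)$name[
            mcols(ex)$geneIdx[subjectHits(hits)]],
        chrom = dip$snps$chrom[queryHits(hits)],
        pos = dip$snps$pos[queryHits(hits)],
        allele1 = dip$snps$ref[queryHits(hits)],
        allele2 = dip$snps$alt[queryHits(hits)])
    exonic <- exonic[!duplicated(paste(exonic$gene_id, exonic$pos)), ,
                     drop = FALSE]
    set.seed(config$seed + 606L)
    withSnp <- unique(exonic$gene_id)
    nAse <- round(config$aseFraction * length(withSnp))
    aseGenes <- data.frame(
        gene_id = if (nAse) sample(withSnp, nAse) else character(0),
        bias = config$aseBias)
    truth <- meth$truth
    truth$ase_genes <- aseGenes
    truth$exonic_snps <- exonic
    truth$snps <- dip$snps
    rna <- simulateRnaCounts(exonic, aseGenes, config)
    expr <- simulateExpression(mcols(gen$annotations$genes)$name,
                               gen$annotations$tfbs, meth$truth$tfbs_meth,
                               gen$motifs, config)
    rd <- if (reads)
        simulateBsReads(list(hap1 = dip$hap1, hap2 = dip$hap2),
                        meth$sites, meth$probs[[1L]], config)
    else NULL
    list(genome = gen$genome, annotations = gen$annotations,
         motifs = gen$motifs, hap1 = dip$hap1, hap2 = dip$hap2,
         snps = dip$snps, sites = meth$sites, probs = meth$probs,
         truth = truth, reads = rd, rnaCounts = rna, expression = expr)
}
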
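## Bisulfite-aware heterozygous SNP calling and allele-specific expression.

#' Exact two-sided binomial test (minimum-likelihood convention)
#'
#' P-value = sum of the probabilities of all outcomes whose probability
#' under Binomial(n, p) does not exceed that of the observed outcome (with
#' a 1 + 1e-7 relative tolerance for floating-point ties, as in
#' \code{binom.test}). Degenerate p in {0, 1} is handled exactly via the
#' point-mass distribution.
#'
#' @param k Observed successes (vectorized).
#' @param n Trials.
#' @param p Null success probability.
#' @return P-value(s) in [0, 1].
#' @export
binomTwoSided <- function(k, n, p = 0.5) {
    stopifnot(all(k >= 0L), all(k <= n))
    mapply(function(ki, ni, pi) {
        d <- dbinom(0:ni, ni, pi)
        sum(d[d <= d[ki + 1L] * (1 + 1e-7)])
    }, k, n, p)
}

#' Upper-tail hypergeometric probability P(X >= k)
#'
#' @param k Observed successes among the draws.
#' @param nSuccessPop Successes in the population.
#' @param nDraws Draws.
#' @param nPop Population size.
#' @return P(X >= k).
#' @export
hyperUpperTail <- function(k, nSuccessPop, nDraws, nPop) {
    phyper(k - 1, nSuccessPop, nPop - nSuccessPop, nDraws,
           lower.tail = FALSE)
}

#' Call heterozygous SNPs from bisulfite reads
#'
#' Per position, per-strand base tallies are built from the aligned reads.
#' Because bisulfite converts unmethylated C to T, observations that are
#' ambiguous under conversion are excluded from allele evidence: at a
#' genomic plus-strand C, Watson-fragment reads showing C or T; at a
#' genomic G (a minus-strand C), Crick-fragment reads showing G or A in
#' plus orientation. Per-allele counts are the average of the Watson and
#' Crick tallies. A position is called heterozygous when (i) raw read
#' coverage >= \code{minCov}, (ii) the two main alleles carry more than
#' \code{mainFrac} of the (strand-averaged) included evidence, and
#' (iii) the two main allele counts differ by at most \code{balance} of
#' their total. Positions whose reference base is N are never candidates.
#'
#' @param reads Read \code{data.frame} (see \code{\link{readBsReads}}).
#' @param genome A \code{DNAStringSet}.
#' @param minCov Minimum raw read coverage (default 8).
#' @param mainFrac Minimum fraction of evidence on the two main alleles
#'   (default 0.75, strict inequality).
#' @param balance Maximum allowed |count1 - count2| as a fraction of
#'   count1 + count2 (default 0.20).
#' @param audit Also return filtered candidate positions with status flags.
#' @return \code{data.frame}: chrom, pos (1-based), allele1, allele2
#'   (allele1 has the larger count), count1, count2 (strand-averaged:
#'   the mean of the Watson and Crick tallies), coverage (raw reads).
#'   The main-allele and balance filters are applied to the raw summed
#'   evidence, of which the reported strand-averaged counts are half.
#'   With \code{audit = TRUE}, extra logical columns
#'   \code{c_ambiguous_excluded}, \code{low_coverage},
#'   \code{low_main_fraction}, \code{unbalanced}, \code{is_het} and all
#'   candidate positions are returned.
#' @export
callSnps <- function(reads, genome, minCov = 8L, mainFrac = 0.75,
                     balance = 0.20, audit = FALSE) {
    validateBsReads(reads, genome)
    raws <- .genomeRaw(genome)
    ex <- if (nrow(reads)) .expandReads(reads) else NULL
    out <- list()
    for (cn in names(raws)) {
        s <- raws[[cn]]
        L <- length(s)
        sel <- if (is.null(ex)) integer(0) else which(ex$chrom == cn)
        if (!length(sel)) next
        pos <- ex$pos[sel]; base <- ex$base[sel]; isW <- ex$isW[sel]
        gb <- s[pos]
        coverage <- tabulate(pos, nbins = L)
        ## conversion-ambiguous observations carry no allele information:
        ## at genomic C, Watson reads' C/T; at genomic G (a minus-strand
        ## C), Crick reads' G/A
        ambig <- (isW & gb == .rawC & (base == .rawC | base == .rawT)) |
                 (!isW & gb == .rawG & (base == .rawG | base == .rawA))
        anyAmbig <- tabulate(pos[ambig], nbins = L) > 0L
        inc <- !ambig & base != .rawN
        tal <- function(strandW, b)
            tabulate(pos[inc & (isW == strandW) & base == charToRaw(b)],
                     nbins = L)
        ## raw evidence summed over strands; reported counts are the
        ## strand average (half of this)
        cnt <- sapply(.BASES, function(b) tal(TRUE, b) + tal(FALSE, b))
        ## candidates: >= 2 distinct alleles with included evidence
        nAllele <- rowSums(cnt > 0)
        cand <- which(nAllele >= 2L & s != .rawN)
        if (!length(cand)) next
        cc <- cnt[cand, , drop = FALSE]
        ord <- t(apply(cc, 1L, order, decreasing = TRUE))
        r1 <- cc[cbind(seq_len(nrow(cc)), ord[, 1])]
        r2 <- cc[cbind(seq_len(nrow(cc)), ord[, 2])]
        lowCov <- coverage[cand] < minCov
        lowMain <- (r1 + r2) <= mainFrac * coverage[cand]
        unbal <- abs(r1 - r2) > balance * (r1 + r2)
        isHet <- !lowCov & !lowMain & !unbal
        df <- data.frame(chrom = cn, pos = cand,
                         allele1 = .BASES[ord[, 1]],
                         allele2 = .BASES[ord[, 2]],
                         count1 = r1 / 2, count2 = r2 / 2,
                         coverage = coverage[cand])
        if (audit) {
            df$c_ambiguous_excluded <- anyAmbig[cand]
            df$low_coverage <- lowCov
            df$low_main_fraction <- lowMain
            df$unbalanced <- unbal
            df$is_het <- isHet
        } else {
            df <- df[isHet, , drop = FALSE]
        }
        out[[cn]] <- df
    }
    if (!length(out))
        return(data.frame(chrom = character(0), pos = integer(0),
                          allele1 = character(0), allele2 = character(0),
                          count1 = numeric(0), count2 = numeric(0),
                          coverage = integer(0)))
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}

#' Map heterozygous SNPs to exons and attach RNA allele counts
#'
#' Keeps SNPs falling inside exon blocks of the gene models, with total
#' RNA coverage of the two alleles of at least \code{minRna} reads. The
#' allele with more RNA reads is the major allele. A SNP inside
#' overlapping genes is assigned to each of them (flagged).
#'
#' @param snps SNP table from \code{\link{callSnps}}.
#' @param rnaCounts \code{data.frame} with chrom, pos, allele, count (RNA
#'   reads per allele at heterozygous positions).
#' @param genes BED12-style \code{GRanges} with \code{name} and
#'   \code{blocks}.
#' @param minRna Minimum total RNA reads across the two alleles
#'   (default 4).
#' @return \code{data.frame}: gene_id, chrom, pos, major_allele,
#'   minor_allele, rna_major, rna_minor, multi_gene.
#' @export
mapExonicSnps <- function(snps, rnaCounts, genes, minRna = 4L) {
    if (nrow(snps) == 0L)
        return(data.frame(gene_id = character(0), chrom = character(0),
                          pos = integer(0), major_allele = character(0),
                          minor_allele = character(0),
                          rna_major = integer(0), rna_minor = integer(0),
                          multi_gene = logical(0)))
    ex <- .exonRanges(genes)
    sgr <- GRanges(snps$chrom, IRanges(snps$pos, width = 1L))
    hits <- findOverlaps(sgr, ex, ignore.strand = TRUE)
    si <- queryHits(hits)
    gid <- mcols(genes)$name[mcols(ex)$geneIdx[subjectHits(hits)]]
    ## one row per (snp, gene)
    dup <- duplicated(paste(si, gid))
    si <- si[!dup]; gid <- gid[!dup]
    nGenes <- table(si)
    rkey <- paste(rnaCounts$chrom, rnaCounts$pos, rnaCounts$allele)
    getCount <- function(i, allele) {
        j <- match(paste(snps$chrom[i], snps$pos[i], allele), rkey)
        ifelse(is.na(j), 0L, rnaCounts$count[j])
    }
    n1 <- getCount(si, snps$allele1[si])
    n2 <- getCount(si, snps$allele2[si])
    keep <- (n1 + n2) >= minRna
    major1 <- n1 >= n2
    data.frame(
        gene_id = gid[keep],
        chrom = snps$chrom[si][keep],
        pos = snps$pos[si][keep],
        major_allele = ifelse(major1, snps$allele1[si],
                              snps$allele2[si])[keep],
        minor_allele = ifelse(major1, snps$allele2[si],
                              snps$allele1[si])[keep],
        rna_major = pmax(n1, n2)[keep],
        rna_minor = pmin(n1, n2)[keep],
        multi_gene = (as.integer(nGenes[as.character(si)]) > 1L)[keep])
}

#' Gene-level allele-specific expression test
#'
#' Sums each exonic SNP's major and minor RNA counts over the gene and
#' tests the total against Binomial(n, 0.5) with the exact two-sided
#' minimum-likelihood test. Significance is assessed by Benjamini-Hochberg
#' FDR control at \code{q} across all tested genes.
#'
#' @param exonicSnps Table from \code{\link{mapExonicSnps}}.
#' @param q FDR level (default 0.01).
#' @return \code{data.frame}: gene_id, n_snps, major_total, minor_total,
#'   p_value, significant.
#' @export
aseTest <- function(exonicSnps, q = 0.01) {
    if (nrow(exonicSnps) == 0L) .stopf("no exonic SNPs to test")
    major <- rowsum(exonicSnps$rna_major, exonicSnps$gene_id)
    minor <- rowsum(exonicSnps$rna_minor, exonicSnps$gene_id)
    nsnp <- rowsum(rep(1L, nrow(exonicSnps)), exonicSnps$gene_id)
    tot <- major[, 1] + minor[, 1]
    if (any(tot == 0L)) .stopf("gene with zero RNA reads")
    p <- binomTwoSided(major[, 1], tot, 0.5)
    data.frame(gene_id = rownames(major),
               n_snps = nsnp[, 1],
               major_total = major[, 1], minor_total = minor[, 1],
               p_value = p,
               significant = p.adjust(p, "BH") <= q,
               row.names = NULL)
}

#' Largest P-value passing Benjamini-Hochberg FDR control
#'
#' The computable analog of a fixed P cutoff quoted for a given FDR level:
#' the largest p among the BH-significant hypotheses (0 when none pass).
#'
#' @param pValues P-values of all tested hypotheses.
#' @param q FDR level (default 0.01).
#' @return The calibrated threshold.
#' @export
calibrateThreshold <- function(pValues, q = 0.01) {
    sig <- p.adjust(pValues, "BH") <= q
    if (!any(sig)) 0 else max(pValues[sig])
}

#' Enrichment of imprinted genes among significant ASE genes
#'
#' Upper-tail hypergeometric test: population = tested gene universe,
#' population successes = significant genes, draws = testable imprinted
#' genes (imprinted genes present in the universe), observed = significant
#' imprinted genes.
#'
#' @param significantGenes Character vector of significant gene ids.
#' @param imprintedGenes Character vector of imprinted gene ids.
#' @param universe Character vector of all tested gene ids.
#' @return List: p_value, n_testable, n_significant_imprinted,
#'   n_significant, n_universe.
#' @export
imprintedEnrichment <- function(significantGenes, imprintedGenes, universe) {
    testable <- intersect(imprintedGenes, universe)
    if (length(testable) == 0L) .stopf("no imprinted gene is testable")
    sig <- intersect(significantGenes, universe)
    k <- length(intersect(sig, testable))
    list(p_value = hyperUpperTail(k, length(sig), length(testable),
                                  length(universe)),
         n_testable = length(testable),
         n_significant_imprinted = k,
         n_significant = length(sig),
         n_universe = length(universe))
}
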
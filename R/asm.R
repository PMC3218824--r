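## Allele-specific methylation: segregating reads by SNP alleles, testing
## per-cytosine differential methylation between the two allele groups,
## gene-level enrichment, and read-backed phasing of methylation patterns.

## base shown by each read (plus orientation) at a genomic position;
## NA when the read does not cover it
.readBaseAt <- function(reads, chrom, pos) {
    off <- pos - reads$start0
    ok <- reads$chrom == chrom & off >= 1L & off <= nchar(reads$seq)
    out <- rep(NA_character_, nrow(reads))
    out[ok] <- substring(reads$seq[ok], off[ok], off[ok])
    out
}

#' Segregate bisulfite reads by the alleles of a heterozygous SNP
#'
#' A read joins the group of the allele it shows at the SNP position.
#' Reads not covering the SNP, showing neither allele, or whose
#' observation at the SNP is bisulfite-ambiguous (a C allele observed as
#' C/T by a Watson read; a G allele observed as G/A by a Crick read) are
#' unassigned.
#'
#' @param reads Read \code{data.frame}.
#' @param snp One-row SNP record with chrom, pos, allele1, allele2.
#' @return List of integer row indices: \code{group1}, \code{group2},
#'   \code{unassigned} (reads covering the SNP only).
#' @export
segregateReads <- function(reads, snp) {
    b <- .readBaseAt(reads, snp$chrom, snp$pos)
    covering <- which(!is.na(b))
    b <- b[covering]
    isW <- reads$bs_strand[covering] == "W"
    alleles <- c(snp$allele1, snp$allele2)
    ambig <- (isW & "C" %in% alleles & b %in% c("C", "T")) |
             (!isW & "G" %in% alleles & b %in% c("G", "A"))
    g1 <- covering[!ambig & b == snp$allele1]
    g2 <- covering[!ambig & b == snp$allele2]
    list(group1 = g1, group2 = g2,
         unassigned = setdiff(covering, c(g1, g2)))
}

#' Double binomial test for allele-specific methylation at one cytosine
#'
#' Given per-allele methylated/total read counts, estimates the
#' methylation probability from group 1 and tests group 2's methylated
#' count against Binomial(n2, k1/n1) with the exact two-sided
#' minimum-likelihood test; the test is repeated with the groups swapped
#' and the larger P-value is returned. Degenerate estimated probabilities
#' (0 or 1) are handled exactly through the point-mass distribution.
#'
#' @param k1,n1 Methylated and total reads for allele 1 (vectorized).
#' @param k2,n2 Same for allele 2.
#' @return P-value(s); symmetric in the group labels.
#' @export
asmTest <- function(k1, n1, k2, n2) {
    stopifnot(all(n1 >= 1L), all(n2 >= 1L))
    pA <- binomTwoSided(k2, n2, k1 / n1)
    pB <- binomTwoSided(k1, n1, k2 / n2)
    pmax(pA, pB)
}

## pile methylation evidence of one read group over cytosines of given
## context; returns data.frame(chrom,pos,strand,meth,total)
.pileGroup <- function(reads, genome, context = "CG") {
    m <- callMethylation(reads, genome, filterNonconverted = FALSE)
    mt <- methTable(m)
    mt[mt$context3 == context, c("chrom", "pos", "strand", "meth", "total"),
       drop = FALSE]
}

#' Scan for allele-specifically methylated cytosines
#'
#' For every called heterozygous SNP, reads are segregated by allele and
#' the CG-context cytosines covered by both groups become candidates;
#' each candidate is tested with \code{\link{asmTest}}. A cytosine linked
#' to several SNPs keeps the anchor SNP giving the largest combined
#' coverage. Significance is Benjamini-Hochberg FDR control at \code{q}
#' across all tested cytosines.
#'
#' @param reads Read \code{data.frame}.
#' @param snps SNP table (\code{\link{callSnps}} output or compatible).
#' @param genome A \code{DNAStringSet}.
#' @param q FDR level (default 0.05).
#' @param context Cytosine context tested (default \code{"CG"}).
#' @return \code{data.frame}: chrom, pos, strand, snp_pos, meth1, total1,
#'   meth2, total2, p_value, significant. The fraction of candidate
#'   cytosines called differentially methylated is in attribute
#'   \code{"fraction_significant"}.
#' @export
asmScan <- function(reads, snps, genome, q = 0.05, context = "CG") {
    recs <- list()
    for (i in seq_len(nrow(snps))) {
        snp <- snps[i, ]
        grp <- segregateReads(reads, snp)
        if (!length(grp$group1) || !length(grp$group2)) next
        p1 <- .pileGroup(reads[grp$group1, , drop = FALSE], genome, context)
        p2 <- .pileGroup(reads[grp$group2, , drop = FALSE], genome, context)
        if (!nrow(p1) || !nrow(p2)) next
        j <- match(.siteKey(p1$chrom, p1$pos, p1$strand),
                   .siteKey(p2$chrom, p2$pos, p2$strand))
        keep <- which(!is.na(j))
        if (!length(keep)) next
        recs[[length(recs) + 1L]] <- data.frame(
            chrom = p1$chrom[keep], pos = p1$pos[keep],
            strand = p1$strand[keep], snp_pos = snp$pos,
            meth1 = p1$meth[keep], total1 = p1$total[keep],
            meth2 = p2$meth[j[keep]], total2 = p2$total[j[keep]])
    }
    if (!length(recs))
        return(structure(data.frame(chrom = character(0), pos = integer(0),
                                    strand = character(0),
                                    snp_pos = integer(0),
                                    meth1 = integer(0), total1 = integer(0),
                                    meth2 = integer(0), total2 = integer(0),
                                    p_value = numeric(0),
                                    significant = logical(0)),
                         fraction_significant = NA_real_))
    df <- do.call(rbind, recs)
    ## one anchor SNP per cytosine: the best-covered linkage
    ord <- order(df$chrom, df$pos, df$strand, -(df$total1 + df$total2))
    df <- df[ord, , drop = FALSE]
    df <- df[!duplicated(.siteKey(df$chrom, df$pos, df$strand)), ,
             drop = FALSE]
    df$p_value <- asmTest(df$meth1, df$total1, df$meth2, df$total2)
    df$significant <- p.adjust(df$p_value, "BH") <= q
    rownames(df) <- NULL
    attr(df, "fraction_significant") <- mean(df$significant)
    df
}

#' Gene-level enrichment of allele-specifically methylated cytosines
#'
#' For genes with at least \code{minTested} tested cytosines, tests
#' whether the number of significant cytosines exceeds what the
#' genome-wide significant rate predicts (upper-tail binomial), with
#' Benjamini-Hochberg control at \code{q}.
#'
#' @param geneSites \code{data.frame} with gene_id, n_tested,
#'   n_significant per gene (see \code{\link{asmGeneTable}}).
#' @param globalRate Genome-wide fraction of tested cytosines that are
#'   significant.
#' @param q FDR level (default 0.05).
#' @param minTested Minimum tested cytosines per gene (default 3).
#' @return Input with p_value and enriched columns appended.
#' @export
geneAsmEnrichment <- function(geneSites, globalRate, q = 0.05,
                              minTested = 3L) {
    df <- geneSites[geneSites$n_tested >= minTested, , drop = FALSE]
    if (nrow(df) == 0L) .stopf("no genes with enough tested cytosines")
    df$p_value <- pbinom(df$n_significant - 1L, df$n_tested, globalRate,
                         lower.tail = FALSE)
    df$enriched <- p.adjust(df$p_value, "BH") <= q
    df
}

#' Summarize ASM sites per gene
#'
#' @param asmSites Output of \code{\link{asmScan}}.
#' @param genes BED12-style \code{GRanges} with \code{name} and
#'   \code{blocks}.
#' @return \code{data.frame}: gene_id, n_tested, n_significant (sites
#'   inside the gene span).
#' @export
asmGeneTable <- function(asmSites, genes) {
    sgr <- GRanges(asmSites$chrom, IRanges(asmSites$pos, width = 1L))
    hits <- findOverlaps(sgr, granges(genes), ignore.strand = TRUE)
    gid <- mcols(genes)$name[subjectHits(hits)]
    sig <- asmSites$significant[queryHits(hits)]
    nT <- rowsum(rep(1L, length(gid)), gid)
    nS <- rowsum(as.integer(sig), gid)
    data.frame(gene_id = rownames(nT), n_tested = nT[, 1],
               n_significant = nS[, 1], row.names = NULL)
}

#' Phase methylation patterns onto the two alleles of a SNP
#'
#' For reads spanning both the SNP and a CG-context cytosine, reports the
#' methylated fraction per allele at each linked cytosine, in genomic
#' order: the read-backed reconstruction of the two parental methylation
#' patterns.
#'
#' @param reads Read \code{data.frame}.
#' @param snp One-row SNP record (chrom, pos, allele1, allele2).
#' @param cgSites \code{data.frame} of candidate cytosines (chrom, pos,
#'   strand), e.g. the CG rows of \code{\link{cytosineSites}} or
#'   \code{\link{methTable}}.
#' @param genome A \code{DNAStringSet}.
#' @return \code{data.frame}: chrom, pos, strand, frac1, n1, frac2, n2 for
#'   every linked cytosine (zero rows when no read spans both).
#' @export
phaseMethylation <- function(reads, snp, cgSites, genome) {
    grp <- segregateReads(reads, snp)
    phase1 <- .pileGroup(reads[grp$group1, , drop = FALSE], genome, "CG")
    phase2 <- .pileGroup(reads[grp$group2, , drop = FALSE], genome, "CG")
    want <- .siteKey(cgSites$chrom, cgSites$pos, cgSites$strand)
    k1 <- .siteKey(phase1$chrom, phase1$pos, phase1$strand)
    k2 <- .siteKey(phase2$chrom, phase2$pos, phase2$strand)
    keys <- union(intersect(k1, want), intersect(k2, want))
    if (!length(keys))
        return(data.frame(chrom = character(0), pos = integer(0),
                          strand = character(0), frac1 = numeric(0),
                          n1 = integer(0), frac2 = numeric(0),
                          n2 = integer(0)))
    i1 <- match(keys, k1); i2 <- match(keys, k2)
    out <- data.frame(
        chrom = sub(":.*", "", keys),
        pos = as.integer(sub("^[^:]+:([0-9]+):.*$", "\\1", keys)),
        strand = sub(".*:", "", keys),
        frac1 = ifelse(is.na(i1), NA_real_,
                       phase1$meth[i1] / phase1$total[i1]),
        n1 = ifelse(is.na(i1), 0L, phase1$total[i1]),
        frac2 = ifelse(is.na(i2), NA_real_,
                       phase2$meth[i2] / phase2$total[i2]),
        n2 = ifelse(is.na(i2), 0L, phase2$total[i2]))
    out[order(out$chrom, out$pos, out$strand), , drop = FALSE]
}
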
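## Cross-line conservation of per-site methylation, flanking-sequence
## motifs, splice-site CHG profiles and strand-symmetry contingency tables.

.CG_BINS <- c("low", "medium", "high")
.NONCG_BINS <- c("none", "low", "high")

#' Bin a methylation level
#'
#' CG sites use integer-percent bins low [0,33], medium [34,66],
#' high [67,100] (the percent is rounded so the printed integer edges
#' partition exactly). Non-CG sites use none (no methylated read),
#' low (0,30] and high (30,100].
#'
#' @param level Methylation level(s) in [0,1].
#' @param methCount Methylated read count(s) (distinguishes "none" from a
#'   level that merely rounds to zero for non-CG sites).
#' @param contextClass \code{"CG"} or \code{"nonCG"}.
#' @return Factor of bin labels.
#' @export
categorizeLevel <- function(level, methCount, contextClass = c("CG", "nonCG")) {
    contextClass <- match.arg(contextClass)
    stopifnot(all(level >= 0 & level <= 1, na.rm = TRUE))
    if (contextClass == "CG") {
        p <- round(100 * level)
        factor(ifelse(p <= 33, "low", ifelse(p <= 66, "medium", "high")),
               levels = .CG_BINS)
    } else {
        factor(ifelse(methCount == 0L, "none",
                      ifelse(level > 0.30, "high", "low")),
               levels = .NONCG_BINS)
    }
}

## covered, context-filtered site table with levels and bins
.binnedSites <- function(methylome, contextClass, minCoverage) {
    df <- methTable(methylome)
    keep <- df$total >= minCoverage &
        (if (contextClass == "CG") df$context3 == "CG"
         else df$context3 %in% c("CHG", "CHH"))
    df <- df[keep, , drop = FALSE]
    df$level <- df$meth / df$total
    df$bin <- categorizeLevel(df$level, df$meth, contextClass)
    df$key <- .siteKey(df$chrom, df$pos, df$strand)
    df
}

#' Cross-line conservation contingency table
#'
#' Sites covered by at least \code{minCoverage} reads in both methylomes
#' are binned per line (\code{\link{categorizeLevel}}); the 3x3 observed
#' table is compared with the expected table under independence of the two
#' lines. A site is conserved when it falls in the same bin in both lines,
#' so the conserved fraction is \code{\link{concordantFraction}} of the
#' result.
#'
#' @param methylomeA,methylomeB \code{\linkS4class{Methylome}}s on the same
#'   genome.
#' @param contextClass \code{"CG"} or \code{"nonCG"}.
#' @param minCoverage Minimum informative reads per site in each line.
#' @return A \code{\linkS4class{ContingencySummary}}.
#' @export
conservationContingency <- function(methylomeA, methylomeB,
                                    contextClass = c("CG", "nonCG"),
                                    minCoverage = 4L) {
    contextClass <- match.arg(contextClass)
    a <- .binnedSites(methylomeA, contextClass, minCoverage)
    b <- .binnedSites(methylomeB, contextClass, minCoverage)
    i <- match(a$key, b$key)
    keep <- !is.na(i)
    if (!any(keep)) .stopf("no sites covered in both methylomes")
    obs <- table(A = a$bin[keep], B = b$bin[i[keep]])
    .contingency(unclass(obs))
}

#' Classify non-CG sites by conservation of methylation
#'
#' Splits jointly covered non-CG sites between two lines into the three
#' classes used for motif analysis: conserved highly methylated (high bin
#' in both lines), unconserved methylated (high in exactly one line and
#' none in the other) and unmethylated (none in both).
#'
#' @inheritParams conservationContingency
#' @return Named list of \code{data.frame}s (\code{conserved_high},
#'   \code{unconserved_methylated}, \code{unmethylated}) with chrom, pos,
#'   strand columns.
#' @export
conservationClasses <- function(methylomeA, methylomeB, minCoverage = 4L) {
    a <- .binnedSites(methylomeA, "nonCG", minCoverage)
    b <- .binnedSites(methylomeB, "nonCG", minCoverage)
    i <- match(a$key, b$key)
    keep <- which(!is.na(i))
    a <- a[keep, , drop = FALSE]
    binB <- b$bin[i[keep]]
    pick <- function(sel) a[sel, c("chrom", "pos", "strand"), drop = FALSE]
    list(
        conserved_high = pick(a$bin == "high" & binB == "high"),
        unconserved_methylated = pick((a$bin == "high" & binB == "none") |
                                      (a$bin == "none" & binB == "high")),
        unmethylated = pick(a$bin == "none" & binB == "none")
    )
}

#' Position frequency matrix of site flanks
#'
#' Builds base counts over offsets -k..+k around each site, oriented so the
#' site cytosine is at offset 0 read 5'->3' on its own strand (minus-strand
#' flanks are reverse-complemented). Sites closer than k to a chromosome
#' edge are dropped and counted.
#'
#' @param sites \code{data.frame} with chrom, pos, strand.
#' @param genome A \code{DNAStringSet}.
#' @param k Flank width (default 5).
#' @return A \code{\linkS4class{PositionFrequencyMatrix}}.
#' @export
buildFlankPfm <- function(sites, genome, k = 5L) {
    if (nrow(sites) == 0L) .stopf("empty site class")
    raws <- .genomeRaw(genome)
    counts <- matrix(0L, 4L, 2L * k + 1L,
                     dimnames = list(c("A", "C", "G", "T"),
                                     as.character(-k:k)))
    dropped <- 0L
    for (cn in unique(sites$chrom)) {
        s <- raws[[cn]]
        L <- length(s)
        sub <- sites[sites$chrom == cn, , drop = FALSE]
        ok <- sub$pos - k >= 1L & sub$pos + k <= L
        dropped <- dropped + sum(!ok)
        sub <- sub[ok, , drop = FALSE]
        if (!nrow(sub)) next
        m <- s[outer(sub$pos, -k:k, "+")]
        dim(m) <- c(nrow(sub), 2L * k + 1L)
        minus <- sub$strand == "-"
        if (any(minus))  # reverse-complement minus-strand flanks
            m[minus, ] <- .comp(m[minus, rev(seq_len(ncol(m))), drop = FALSE])
        for (j in seq_len(ncol(m)))
            for (b in .BASES)
                counts[b, j] <- counts[b, j] + sum(m[, j] == charToRaw(b))
    }
    new("PositionFrequencyMatrix", counts = counts,
        nSites = as.integer(nrow(sites) - dropped),
        nDropped = as.integer(dropped))
}

#' Fraction of sites lying in a TACAG 5-mer
#'
#' @inheritParams buildFlankPfm
#' @return Fraction of sites whose strand-local -2..+2 5-mer is TACAG.
#' @export
tacagFraction <- function(sites, genome) {
    if (nrow(sites) == 0L) .stopf("empty site class")
    ctx <- assignContext(genome, sites$chrom, sites$pos, sites$strand)
    mean(ctx$is_tacag)
}

## acceptor/donor junction positions of internal exon boundaries;
## offset convention (3p): -1 = last intronic base (the acceptor G),
## 0 = first exonic base, measured along the coding strand
.junctionPositions <- function(genes, side, offsets) {
    recs <- list()
    for (i in seq_along(genes)) {
        b <- mcols(genes)$blocks[[i]]
        if (nrow(b) < 2L) next
        st <- as.character(strand(genes))[i]
        cn <- as.character(seqnames(genes))[i]
        if (side == "3p") {
            ## acceptor of every non-first exon (transcript order)
            bound0 <- if (st == "+") b[-1L, "start"] else b[-nrow(b), "end"] - 1L
        } else {
            ## first intronic base after every non-last exon
            bound0 <- if (st == "+") b[-nrow(b), "end"] else b[-1L, "start"] - 1L
        }
        for (b0 in bound0) {
            pos0 <- if (st == "+") b0 + offsets else b0 - offsets
            recs[[length(recs) + 1L]] <-
                data.frame(chrom = cn, pos = pos0 + 1L, strand = st,
                           offset = offsets)
        }
    }
    if (!length(recs)) .stopf("no multi-exon genes")
    do.call(rbind, recs)
}

#' CHG methylation profile around splice sites
#'
#' For each offset of a window around exon junctions (measured on the
#' coding strand; at 3' splice sites offset -1 is the last intronic base,
#' the acceptor G, and the exon starts at offset 0) this counts
#' coding-strand CHG cytosines across all junctions of multi-exon genes,
#' and among those covered by at least \code{minCoverage} reads the
#' fraction with methylation level above \code{highThreshold}.
#'
#' @param methylome A \code{\linkS4class{Methylome}}.
#' @param genes BED12-style \code{GRanges} with \code{blocks} metadata.
#' @param genome A \code{DNAStringSet}.
#' @param side \code{"3p"} (acceptor) or \code{"5p"} (donor).
#' @param window Integer offsets (default -20..+5).
#' @param highThreshold Level above which a CHG site counts as highly
#'   methylated (default 0.30).
#' @param minCoverage Minimum reads for the methylation fraction.
#' @return \code{data.frame}: offset, n_chg, n_covered, frac_high.
#' @export
spliceSiteProfile <- function(methylome, genes, genome,
                              side = c("3p", "5p"), window = -20:5,
                              highThreshold = 0.30, minCoverage = 4L) {
    side <- match.arg(side)
    jx <- .junctionPositions(genes, side, window)
    raws <- .genomeRaw(genome)
    ## CHG test at each (chrom,pos,strand)
    isChg <- logical(nrow(jx))
    for (cn in unique(jx$chrom)) {
        s <- raws[[cn]]
        L <- length(s)
        sel <- which(jx$chrom == cn)
        pos <- jx$pos[sel]
        inb <- pos >= 1L & pos <= L
        onC <- inb & ifelse(jx$strand[sel] == "+",
                            s[pmax(pos, 1L)] == .rawC,
                            s[pmax(pos, 1L)] == .rawG)
        idx <- sel[which(onC)]
        if (!length(idx)) next
        ctx <- .contextAt(s, jx$pos[idx], jx$strand[idx])
        isChg[idx] <- !is.na(ctx$context3) & ctx$context3 == "CHG"
    }
    jx <- jx[isChg, , drop = FALSE]
    mt <- methTable(methylome)
    mt <- mt[mt$total >= minCoverage, , drop = FALSE]
    i <- match(.siteKey(jx$chrom, jx$pos, jx$strand),
               .siteKey(mt$chrom, mt$pos, mt$strand))
    lev <- (mt$meth / mt$total)[i]
    out <- data.frame(offset = window)
    out$n_chg <- vapply(window, function(o) sum(jx$offset == o), integer(1))
    out$n_covered <- vapply(window, function(o)
        sum(jx$offset == o & !is.na(lev)), integer(1))
    out$frac_high <- vapply(window, function(o) {
        l <- lev[jx$offset == o]
        l <- l[!is.na(l)]
        if (!length(l)) return(NA_real_)
        mean(l > highThreshold)
    }, numeric(1))
    out
}

## exon GRanges (1-based) from BED12 blocks, with gene index and block rank
.exonRanges <- function(genes) {
    blocks <- mcols(genes)$blocks
    nb <- vapply(blocks, nrow, integer(1))
    geneIdx <- rep(seq_along(genes), nb)
    b <- do.call(rbind, blocks)
    gr <- GRanges(rep(as.character(seqnames(genes)), nb),
                  IRanges(b[, "start"] + 1L, b[, "end"]),
                  strand = rep(as.character(strand(genes)), nb))
    mcols(gr)$geneIdx <- geneIdx
    mcols(gr)$rank <- unlist(lapply(nb, seq_len))
    mcols(gr)$nblocks <- nb[geneIdx]
    gr
}

#' Methylation of alternative versus interior exons
#'
#' Unweighted mean CG and non-CG methylation levels over sites (covered at
#' \code{minCoverage}) inside alternatively spliced exons versus interior
#' exons (non-first, non-last blocks not flagged alternative).
#'
#' @param methylome A \code{\linkS4class{Methylome}}.
#' @param genes BED12-style \code{GRanges} with \code{blocks}.
#' @param altExons \code{GRanges} of alternative (cassette) exons, or
#'   \code{NULL}.
#' @param minCoverage Minimum reads per site.
#' @return \code{data.frame}: exon_class, cg_level, noncg_level, n_cg,
#'   n_noncg (\code{NA} levels for empty classes).
#' @export
exonClassMethylation <- function(methylome, genes, altExons,
                                 minCoverage = 4L) {
    ex <- .exonRanges(genes)
    interior <- ex[mcols(ex)$rank > 1L & mcols(ex)$rank < mcols(ex)$nblocks]
    haveAlt <- !is.null(altExons) && length(altExons) > 0L
    if (haveAlt)
        interior <- interior[!overlapsAny(interior, altExons,
                                          ignore.strand = TRUE)]
    mt <- methTable(methylome)
    mt <- mt[mt$total >= minCoverage, , drop = FALSE]
    sgr <- GRanges(mt$chrom, IRanges(mt$pos, width = 1L))
    classMeans <- function(target) {
        if (is.null(target) || length(target) == 0L)
            return(c(NA_real_, NA_real_, 0L, 0L))
        hit <- overlapsAny(sgr, target, ignore.strand = TRUE)
        lev <- mt$meth[hit] / mt$total[hit]
        cg <- mt$context3[hit] == "CG"
        c(if (any(cg)) mean(lev[cg]) else NA_real_,
          if (any(!cg)) mean(lev[!cg]) else NA_real_,
          sum(cg), sum(!cg))
    }
    a <- classMeans(if (haveAlt) altExons else NULL)
    b <- classMeans(interior)
    data.frame(exon_class = c("alternative", "interior"),
               cg_level = c(a[1], b[1]), noncg_level = c(a[2], b[2]),
               n_cg = c(a[3], b[3]), n_noncg = c(a[4], b[4]))
}

#' Non-CG methylation at splice-site windows versus the rest of gene bodies
#'
#' @param methylome A \code{\linkS4class{Methylome}}.
#' @param genes BED12-style \code{GRanges} with \code{blocks}.
#' @param flank Half-width of the splice-site window around each internal
#'   exon junction (default 20 bp).
#' @param minCoverage Minimum reads per site.
#' @return \code{data.frame}: region (splice_site / gene_body),
#'   noncg_level, n_sites.
#' @export
spliceVsGeneBody <- function(methylome, genes, flank = 20L,
                             minCoverage = 4L) {
    ex <- .exonRanges(genes)
    junc <- c(GRanges(seqnames(ex)[mcols(ex)$rank > 1L],
                      IRanges(start(ex)[mcols(ex)$rank > 1L] - flank,
                              start(ex)[mcols(ex)$rank > 1L] + flank)),
              GRanges(seqnames(ex)[mcols(ex)$rank < mcols(ex)$nblocks],
                      IRanges(end(ex)[mcols(ex)$rank <
                                      mcols(ex)$nblocks] - flank,
                              end(ex)[mcols(ex)$rank <
                                      mcols(ex)$nblocks] + flank)))
    junc <- reduce(junc)
    body <- reduce(GRanges(seqnames(genes),
                           IRanges(start(genes), end(genes))))
    mt <- methTable(methylome)
    mt <- mt[mt$total >= minCoverage &
             mt$context3 %in% c("CHG", "CHH"), , drop = FALSE]
    sgr <- GRanges(mt$chrom, IRanges(mt$pos, width = 1L))
    inBody <- overlapsAny(sgr, body, ignore.strand = TRUE)
    inJunc <- overlapsAny(sgr, junc, ignore.strand = TRUE) & inBody
    lev <- mt$meth / mt$total
    data.frame(
        region = c("splice_site", "gene_body"),
        noncg_level = c(if (any(inJunc)) mean(lev[inJunc]) else NA_real_,
                        if (any(inBody & !inJunc))
                            mean(lev[inBody & !inJunc]) else NA_real_),
        n_sites = c(sum(inJunc), sum(inBody & !inJunc)))
}

#' Strand symmetry of CG or CHG methylation
#'
#' Builds the 2x2 contingency table of the methylation status of the two
#' cytosines of a dyad: for CG, the plus-strand C at i paired with the
#' minus-strand C at i+1; for CHG, the plus-strand CHG at i paired with the
#' minus-strand CHG whose C pairs with the G at i+2 (both members must be
#' CHG, i.e. the central base is A or T). Both members must be covered by
#' \code{minCoverage} reads. For \code{stratum = "all"} the per-strand
#' factor is level > \code{binarizeThreshold}; for \code{"low"} /
#' \code{"high"} it is membership in that stratum (level < 0.30 /
#' level > 0.30). Expected counts assume independence of the two strands.
#'
#' @param methylome A \code{\linkS4class{Methylome}}.
#' @param genome A \code{DNAStringSet}.
#' @param contextClass \code{"CG"} or \code{"CHG"}.
#' @param binarizeThreshold Level above which a strand counts as methylated
#'   (default 0).
#' @param stratum \code{"all"}, \code{"low"} or \code{"high"}.
#' @param minCoverage Minimum reads per dyad member.
#' @return A \code{\linkS4class{ContingencySummary}} (2x2; "yes" = factor
#'   true on that strand). The symmetric fraction is its
#'   \code{\link{concordantFraction}}.
#' @export
symmetryAnalysis <- function(methylome, genome,
                             contextClass = c("CG", "CHG"),
                             binarizeThreshold = 0,
                             stratum = c("all", "low", "high"),
                             minCoverage = 4L) {
    contextClass <- match.arg(contextClass)
    stratum <- match.arg(stratum)
    gap <- if (contextClass == "CG") 1L else 2L
    mt <- methTable(methylome)
    mt <- mt[mt$total >= minCoverage & mt$context3 == contextClass, ,
             drop = FALSE]
    plus <- mt[mt$strand == "+", , drop = FALSE]
    minus <- mt[mt$strand == "-", , drop = FALSE]
    i <- match(.siteKey(plus$chrom, plus$pos + gap, "-"),
               .siteKey(minus$chrom, minus$pos, minus$strand))
    keep <- which(!is.na(i))
    if (!length(keep)) .stopf("no qualifying dyads")
    lp <- plus$meth[keep] / plus$total[keep]
    lm <- minus$meth[i[keep]] / minus$total[i[keep]]
    f <- switch(stratum,
                all = cbind(lp > binarizeThreshold, lm > binarizeThreshold),
                low = cbind(lp < 0.30, lm < 0.30),
                high = cbind(lp > 0.30, lm > 0.30))
    lab <- c("yes", "no")
    obs <- table(plusC = factor(ifelse(f[, 1], "yes", "no"), levels = lab),
                 minusC = factor(ifelse(f[, 2], "yes", "no"), levels = lab))
    .contingency(unclass(obs))
}
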
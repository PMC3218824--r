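## Context classification and methylation calling from aligned bisulfite
## reads. Watson (W) fragments report plus-strand cytosines: read C =
## methylated, read T = unmethylated. Crick (C) fragments, stored in
## plus-strand orientation, report minus-strand cytosines (plus-strand G
## positions): read G = methylated, read A = unmethylated.

## per-chromosome vectorized context assignment; pos 1-based, on `strand`
.contextAt <- function(s, pos, strand) {
    L <- length(s)
    n <- length(pos)
    context3 <- rep(NA_character_, n)
    dinuc <- rep(NA_character_, n)
    tacag <- rep(FALSE, n)
    plus <- strand == "+"
    ## next two bases read 5'->3' on the site's strand
    nxt <- rep(as.raw(0), n); nxt2 <- rep(as.raw(0), n)
    ok1 <- logical(n); ok2 <- logical(n)
    p <- pos[plus]
    ok1[plus] <- p + 1L <= L
    ok2[plus] <- p + 2L <= L
    nxt[plus][ok1[plus]] <- s[p[ok1[plus]] + 1L]
    nxt2[plus][ok2[plus]] <- s[p[ok2[plus]] + 2L]
    q <- pos[!plus]
    ok1[!plus] <- q - 1L >= 1L
    ok2[!plus] <- q - 2L >= 1L
    nxt[!plus][ok1[!plus]] <- .comp(s[q[ok1[!plus]] - 1L])
    nxt2[!plus][ok2[!plus]] <- .comp(s[q[ok2[!plus]] - 2L])

    isg1 <- ok1 & nxt == .rawG
    context3[isg1] <- "CG"
    isg2 <- ok1 & ok2 & !isg1 & nxt2 == .rawG &
        (nxt == .rawA | nxt == .rawC | nxt == .rawT)
    context3[isg2] <- "CHG"
    ishh <- ok1 & ok2 & !isg1 & !isg2 &
        (nxt == .rawA | nxt == .rawC | nxt == .rawT) &
        (nxt2 == .rawA | nxt2 == .rawC | nxt2 == .rawG | nxt2 == .rawT)
    context3[ishh] <- "CHH"

    known <- !is.na(context3)
    dn <- rep(NA_character_, n)
    dn[known & nxt == .rawG] <- "CG"
    dn[known & nxt == .rawA] <- "CA"
    dn[known & nxt == .rawC] <- "CC"
    dn[known & nxt == .rawT] <- "CT"
    dinuc <- dn

    ## TACAG: strand-local 5-mer at offsets -2..+2; on the minus strand this
    ## is plus-strand CTGTA centred on the G
    can <- pos - 2L >= 1L & pos + 2L <= L
    ci <- which(can & plus)
    if (length(ci)) {
        m <- s[outer(pos[ci], -2:2, "+")]
        dim(m) <- c(length(ci), 5L)
        tacag[ci] <- m[, 1] == .rawT & m[, 2] == .rawA & m[, 3] == .rawC &
            m[, 4] == .rawA & m[, 5] == .rawG
    }
    ci <- which(can & !plus)
    if (length(ci)) {
        m <- s[outer(pos[ci], -2:2, "+")]
        dim(m) <- c(length(ci), 5L)
        tacag[ci] <- m[, 1] == .rawC & m[, 2] == .rawT & m[, 3] == .rawG &
            m[, 4] == .rawT & m[, 5] == .rawA
    }
    list(context3 = context3, dinuc = dinuc, is_tacag = tacag)
}

#' Classify the sequence context of a cytosine
#'
#' Reads the named strand 5'->3' (the minus strand as the reverse
#' complement of the plus strand). The context is CG if the next base is G,
#' CHG if the base after next is G, otherwise CHH; \code{dinuc} is the
#' cytosine plus its next base; \code{is_tacag} is \code{TRUE} iff the
#' 5-mer at offsets -2..+2 around the cytosine reads TACAG on that strand.
#' Sites with insufficient downstream sequence get \code{NA} context and
#' are excluded from methylomes.
#'
#' @param genome A \code{DNAStringSet}.
#' @param chrom,pos,strand Parallel vectors locating cytosines (1-based
#'   positions).
#' @return A \code{data.frame} with columns \code{context3}, \code{dinuc},
#'   \code{is_tacag}.
#' @export
assignContext <- function(genome, chrom, pos, strand) {
    raws <- .genomeRaw(genome)
    n <- length(pos)
    out <- data.frame(context3 = rep(NA_character_, n),
                      dinuc = rep(NA_character_, n),
                      is_tacag = rep(FALSE, n))
    for (cn in unique(chrom)) {
        sel <- chrom == cn
        s <- raws[[cn]]
        if (is.null(s)) .stopf("unknown chromosome: %s", cn)
        base <- s[pos[sel]]
        onC <- ifelse(strand[sel] == "+", base == .rawC, base == .rawG)
        if (!all(onC))
            .stopf("position %d (%s) is not a cytosine on strand %s",
                   pos[sel][!onC][1], cn, strand[sel][!onC][1])
        ctx <- .contextAt(s, pos[sel], strand[sel])
        out$context3[sel] <- ctx$context3
        out$dinuc[sel] <- ctx$dinuc
        out$is_tacag[sel] <- ctx$is_tacag
    }
    out
}

#' All cytosine sites of a genome
#'
#' @param genome A \code{DNAStringSet}.
#' @return \code{data.frame} with chrom, pos (1-based), strand, context3,
#'   dinuc, is_tacag for every classifiable cytosine on both strands
#'   (positions over N and chromosome-edge sites are excluded).
#' @export
cytosineSites <- function(genome) {
    raws <- .genomeRaw(genome)
    parts <- lapply(names(raws), function(cn) {
        s <- raws[[cn]]
        pp <- which(s == .rawC)
        pm <- which(s == .rawG)
        pos <- c(pp, pm)
        strand <- rep(c("+", "-"), c(length(pp), length(pm)))
        ctx <- .contextAt(s, pos, strand)
        keep <- !is.na(ctx$context3)
        data.frame(chrom = cn, pos = pos[keep], strand = strand[keep],
                   context3 = ctx$context3[keep], dinuc = ctx$dinuc[keep],
                   is_tacag = ctx$is_tacag[keep])
    })
    out <- do.call(rbind, parts)
    out[order(out$chrom, out$pos, out$strand), , drop = FALSE]
}

#' Flag non-converted reads
#'
#' A read is considered to have escaped bisulfite conversion when it shows
#' three or more consecutive methylated non-CG cytosines ("more than two in
#' a row"), counted along the read's own non-CG cytosine positions on its
#' bisulfite strand regardless of genomic gaps. CG positions are skipped;
#' any unmethylated or unreadable non-CG call breaks the run.
#'
#' @param reads Read \code{data.frame} (see \code{\link{readBsReads}}).
#' @param genome A \code{DNAStringSet}.
#' @param maxRun Longest tolerated run of methylated non-CG calls
#'   (default 2).
#' @return Logical vector, \code{TRUE} for reads to discard.
#' @export
isNonconverted <- function(reads, genome, maxRun = 2L) {
    out <- logical(nrow(reads))
    if (nrow(reads) == 0L) return(out)
    raws <- .genomeRaw(genome)
    ex <- .expandReads(reads)
    for (cn in unique(reads$chrom)) {
        s <- raws[[cn]]
        L <- length(s)
        sel <- which(ex$chrom == cn)
        pos <- ex$pos[sel]
        gb <- s[pos]
        isW <- ex$isW[sel]
        ## non-CG cytosine positions on the read's bisulfite strand
        siteW <- isW & gb == .rawC
        ## plus-strand context: CG iff next base G; edge (pos==L) unknown
        nonCgW <- siteW & pos < L & s[pmin(pos + 1L, L)] != .rawG
        siteC <- !isW & gb == .rawG
        nonCgC <- siteC & pos > 1L & s[pmax(pos - 1L, 1L)] != .rawC
        keep <- which(nonCgW | nonCgC)
        if (!length(keep)) next
        meth <- ifelse(isW[keep], ex$base[sel][keep] == .rawC,
                       ex$base[sel][keep] == .rawG)
        badIdx <- .hasRunAtLeast(meth, ex$readIdx[sel][keep], maxRun + 1L)
        out[badIdx] <- TRUE
    }
    out
}

#' Call per-cytosine methylation from aligned bisulfite reads
#'
#' For every genomic cytosine on each strand, counts reads of the matching
#' bisulfite strand showing C (methylated) or T (unmethylated); other bases
#' are ignored. Reads failing the non-conversion filter are discarded first
#' (their number is recorded in the \code{"nonconverted"} attribute).
#' Contexts are attached via \code{\link{assignContext}}; cytosines with no
#' informative read are absent.
#'
#' @param reads Read \code{data.frame}.
#' @param genome A \code{DNAStringSet}.
#' @param filterNonconverted Apply the non-conversion read filter
#'   (default \code{TRUE}).
#' @return A \code{\linkS4class{Methylome}} of covered cytosines.
#' @export
callMethylation <- function(reads, genome, filterNonconverted = TRUE) {
    validateBsReads(reads, genome)
    nDiscarded <- 0L
    if (filterNonconverted && nrow(reads)) {
        bad <- isNonconverted(reads, genome)
        nDiscarded <- sum(bad)
        reads <- reads[!bad, , drop = FALSE]
    }
    raws <- .genomeRaw(genome)
    parts <- list()
    ex <- if (nrow(reads)) .expandReads(reads) else NULL
    for (cn in names(raws)) {
        s <- raws[[cn]]
        L <- length(s)
        sel <- if (is.null(ex)) integer(0) else which(ex$chrom == cn)
        pos <- ex$pos[sel]; base <- ex$base[sel]; isW <- ex$isW[sel]
        gb <- s[pos]
        ## plus-strand cytosines (W reads)
        wSite <- isW & gb == .rawC
        methP <- tabulate(pos[wSite & base == .rawC], nbins = L)
        totP <- methP + tabulate(pos[wSite & base == .rawT], nbins = L)
        ## minus-strand cytosines (Crick reads; G = methylated C on minus)
        cSite <- !isW & gb == .rawG
        methM <- tabulate(pos[cSite & base == .rawG], nbins = L)
        totM <- methM + tabulate(pos[cSite & base == .rawA], nbins = L)
        pp <- which(totP > 0L); pm <- which(totM > 0L)
        if (!length(pp) && !length(pm)) next
        posAll <- c(pp, pm)
        strandAll <- rep(c("+", "-"), c(length(pp), length(pm)))
        ctx <- .contextAt(s, posAll, strandAll)
        keep <- !is.na(ctx$context3)
        parts[[cn]] <- data.frame(
            chrom = cn, pos = posAll[keep], strand = strandAll[keep],
            context3 = ctx$context3[keep], dinuc = ctx$dinuc[keep],
            is_tacag = ctx$is_tacag[keep],
            meth = c(methP[pp], methM[pm])[keep],
            total = c(totP[pp], totM[pm])[keep])
    }
    df <- if (length(parts)) do.call(rbind, parts) else
        data.frame(chrom = character(0), pos = integer(0),
                   strand = character(0), context3 = character(0),
                   dinuc = character(0), is_tacag = logical(0),
                   meth = integer(0), total = integer(0))
    m <- Methylome(df$chrom, df$pos, df$strand, df$context3, df$dinuc,
                   df$is_tacag, df$meth, df$total)
    attr(m, "nonconverted") <- nDiscarded
    m
}

.GLOBAL_LABELS <- c("CG", "CHG", "CHH", "CA", "CT", "CC", "CAG", "TACAG")

#' Global methylation levels per context
#'
#' Mean methylation level for each context label over cytosines covered by
#' at least \code{minCoverage} reads. CA/CC/CT are dinucleotide classes
#' pooled over non-CG contexts; CAG is the CHG subclass whose next base is
#' A; TACAG the 5-mer subclass (classes overlap, by design). The default is
#' the unweighted mean of per-site levels; \code{pooled = TRUE} instead
#' divides summed methylated counts by summed totals.
#'
#' @param methylome A \code{\linkS4class{Methylome}}.
#' @param minCoverage Minimum informative reads per site (default 4).
#' @param pooled Use read-pooled instead of site-averaged means.
#' @return \code{data.frame} with columns \code{label}, \code{level}
#'   (fraction in [0,1], \code{NA} when no qualifying site) and
#'   \code{n_sites}.
#' @export
globalLevels <- function(methylome, minCoverage = 4L, pooled = FALSE) {
    stopifnot(length(methylome) > 0L)
    df <- methTable(methylome)
    df <- df[df$total >= minCoverage, , drop = FALSE]
    lev <- df$meth / df$total
    nonCg <- df$context3 %in% c("CHG", "CHH")
    sel <- list(
        CG = df$context3 == "CG",
        CHG = df$context3 == "CHG",
        CHH = df$context3 == "CHH",
        CA = nonCg & df$dinuc == "CA",
        CT = nonCg & df$dinuc == "CT",
        CC = nonCg & df$dinuc == "CC",
        CAG = df$context3 == "CHG" & df$dinuc == "CA",
        TACAG = df$is_tacag
    )
    level <- vapply(sel, function(s) {
        if (!any(s)) return(NA_real_)
        if (pooled) sum(df$meth[s]) / sum(df$total[s]) else mean(lev[s])
    }, numeric(1))
    data.frame(label = .GLOBAL_LABELS,
               level = unname(level[.GLOBAL_LABELS]),
               n_sites = unname(vapply(sel[.GLOBAL_LABELS], sum,
                                       integer(1))),
               min_coverage = minCoverage)
}
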
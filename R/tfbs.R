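## Methylation-sensitivity screen for transcription-factor binding sites:
## correlate between-line methylation changes at binding sites with
## expression changes of their target genes, against +/-500 bp neighbor
## controls.

#' Mean methylation level within binding-site intervals
#'
#' Unweighted mean of per-cytosine levels (coverage >= \code{minCoverage},
#' context-filtered) inside each interval; \code{NA} when no covered
#' cytosine overlaps.
#'
#' @param methylome A \code{\linkS4class{Methylome}}.
#' @param tfbs \code{GRanges} of binding sites.
#' @param minCoverage Minimum reads per cytosine (default 4).
#' @param context Cytosine context used (default \code{"CG"}).
#' @return Numeric vector parallel to \code{tfbs}.
#' @export
siteMethylation <- function(methylome, tfbs, minCoverage = 4L,
                            context = "CG") {
    mt <- methTable(methylome)
    mt <- mt[mt$total >= minCoverage & mt$context3 == context, ,
             drop = FALSE]
    sgr <- GRanges(mt$chrom, IRanges(mt$pos, width = 1L))
    hits <- findOverlaps(sgr, granges(tfbs), ignore.strand = TRUE)
    lev <- (mt$meth / mt$total)[queryHits(hits)]
    out <- rep(NA_real_, length(tfbs))
    if (length(hits)) {
        agg <- rowsum(lev, subjectHits(hits))
        n <- tabulate(subjectHits(hits), nbins = length(tfbs))
        idx <- as.integer(rownames(agg))
        out[idx] <- agg[, 1] / n[idx]
    }
    out
}

#' @rdname siteMethylation
#' @param span Neighbor half-width in bp (default 500); the neighbor mean
#'   covers \code{span} bp on each side of the site, excluding the site
#'   itself.
#' @export
neighborMethylation <- function(methylome, tfbs, span = 500L,
                                minCoverage = 4L, context = "CG") {
    left <- GRanges(seqnames(tfbs),
                    IRanges(pmax(start(tfbs) - span, 1L),
                            pmax(start(tfbs) - 1L, 1L)))
    right <- GRanges(seqnames(tfbs),
                     IRanges(end(tfbs) + 1L, end(tfbs) + span))
    mt <- methTable(methylome)
    mt <- mt[mt$total >= minCoverage & mt$context3 == context, ,
             drop = FALSE]
    sgr <- GRanges(mt$chrom, IRanges(mt$pos, width = 1L))
    lev <- mt$meth / mt$total
    tallies <- function(flank) {
        hits <- findOverlaps(sgr, flank, ignore.strand = TRUE)
        s <- rep(0, length(tfbs)); n <- rep(0L, length(tfbs))
        if (length(hits)) {
            agg <- rowsum(lev[queryHits(hits)], subjectHits(hits))
            idx <- as.integer(rownames(agg))
            s[idx] <- agg[, 1]
            n <- tabulate(subjectHits(hits), nbins = length(tfbs))
        }
        list(s = s, n = n)
    }
    a <- tallies(left); b <- tallies(right)
    n <- a$n + b$n
    ifelse(n > 0L, (a$s + b$s) / n, NA_real_)
}

#' Screen motifs for methylation-sensitive binding sites
#'
#' For one pair of cell lines, computes per site the methylation change
#' (line B minus line A site mean) and the log2 expression change of the
#' site's assigned gene, keeps sites where differential methylation was
#' observed (|delta meth| >= \code{minAbsDelta} and both expression values
#' present), and per motif reports the Pearson correlation (and P-value)
#' of methylation change versus expression change, the same for the
#' +/-\code{span} bp neighbor methylation, the filter status (at least
#' \code{minSites} sites and site P < \code{alpha}) and the
#' methylation-sensitivity call (passes filters and |r_site| >
#' |r_neighbor|).
#'
#' @param methylomeA,methylomeB \code{\linkS4class{Methylome}}s of the two
#'   lines.
#' @param expr Expression matrix (genes x lines; see
#'   \code{\link{readExpressionTable}}).
#' @param lineA,lineB Column names in \code{expr}.
#' @param tfbs \code{GRanges} with metadata \code{name}
#'   ("motifID:TFname") and \code{gene}.
#' @param minSites Minimum kept sites per motif (default 10).
#' @param minAbsDelta Minimum |methylation change| for a site to count as
#'   differentially methylated (default 0.1).
#' @param alpha Site-correlation P-value cutoff (default 0.05).
#' @param span Neighbor half-width (default 500).
#' @param minCoverage,context Passed to \code{\link{siteMethylation}}.
#' @param logExpr Correlate log2(expr + 1) differences (default) instead
#'   of raw differences.
#' @return \code{data.frame}, one row per motif: motif_id, tf_name,
#'   n_sites, r_site, p_site, r_neighbor, p_neighbor, passes_filters,
#'   methylation_sensitive.
#' @export
motifCorrelation <- function(methylomeA, methylomeB, expr, lineA, lineB,
                             tfbs, minSites = 10L, minAbsDelta = 0.1,
                             alpha = 0.05, span = 500L, minCoverage = 4L,
                             context = "CG", logExpr = TRUE) {
    stopifnot(all(c(lineA, lineB) %in% colnames(expr)))
    nm <- mcols(tfbs)$name
    if (is.null(nm) || any(!grepl(":", nm)))
        .stopf("TFBS names must parse as motifID:TFname")
    motif <- sub(":.*$", "", nm)
    tf <- sub("^[^:]*:", "", nm)
    gene <- mcols(tfbs)$gene
    if (is.null(gene)) .stopf("TFBS require an assigned gene")
    mA <- siteMethylation(methylomeA, tfbs, minCoverage, context)
    mB <- siteMethylation(methylomeB, tfbs, minCoverage, context)
    nA <- neighborMethylation(methylomeA, tfbs, span, minCoverage, context)
    nB <- neighborMethylation(methylomeB, tfbs, span, minCoverage, context)
    gi <- match(gene, rownames(expr))
    eA <- expr[gi, lineA]; eB <- expr[gi, lineB]
    de <- if (logExpr) log2(eB + 1) - log2(eA + 1) else eB - eA
    dm <- mB - mA
    dn <- nB - nA
    keep <- !is.na(dm) & !is.na(de) & abs(dm) >= minAbsDelta
    safeCor <- function(x, y) {
        ok <- is.finite(x) & is.finite(y)
        if (sum(ok) < 3L || sd(x[ok]) == 0 || sd(y[ok]) == 0)
            return(c(NA_real_, NA_real_))
        ct <- cor.test(x[ok], y[ok], method = "pearson")
        c(unname(ct$estimate), ct$p.value)
    }
    out <- lapply(unique(motif), function(mid) {
        sel <- keep & motif == mid
        site <- safeCor(dm[sel], de[sel])
        nb <- safeCor(dn[sel], de[sel])
        n <- sum(sel)
        passes <- !is.na(site[2]) && n >= minSites && site[2] < alpha
        data.frame(motif_id = mid, tf_name = tf[match(mid, motif)],
                   n_sites = n, r_site = site[1], p_site = site[2],
                   r_neighbor = nb[1], p_neighbor = nb[2],
                   passes_filters = passes,
                   methylation_sensitive = passes && !is.na(nb[1]) &&
                       abs(site[1]) > abs(nb[1]))
    })
    do.call(rbind, out)
}
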
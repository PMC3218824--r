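## Window-based differential methylation between cell-line pairs,
## conserved-DMR overlap across the three pairs, permutation FDR, and
## genomic-feature enrichment.

#' Mean methylation in tiling windows
#'
#' Tiles every chromosome with fixed-width windows and reports the
#' unweighted mean of qualifying per-site levels per window. Windows with
#' fewer than \code{minSites} qualifying sites get \code{NA}.
#'
#' @param methylome A \code{\linkS4class{Methylome}}.
#' @param chromLengths Named integer vector of chromosome lengths (or a
#'   \code{DNAStringSet}).
#' @param windowSize Window width in bp (default 1000).
#' @param minSites Minimum covered sites per window (default 5).
#' @param minCoverage Minimum reads per site (default 4).
#' @param context \code{"CG"} or \code{"CHG"}.
#' @return \code{data.frame}: chrom, start0 (0-based), mean (level or
#'   \code{NA}), n_sites. Windows tile each chromosome completely.
#' @export
windowMethylation <- function(methylome, chromLengths, windowSize = 1000L,
                              minSites = 5L, minCoverage = 4L,
                              context = c("CG", "CHG")) {
    context <- match.arg(context)
    if (is(chromLengths, "DNAStringSet"))
        chromLengths <- .chromLengths(chromLengths)
    mt <- methTable(methylome)
    mt <- mt[mt$total >= minCoverage & mt$context3 == context, ,
             drop = FALSE]
    parts <- lapply(names(chromLengths), function(cn) {
        nwin <- ceiling(chromLengths[[cn]] / windowSize)
        sub <- mt[mt$chrom == cn, , drop = FALSE]
        widx <- (sub$pos - 1L) %/% windowSize + 1L
        lev <- sub$meth / sub$total
        n <- tabulate(widx, nbins = nwin)
        s <- rep(0, nwin)
        if (nrow(sub)) {
            agg <- rowsum(lev, widx)
            s[as.integer(rownames(agg))] <- agg[, 1]
        }
        mean <- ifelse(n >= minSites, s / pmax(n, 1L), NA_real_)
        data.frame(chrom = cn, start0 = (seq_len(nwin) - 1L) * windowSize,
                   mean = mean, n_sites = n)
    })
    do.call(rbind, parts)
}

#' Call differentially methylated windows between two lines
#'
#' For every window with a defined mean in both lines, the ratio
#' r = (higher mean + epsilon) / (lower mean + epsilon) is computed and
#' standardized over all such windows; windows with Z above \code{zCut}
#' (default 2) are flagged as differentially methylated.
#'
#' @param windowsA,windowsB Window tables from
#'   \code{\link{windowMethylation}} over the same tiling.
#' @param zCut Z-score threshold (default 2).
#' @param epsilon Pseudocount guarding against division by zero
#'   (default 0.01).
#' @param logRatio Standardize log(r) instead of r.
#' @return \code{data.frame}: chrom, start0, meanA, meanB, ratio,
#'   direction ("A" or "B", the more methylated line), z, is_dmr.
#' @export
callDmrs <- function(windowsA, windowsB, zCut = 2, epsilon = 0.01,
                     logRatio = FALSE) {
    keyA <- paste(windowsA$chrom, windowsA$start0)
    keyB <- paste(windowsB$chrom, windowsB$start0)
    if (!identical(keyA, keyB))
        .stopf("window tables are not on the same tiling")
    keep <- !is.na(windowsA$mean) & !is.na(windowsB$mean)
    if (sum(keep) < 30L)
        .stopf("need at least 30 jointly non-missing windows (got %d)",
               sum(keep))
    a <- windowsA$mean[keep]; b <- windowsB$mean[keep]
    r <- (pmax(a, b) + epsilon) / (pmin(a, b) + epsilon)
    x <- if (logRatio) log(r) else r
    s <- sd(x)
    if (s == 0) .stopf("degenerate ratio distribution (sd = 0)")
    z <- (x - mean(x)) / s
    data.frame(chrom = windowsA$chrom[keep],
               start0 = windowsA$start0[keep],
               meanA = a, meanB = b, ratio = r,
               direction = ifelse(a >= b, "A", "B"),
               z = z, is_dmr = z > zCut)
}

#' Conserved differentially methylated windows
#'
#' Windows flagged as DMRs in all three pairwise comparisons.
#'
#' @param dmrsAB,dmrsAC,dmrsBC Tables from \code{\link{callDmrs}} for the
#'   three pairs of lines.
#' @return List: \code{windows} (data.frame chrom/start0),
#'   \code{fraction} (conserved windows over windows tested in all three
#'   comparisons), \code{n_tested}.
#' @export
conservedDmrs <- function(dmrsAB, dmrsAC, dmrsBC) {
    key <- function(d) paste(d$chrom, d$start0)
    tested <- intersect(intersect(key(dmrsAB), key(dmrsAC)), key(dmrsBC))
    flag <- function(d) key(d)[d$is_dmr]
    cons <- intersect(intersect(flag(dmrsAB), flag(dmrsAC)), flag(dmrsBC))
    i <- match(cons, key(dmrsAB))
    list(windows = data.frame(chrom = dmrsAB$chrom[i],
                              start0 = dmrsAB$start0[i]),
         fraction = if (length(tested)) length(cons) / length(tested)
                    else NA_real_,
         n_tested = length(tested))
}

## full conserved-DMR pipeline on three window tables
.conservedFraction <- function(w1, w2, w3, zCut, epsilon) {
    d12 <- callDmrs(w1, w2, zCut, epsilon)
    d13 <- callDmrs(w1, w3, zCut, epsilon)
    d23 <- callDmrs(w2, w3, zCut, epsilon)
    conservedDmrs(d12, d13, d23)
}

#' Permutation FDR for the conserved-DMR fraction
#'
#' Each permutation independently shuffles each line's vector of window
#' means (over its non-missing windows), re-runs the pairwise DMR calls and
#' their three-way overlap, and records the conserved fraction. The FDR
#' estimate is the mean null fraction divided by the observed fraction.
#'
#' @param windows1,windows2,windows3 Window tables for the three lines
#'   (same tiling).
#' @param nPerm Number of permutations (default 300).
#' @param seed Integer seed for the permutation stream.
#' @param zCut,epsilon Passed to \code{\link{callDmrs}}.
#' @return List: observed (fraction), null_mean, null_sd, fdr (\code{NA}
#'   when the observed fraction is 0), null_fractions.
#' @export
permutationFdr <- function(windows1, windows2, windows3, nPerm = 300L,
                           seed = 1L, zCut = 2, epsilon = 0.01) {
    if (nPerm < 1L) .stopf("nPerm must be >= 1")
    obs <- .conservedFraction(windows1, windows2, windows3, zCut, epsilon)
    set.seed(seed)
    shuffle <- function(w) {
        i <- which(!is.na(w$mean))
        w$mean[i] <- w$mean[sample(i)]
        w
    }
    nullFrac <- vapply(seq_len(nPerm), function(p) {
        s1 <- shuffle(windows1); s2 <- shuffle(windows2)
        s3 <- shuffle(windows3)
        ## the permutation must preserve each line's multiset of means
        stopifnot(identical(sort(s1$mean[!is.na(s1$mean)]),
                            sort(windows1$mean[!is.na(windows1$mean)])))
        .conservedFraction(s1, s2, s3, zCut, epsilon)$fraction
    }, numeric(1))
    list(observed = obs$fraction,
         null_mean = mean(nullFrac),
         null_sd = sd(nullFrac),
         fdr = if (!is.na(obs$fraction) && obs$fraction > 0)
             mean(nullFrac) / obs$fraction else NA_real_,
         null_fractions = nullFrac)
}

#' Genomic-feature enrichment of a region set
#'
#' Fold enrichment of region coverage in each annotated feature class:
#' (fraction of region bases inside the feature) / (fraction of genome
#' bases inside the feature). CpG-island shores are derived as the 2-kb
#' flanks of islands, excluding the islands themselves.
#'
#' @param regions \code{GRanges} of regions (e.g. conserved DMR windows).
#' @param annotations Named list of \code{GRanges}: any of
#'   \code{promoters}, \code{exons}, \code{introns}, \code{cpg_islands};
#'   missing features yield \code{NA}.
#' @param chromLengths Named lengths vector or \code{DNAStringSet}.
#' @return \code{data.frame}: feature, fold, region_fraction,
#'   genome_fraction.
#' @export
featureEnrichment <- function(regions, annotations, chromLengths) {
    if (length(regions) == 0L) .stopf("empty region set")
    if (is(chromLengths, "DNAStringSet"))
        chromLengths <- .chromLengths(chromLengths)
    gsize <- sum(as.numeric(chromLengths))
    regions <- reduce(regions, ignore.strand = TRUE)
    rsize <- sum(width(regions))
    feats <- annotations[intersect(c("promoters", "exons", "introns",
                                     "cpg_islands"),
                                   names(annotations))]
    if (!is.null(annotations$cpg_islands)) {
        isl <- reduce(annotations$cpg_islands, ignore.strand = TRUE)
        sh <- reduce(c(GRanges(seqnames(isl),
                               IRanges(pmax(start(isl) - 2000L, 1L),
                                       pmax(start(isl) - 1L, 1L))),
                       GRanges(seqnames(isl),
                               IRanges(end(isl) + 1L, end(isl) + 2000L))),
                     ignore.strand = TRUE)
        feats$cpg_shores <- GenomicRanges::setdiff(sh, isl,
                                                   ignore.strand = TRUE)
    }
    out <- lapply(names(feats), function(fn) {
        f <- reduce(feats[[fn]], ignore.strand = TRUE)
        fsize <- sum(width(f))
        inter <- sum(width(GenomicRanges::intersect(regions, f,
                                                    ignore.strand = TRUE)))
        rf <- inter / rsize
        gf <- fsize / gsize
        data.frame(feature = fn, fold = if (gf > 0) rf / gf else NA_real_,
                   region_fraction = rf, genome_fraction = gf)
    })
    do.call(rbind, out)
}

#' Correlate island methylation change with expression change
#'
#' Pearson correlation between per-gene CpG-island methylation differences
#' and log2 expression differences.
#'
#' @param deltaMeth Per-gene island methylation change (fraction).
#' @param deltaExpr Per-gene log2 expression change.
#' @return List: r, p_value, n.
#' @export
islandExpressionCorrelation <- function(deltaMeth, deltaExpr) {
    keep <- is.finite(deltaMeth) & is.finite(deltaExpr)
    if (sum(keep) < 3L) .stopf("need at least 3 genes (got %d)", sum(keep))
    ct <- cor.test(deltaMeth[keep], deltaExpr[keep], method = "pearson")
    list(r = unname(ct$estimate), p_value = ct$p.value, n = sum(keep))
}
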
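#' @import methods
#' @importFrom stats cor.test dbinom p.adjust pbinom phyper rbeta rbinom
#'   rnorm rpois runif sd setNames complete.cases
#' @importFrom utils read.table write.table head
#' @importFrom S4Vectors mcols mcols<- DataFrame queryHits subjectHits
#' @importFrom IRanges IRanges findOverlaps overlapsAny
#' @importFrom GenomicRanges GRanges granges seqnames start end width strand
#'   strand<- reduce intersect setdiff
#' @importFrom Biostrings DNAStringSet readDNAStringSet writeXStringSet
NULL

## Context labels used throughout; H = A, C or T.
.CONTEXT3 <- c("CG", "CHG", "CHH")
.DINUC <- c("CG", "CA", "CC", "CT")

#' Per-cytosine methylome
#'
#' A \code{Methylome} holds strand-aware per-cytosine methylation calls:
#' for every covered genomic cytosine (on either strand) the number of
#' methylated reads (\code{meth}, reads showing C) and the number of
#' informative reads (\code{total}, reads showing C or T), together with its
#' sequence context. Context is classified from the two bases downstream of
#' the cytosine on its own strand: CG if the next base is G, CHG if the base
#' after that is G, otherwise CHH. \code{dinuc} is the cytosine plus its next
#' base (CG/CA/CC/CT) and \code{is_tacag} flags cytosines whose strand-local
#' 5-mer (positions -2..+2) reads TACAG.
#'
#' Positions are 1-based; the underlying \code{GRanges} has width-1 ranges.
#'
#' @slot sites A \code{GRanges} with metadata columns \code{context3},
#'   \code{dinuc}, \code{is_tacag}, \code{meth}, \code{total}.
#' @export
setClass("Methylome", representation(sites = "GRanges"))

setValidity("Methylome", function(object) {
    gr <- object@sites
    mc <- mcols(gr)
    need <- c("context3", "dinuc", "is_tacag", "meth", "total")
    if (!all(need %in% colnames(mc)))
        return(paste("missing metadata columns:",
                     paste(setdiff(need, colnames(mc)), collapse = ", ")))
    if (length(gr) == 0L) return(TRUE)
    if (any(width(gr) != 1L)) return("all sites must have width 1")
    if (!all(as.character(strand(gr)) %in% c("+", "-")))
        return("strand must be + or -")
    if (!all(mc$context3 %in% .CONTEXT3)) return("invalid context3")
    if (!all(mc$dinuc %in% .DINUC)) return("invalid dinuc")
    if (any(mc$meth < 0L) || any(mc$total < 0L))
        return("counts must be non-negative")
    if (any(mc$meth > mc$total)) return("meth exceeds total")
    TRUE
})

#' Construct a Methylome from per-site vectors
#'
#' @param chrom Character vector of chromosome names.
#' @param pos Integer vector of 1-based cytosine positions.
#' @param strand Character vector, \code{"+"} or \code{"-"} (the strand the
#'   cytosine lies on).
#' @param context3 \code{"CG"}, \code{"CHG"} or \code{"CHH"}.
#' @param dinuc Dinucleotide class (\code{"CG"}, \code{"CA"}, \code{"CC"},
#'   \code{"CT"}).
#' @param is_tacag Logical: is the site the central C of a TACAG 5-mer.
#' @param meth,total Methylated and informative read counts.
#' @return A \code{\linkS4class{Methylome}}, sorted by (chrom, pos, strand).
#' @export
Methylome <- function(chrom, pos, strand, context3, dinuc, is_tacag,
                      meth, total) {
    gr <- GRanges(chrom, IRanges(as.integer(pos), width = 1L),
                  strand = strand)
    mcols(gr) <- DataFrame(context3 = as.character(context3),
                           dinuc = as.character(dinuc),
                           is_tacag = as.logical(is_tacag),
                           meth = as.integer(meth),
                           total = as.integer(total))
    ord <- order(as.character(seqnames(gr)), start(gr),
                 as.character(strand(gr)))
    new("Methylome", sites = gr[ord])
}

#' @describeIn Methylome Number of cytosine sites.
#' @param x A \code{Methylome}.
#' @export
setMethod("length", "Methylome", function(x) length(x@sites))

#' Accessors for Methylome objects
#'
#' \code{methSites} returns the underlying \code{GRanges};
#' \code{methLevel} the per-site methylation level (meth/total, \code{NaN}
#' where total is 0); \code{methTable} a plain \code{data.frame} view.
#'
#' @param x A \code{\linkS4class{Methylome}}.
#' @return See description.
#' @export
methSites <- function(x) x@sites

#' @rdname methSites
#' @export
methLevel <- function(x) {
    mc <- mcols(x@sites)
    mc$meth / mc$total
}

#' @rdname methSites
#' @export
methTable <- function(x) {
    gr <- x@sites
    mc <- mcols(gr)
    data.frame(chrom = as.character(seqnames(gr)),
               pos = start(gr),
               strand = as.character(strand(gr)),
               context3 = mc$context3,
               dinuc = mc$dinuc,
               is_tacag = mc$is_tacag,
               meth = mc$meth,
               total = mc$total,
               stringsAsFactors = FALSE)
}

setMethod("show", "Methylome", function(object) {
    n <- length(object)
    cat("Methylome with", n, "cytosine sites\n")
    if (n > 0L) {
        ctx <- table(mcols(object@sites)$context3)
        cat("  contexts:",
            paste(names(ctx), as.integer(ctx), sep = "=", collapse = " "),
            "\n")
        lv <- methLevel(object)
        cat(sprintf("  mean level (covered sites): %.4f\n",
                    mean(lv[is.finite(lv)])))
    }
})

#' Observed/expected contingency summary
#'
#' Holds the observed count matrix of a two-factor classification (e.g.
#' methylation bin in line A x bin in line B, or methylation status of the
#' two strands of a CG dyad), the expected matrix under independence of the
#' two factors (row total x column total / grand total), and the fold
#' enrichment observed/expected.
#'
#' @slot observed,expected,fold Numeric matrices with identical dimnames.
#' @slot n Grand total.
#' @export
setClass("ContingencySummary",
         representation(observed = "matrix", expected = "matrix",
                        fold = "matrix", n = "numeric"))

setValidity("ContingencySummary", function(object) {
    if (!identical(dim(object@observed), dim(object@expected)))
        return("observed/expected dimension mismatch")
    if (abs(sum(object@observed) - object@n) > 1e-8)
        return("observed counts do not sum to n")
    if (abs(sum(object@expected) - object@n) > 1e-6)
        return("expected counts do not sum to n")
    if (any(object@fold < 0, na.rm = TRUE)) return("negative fold")
    TRUE
})

.contingency <- function(observed) {
    n <- sum(observed)
    expected <- outer(rowSums(observed), colSums(observed)) / n
    fold <- observed / expected
    fold[expected == 0] <- NA_real_
    new("ContingencySummary", observed = observed, expected = expected,
        fold = fold, n = n)
}

#' @describeIn ContingencySummary Fraction of concordant (diagonal)
#'   observations -- the conserved fraction for conservation tables and the
#'   symmetric fraction for dyad tables.
#' @param x A \code{ContingencySummary}.
#' @export
concordantFraction <- function(x) sum(diag(x@observed)) / x@n

#' @rdname ContingencySummary
#' @param object A \code{ContingencySummary}.
#' @export
setMethod("show", "ContingencySummary", function(object) {
    cat("ContingencySummary (n =", object@n, ")\n")
    cat("observed:\n"); print(object@observed)
    cat("fold (observed/expected):\n"); print(round(object@fold, 3))
    cat(sprintf("concordant fraction: %.4f\n", concordantFraction(object)))
})

#' Position frequency matrix of site flanks
#'
#' Base counts at each offset of a window centred on a set of cytosine
#' sites, strand-oriented (minus-strand flanks are reverse-complemented so
#' the site C is always at offset 0).
#'
#' @slot counts 4 x (2k+1) matrix, rows A/C/G/T, columns offsets -k..+k.
#' @slot nSites Sites contributing; \code{nDropped} sites lost to chromosome
#'   edges.
#' @slot nDropped Integer.
#' @export
setClass("PositionFrequencyMatrix",
         representation(counts = "matrix", nSites = "integer",
                        nDropped = "integer"))

setValidity("PositionFrequencyMatrix", function(object) {
    if (!identical(rownames(object@counts), c("A", "C", "G", "T")))
        return("rows must be A, C, G, T")
    if (any(object@counts < 0)) return("negative counts")
    if (any(colSums(object@counts) > object@nSites))
        return("column sums cannot exceed nSites")
    TRUE
})

#' @describeIn PositionFrequencyMatrix Majority base at each offset.
#' @param x A \code{PositionFrequencyMatrix}.
#' @export
pfmConsensus <- function(x) {
    apply(x@counts, 2L, function(col) rownames(x@counts)[which.max(col)])
}

setMethod("show", "PositionFrequencyMatrix", function(object) {
    cat("PositionFrequencyMatrix over", object@nSites, "sites (",
        object@nDropped, "dropped at edges )\n")
    print(object@counts)
    cat("consensus:", paste(pfmConsensus(object), collapse = ""), "\n")
})
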
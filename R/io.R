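#' Read a reference genome from FASTA
#'
#' Sequences are uppercased and validated: the alphabet must be within
#' A/C/G/T/N, record names must be unique and every record non-empty.
#'
#' @param path Path to a (multi-)FASTA file.
#' @return A \code{\link[Biostrings]{DNAStringSet}} named by chromosome.
#' @export
readFastaGenome <- function(path) {
    if (!file.exists(path)) .stopf("FASTA file not found: %s", path)
    seqs <- readDNAStringSet(path)
    nm <- sub("\\s.*$", "", names(seqs))
    if (anyDuplicated(nm))
        .stopf("duplicate chromosome name in %s: %s", path,
               nm[duplicated(nm)][1])
    if (any(width(seqs) == 0L))
        .stopf("empty FASTA record in %s: %s", path, nm[width(seqs) == 0L][1])
    seqs <- DNAStringSet(toupper(as.character(seqs)))
    names(seqs) <- nm
    bad <- setdiff(unique(unlist(strsplit(as.character(seqs), "",
                                          fixed = TRUE))),
                   c("A", "C", "G", "T", "N"))
    if (length(bad))
        .stopf("genome alphabet outside A/C/G/T/N: %s",
               paste(bad, collapse = ","))
    seqs
}

#' Write a genome to FASTA
#' @param genome A \code{DNAStringSet}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeFastaGenome <- function(genome, path) {
    writeXStringSet(genome, path, width = 70L)
    invisible(path)
}

.METH_COLS <- c("chrom", "pos", "strand", "context3", "dinuc",
                "meth", "total", "is_tacag")

#' Read / write a methylome TSV
#'
#' The dialect has 8 tab-separated columns (no header): chrom, 1-based
#' position, strand, context3 (CG/CHG/CHH), dinucleotide (CG/CA/CC/CT),
#' methylated count, total count, is_tacag (0/1). Reading a written table
#' reproduces it exactly; rows are stored sorted by (chrom, pos, strand).
#'
#' @param path File path.
#' @return \code{readMethylome}: a \code{\linkS4class{Methylome}}.
#' @export
readMethylome <- function(path) {
    if (!file.exists(path)) .stopf("methylome TSV not found: %s", path)
    df <- read.table(path, sep = "\t", header = FALSE,
                     col.names = .METH_COLS,
                     colClasses = c("character", "integer", "character",
                                    "character", "character", "integer",
                                    "integer", "integer"),
                     quote = "", comment.char = "#")
    bad <- which(df$meth > df$total)
    if (length(bad))
        .stopf("meth_count > total_count at %s line %d", path, bad[1])
    Methylome(df$chrom, df$pos, df$strand, df$context3, df$dinuc,
              df$is_tacag == 1L, df$meth, df$total)
}

#' @rdname readMethylome
#' @param methylome A \code{Methylome}.
#' @return \code{writeMethylome}: invisibly, \code{path}.
#' @export
writeMethylome <- function(methylome, path) {
    df <- methTable(methylome)
    df$is_tacag <- as.integer(df$is_tacag)
    write.table(df[, .METH_COLS], path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    invisible(path)
}

.BSREAD_COLS <- c("read_id", "chrom", "start0", "strand", "bs_strand", "seq")

#' Read / write aligned bisulfite reads
#'
#' Reads are ungapped post-alignment records: 6 tab-separated columns
#' (no header): read_id, chrom, 0-based start, alignment strand (+/-),
#' bisulfite strand (W = Watson-derived fragment, reporting on plus-strand
#' cytosines; C = Crick-derived, reporting on minus-strand cytosines), and
#' the read sequence in aligned (plus-strand) orientation. Row order is
#' preserved on round-trip.
#'
#' @param path File path.
#' @param genome Optional \code{DNAStringSet}; when supplied, reads beyond
#'   chromosome bounds raise an error.
#' @return \code{readBsReads}: a \code{data.frame} with the six columns.
#' @export
readBsReads <- function(path, genome = NULL) {
    if (!file.exists(path)) .stopf("read TSV not found: %s", path)
    df <- read.table(path, sep = "\t", header = FALSE,
                     col.names = .BSREAD_COLS,
                     colClasses = c("character", "character", "integer",
                                    "character", "character", "character"),
                     quote = "", comment.char = "#")
    validateBsReads(df, genome)
    df
}

#' @rdname readBsReads
#' @param reads A read \code{data.frame} as returned by \code{readBsReads}.
#' @export
writeBsReads <- function(reads, path) {
    write.table(reads[, .BSREAD_COLS], path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' @rdname readBsReads
#' @export
validateBsReads <- function(reads, genome = NULL) {
    stopifnot(all(.BSREAD_COLS %in% names(reads)))
    if (!all(reads$bs_strand %in% c("W", "C")))
        .stopf("bs_strand must be W or C")
    if (!all(reads$strand %in% c("+", "-")))
        .stopf("read strand must be + or -")
    if (!is.null(genome)) {
        lens <- .chromLengths(genome)
        if (!all(reads$chrom %in% names(lens)))
            .stopf("read chromosome absent from genome: %s",
                   setdiff(reads$chrom, names(lens))[1])
        over <- reads$start0 + nchar(reads$seq) > lens[reads$chrom] |
            reads$start0 < 0L
        if (any(over))
            .stopf("read %s exceeds bounds of %s",
                   reads$read_id[over][1], reads$chrom[over][1])
    }
    invisible(reads)
}

#' Read a BED track
#'
#' Minimal strict BED reader returning 0-based half-open intervals as a
#' \code{GRanges}. \code{kind = "bed12"} additionally parses exon blocks
#' into a \code{blocks} metadata column (a \code{GRangesList}-free list of
#' genomic 0-based half-open \code{(start, end)} matrices) after checking
#' block count/size/offset consistency.
#'
#' @param path File path.
#' @param kind \code{"bed3"}, \code{"bed6"} or \code{"bed12"}.
#' @return A \code{GRanges} (1-based internally, as usual for
#'   \code{GRanges}); metadata columns \code{name}, \code{score} for BED6+,
#'   plus \code{blocks} for BED12.
#' @export
readBedTrack <- function(path, kind = c("bed6", "bed3", "bed12")) {
    kind <- match.arg(kind)
    if (!file.exists(path)) .stopf("BED file not found: %s", path)
    df <- read.table(path, sep = "\t", header = FALSE, quote = "",
                     comment.char = "#", stringsAsFactors = FALSE)
    ncol.need <- c(bed3 = 3L, bed6 = 4L, bed12 = 12L)[[kind]]
    if (ncol(df) < ncol.need)
        .stopf("%s has %d columns; %s needs at least %d", path, ncol(df),
               kind, ncol.need)
    start0 <- as.integer(df[[2]]); end0 <- as.integer(df[[3]])
    bad <- which(end0 <= start0)
    if (length(bad))
        .stopf("BED interval with end <= start at %s line %d", path, bad[1])
    gr <- GRanges(df[[1]], IRanges(start0 + 1L, end0))
    if (kind != "bed3") {
        mcols(gr)$name <- as.character(df[[4]])
        mcols(gr)$score <- if (ncol(df) >= 5L) df[[5]] else NA
        if (ncol(df) >= 6L) strand(gr) <- df[[6]]
    }
    if (kind == "bed12") {
        nblocks <- as.integer(df[[10]])
        blocks <- vector("list", nrow(df))
        for (i in seq_len(nrow(df))) {
            sizes <- as.integer(strsplit(df[[11]][i], ",")[[1]])
            offs <- as.integer(strsplit(df[[12]][i], ",")[[1]])
            if (length(sizes) != nblocks[i] || length(offs) != nblocks[i])
                .stopf("BED12 block count mismatch at %s line %d", path, i)
            bs <- start0[i] + offs
            be <- bs + sizes
            if (any(be > end0[i]) || any(sizes <= 0L) ||
                offs[1] != 0L || bs[nblocks[i]] + sizes[nblocks[i]] != end0[i])
                .stopf("BED12 blockSizes/blockStarts inconsistent at %s line %d",
                       path, i)
            blocks[[i]] <- cbind(start = bs, end = be)
        }
        mcols(gr)$blocks <- blocks
        ## extra columns beyond 12: keep as gene assignment if present
        if (ncol(df) >= 13L) mcols(gr)$gene <- as.character(df[[13]])
    } else if (kind == "bed6" && ncol(df) >= 7L) {
        mcols(gr)$gene <- as.character(df[[7]])
    }
    gr
}

#' Write intervals as BED
#'
#' @param gr A \code{GRanges}; BED6 columns written when \code{name}
#'   metadata is present (plus an extra \code{gene} column if present).
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeBedTrack <- function(gr, path) {
    df <- data.frame(chrom = as.character(seqnames(gr)),
                     start = start(gr) - 1L, end = end(gr))
    if (!is.null(mcols(gr)$name)) {
        df$name <- mcols(gr)$name
        df$score <- if (is.null(mcols(gr)$score)) 0 else mcols(gr)$score
        df$strand <- as.character(strand(gr))
        if (!is.null(mcols(gr)$gene)) df$gene <- mcols(gr)$gene
    }
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
    invisible(path)
}

#' Write gene models as BED12
#' @param genes A \code{GRanges} with \code{name} and \code{blocks} metadata
#'   (as produced by \code{\link{readBedTrack}} or the simulator).
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeBed12 <- function(genes, path) {
    lines <- vapply(seq_along(genes), function(i) {
        b <- mcols(genes)$blocks[[i]]
        s0 <- start(genes)[i] - 1L
        paste(as.character(seqnames(genes))[i], s0, end(genes)[i],
              mcols(genes)$name[i], 0, as.character(strand(genes))[i],
              s0, end(genes)[i], "0", nrow(b),
              paste0(paste(b[, "end"] - b[, "start"], collapse = ","), ","),
              paste0(paste(b[, "start"] - s0, collapse = ","), ","),
              sep = "\t")
    }, character(1))
    writeLines(lines, path)
    invisible(path)
}

#' Read a gene-by-cell-line expression table
#'
#' Header row names the cell lines; first column \code{gene_id}. Values
#' must be non-negative reals.
#'
#' @param path File path.
#' @return A numeric matrix, rows = genes, columns = cell lines.
#' @export
readExpressionTable <- function(path) {
    df <- read.table(path, sep = "\t", header = TRUE, quote = "",
                     check.names = FALSE, stringsAsFactors = FALSE)
    if (names(df)[1] != "gene_id") .stopf("first column must be gene_id")
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df$gene_id
    if (any(!is.finite(m)) || any(m < 0))
        .stopf("expression values must be non-negative reals")
    m
}

#' @rdname readExpressionTable
#' @param expr Numeric matrix (genes x lines).
#' @export
writeExpressionTable <- function(expr, path) {
    df <- data.frame(gene_id = rownames(expr), expr, check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read a plain-text gene list (one id per line)
#' @param path File path.
#' @return Character vector of ids.
#' @export
readGeneList <- function(path) {
    x <- trimws(readLines(path))
    x[nzchar(x)]
}
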
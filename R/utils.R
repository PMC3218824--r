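## Internal helpers shared across modules. Genome sequences are handled as
## raw byte vectors for fast per-position lookups.

.BASES <- c("A", "C", "G", "T")
.rawA <- charToRaw("A"); .rawC <- charToRaw("C")
.rawG <- charToRaw("G"); .rawT <- charToRaw("T"); .rawN <- charToRaw("N")

## named list of raw vectors, one per chromosome
.genomeRaw <- function(genome) {
    stopifnot(is(genome, "DNAStringSet"))
    lapply(setNames(as.character(genome), names(genome)), charToRaw)
}

.chromLengths <- function(genome) setNames(width(genome), names(genome))

.revcomp <- function(x) {
    vapply(x, function(s) {
        chartr("ACGTN", "TGCAN",
               paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
    }, character(1), USE.NAMES = FALSE)
}

## complement of a raw base vector
.comp <- function(b) {
    out <- b
    out[b == .rawA] <- .rawT; out[b == .rawT] <- .rawA
    out[b == .rawC] <- .rawG; out[b == .rawG] <- .rawC
    out
}

## site key for joins between per-site tables
.siteKey <- function(chrom, pos, strand) paste(chrom, pos, strand, sep = ":")

.stopf <- function(...) stop(sprintf(...), call. = FALSE)

## expand reads (data.frame with chrom,start0,seq,...) into per-base
## records: position (1-based), base (raw), plus the repeated read columns
.expandReads <- function(reads) {
    len <- nchar(reads$seq)
    idx <- rep.int(seq_len(nrow(reads)), len)
    data <- list(
        readIdx = idx,
        chrom = reads$chrom[idx],
        pos = rep.int(reads$start0, len) + sequence(len),
        base = charToRaw(paste(reads$seq, collapse = "")),
        isW = (reads$bs_strand == "W")[idx]
    )
    data
}

## maximum run length of TRUE within groups (entries assumed grouped)
.hasRunAtLeast <- function(flag, group, k) {
    if (length(flag) == 0L) return(integer(0))
    key <- group * 2 + as.integer(flag)
    r <- rle(key)
    bad <- r$lengths >= k & (r$values %% 2 == 1)
    unique((r$values[bad] - 1) %/% 2)
}
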
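## Shared fixtures: tiny hand-built genomes/reads plus a cached default
## synthetic study (simulation is deterministic, so caching is safe).

.cache <- new.env(parent = emptyenv())

cachedStudy <- function(name, config, reads = TRUE) {
    if (is.null(.cache[[name]]))
        .cache[[name]] <- simulateStudy(config, reads = reads)
    .cache[[name]]
}

## default study: error-free reads so per-read calls equal planted truth
cleanConfig <- function(...)
    simulationConfig(seed = 7L, errorRate = 0, nonConversionRate = 0, ...)

defaultStudy <- function() cachedStudy("default", cleanConfig())

readCols <- c("read_id", "chrom", "start0", "strand", "bs_strand", "seq")

tinyGenome <- function(seqs) {
    g <- Biostrings::DNAStringSet(seqs)
    names(g) <- names(seqs)
    g
}

## build a read data.frame from parallel vectors
mkReads <- function(chrom, start0, bs, seq, strand = NULL) {
    n <- length(start0)
    data.frame(read_id = sprintf("r%03d", seq_len(n)),
               chrom = rep_len(chrom, n), start0 = start0,
               strand = if (is.null(strand))
                   ifelse(rep_len(bs, n) == "W", "+", "-") else strand,
               bs_strand = rep_len(bs, n), seq = seq)
}

## random valid methylome rows for round-trip tests
randomMethylomeTable <- function(n, seed = 1L) {
    set.seed(seed)
    ctx <- sample(c("CG", "CHG", "CHH"), n, replace = TRUE)
    dinuc <- ifelse(ctx == "CG", "CG",
                    sample(c("CA", "CC", "CT"), n, replace = TRUE))
    total <- sample(0:40, n, replace = TRUE)
    meth <- vapply(total, function(t) sample(0:t, 1L), integer(1))
    Methylome(chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
              pos = sample(1e6, n),
              strand = sample(c("+", "-"), n, replace = TRUE),
              context3 = ctx, dinuc = dinuc,
              is_tacag = ctx == "CHG" & dinuc == "CA" &
                  runif(n) < 0.2,
              meth = meth, total = total)
}

## brute-force minlike two-sided binomial (independent oracle)
enumBinomTwoSided <- function(k, n, p) {
    probs <- vapply(0:n, function(i)
        choose(n, i) * p^i * (1 - p)^(n - i), numeric(1))
    sum(probs[probs <= probs[k + 1L] * (1 + 1e-7)])
}

## brute-force upper-tail hypergeometric (independent oracle)
enumHyperUpper <- function(k, K, nDraw, N) {
    kk <- k:min(nDraw, K)
    sum(vapply(kk, function(i)
        choose(K, i) * choose(N - K, nDraw - i), numeric(1))) /
        choose(N, nDraw)
}

## textbook two-pass Pearson r and t-based P (oracle for cor.test)
pearsonTwoPass <- function(x, y) {
    n <- length(x)
    r <- sum((x - mean(x)) * (y - mean(y))) /
        sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    t <- r * sqrt((n - 2) / (1 - r^2))
    list(r = r, p = 2 * pt(-abs(t), n - 2))
}
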
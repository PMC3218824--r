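## End-to-end orchestration: run the synthetic study, every analysis
## stage, and write a report directory. Each stage is also exported on
## its own; this wrapper exists for reproducible demos and the
## acceptance script.

#' Run the complete comparative-methylome pipeline on synthetic data
#'
#' Simulates a study (\code{\link{simulateStudy}}), then runs: methylation
#' calling from reads (line 1) with the non-conversion filter; global
#' context levels; three-line site-count methylomes; cross-line
#' conservation and strand-symmetry tables; splice-site CHG profile;
#' window DMR calls for the three pairs, their conserved overlap and the
#' permutation FDR; bisulfite-aware SNP calling with truth
#' precision/recall; exonic-SNP mapping, gene-level ASE tests and
#' imprinted-gene-style enrichment against the planted truth;
#' allele-specific methylation scan and phasing; and the TFBS
#' methylation-sensitivity screen. All randomness derives from
#' \code{config$seed}.
#'
#' @param config A \code{\link{simulationConfig}}.
#' @param outDir Optional directory; when given, tables are written as
#'   TSVs (genome FASTA, methylome, SNPs, ASE, ASM, DMR, motif records).
#' @param nPerm Permutations for the DMR FDR (default 300).
#' @param siteCoverage Depth for the three-line site-count methylomes
#'   (default \code{config$coverage}).
#' @return Named list with each stage's result plus \code{summary}, a
#'   one-row data.frame of headline numbers.
#' @export
runPipeline <- function(config = simulationConfig(), outDir = NULL,
                        nPerm = 300L, siteCoverage = config$coverage) {
    study <- simulateStudy(config)
    lineNames <- config$lineNames

    ## methylome from reads (line 1)
    methReads <- callMethylation(study$reads[, .BSREAD_COLS], study$genome)
    global <- globalLevels(methReads)

    ## three-line methylomes from site counts (pooled alleles)
    set.seed(config$seed + 707L)
    meths <- lapply(lineNames, function(l)
        simulateSiteCounts(study$sites, rowMeans(study$probs[[l]]),
                           siteCoverage))
    names(meths) <- lineNames

    ## conservation + symmetry
    consCg <- conservationContingency(meths[[1]], meths[[2]], "CG")
    consNonCg <- conservationContingency(meths[[1]], meths[[2]], "nonCG")
    symCg <- symmetryAnalysis(meths[[1]], study$genome, "CG")
    splice <- spliceSiteProfile(meths[[1]], study$annotations$genes,
                                study$genome, "3p")

    ## DMRs
    wins <- lapply(meths, windowMethylation, chromLengths = study$genome,
                   windowSize = config$dmrSize)
    d12 <- callDmrs(wins[[1]], wins[[2]])
    d13 <- callDmrs(wins[[1]], wins[[3]])
    d23 <- callDmrs(wins[[2]], wins[[3]])
    cons <- conservedDmrs(d12, d13, d23)
    fdr <- permutationFdr(wins[[1]], wins[[2]], wins[[3]], nPerm = nPerm,
                          seed = config$seed + 808L)

    ## SNPs against truth
    snps <- callSnps(study$reads[, .BSREAD_COLS], study$genome)
    truthKey <- paste(study$snps$chrom, study$snps$pos)
    callKey <- paste(snps$chrom, snps$pos)
    callable <- !study$snps$at_cg
    snpEval <- list(
        precision = if (nrow(snps)) mean(callKey %in% truthKey) else NA,
        recall = if (any(callable))
            mean(paste(study$snps$chrom, study$snps$pos)[callable] %in%
                 callKey) else NA,
        n_called = nrow(snps), n_truth = nrow(study$snps))

    ## ASE; the planted allele-biased genes play the imprinted-list role
    exonic <- mapExonicSnps(snps, study$rnaCounts,
                            study$annotations$genes)
    ase <- aseTest(exonic)
    aseThreshold <- calibrateThreshold(ase$p_value, 0.01)
    impr <- tryCatch(
        imprintedEnrichment(ase$gene_id[ase$significant],
                            study$truth$ase_genes$gene_id, ase$gene_id),
        error = function(e) NULL)

    ## ASM + phasing of the first planted ASM gene
    asm <- asmScan(study$reads[, .BSREAD_COLS], snps, study$genome)
    geneTab <- asmGeneTable(asm, study$annotations$genes)
    enrich <- if (nrow(geneTab) && any(geneTab$n_tested >= 3L))
        geneAsmEnrichment(geneTab, mean(asm$significant)) else NULL

    ## TFBS screen (lines 1 vs 2)
    tf <- motifCorrelation(meths[[1]], meths[[2]], study$expression,
                           lineNames[1], lineNames[2],
                           study$annotations$tfbs)

    summary <- data.frame(
        cg_level = global$level[global$label == "CG"],
        tacag_level = global$level[global$label == "TACAG"],
        cg_symmetric_fraction = concordantFraction(symCg),
        conserved_cg_fraction = concordantFraction(consCg),
        dmr_conserved_fraction = cons$fraction,
        dmr_fdr = fdr$fdr,
        snp_precision = snpEval$precision,
        snp_recall = snpEval$recall,
        n_ase_significant = sum(ase$significant),
        ase_threshold = aseThreshold,
        asm_fraction_significant = attr(asm, "fraction_significant"),
        n_motifs_sensitive = sum(tf$methylation_sensitive))

    res <- list(study = study, methylome = methReads, global = global,
                lineMethylomes = meths, conservation_cg = consCg,
                conservation_noncg = consNonCg, symmetry_cg = symCg,
                splice = splice, windows = wins,
                dmrs = list(d12 = d12, d13 = d13, d23 = d23),
                conserved_dmrs = cons, dmr_fdr = fdr, snps = snps,
                snp_eval = snpEval, exonic_snps = exonic, ase = ase,
                ase_threshold = aseThreshold, imprinted = impr, asm = asm,
                asm_genes = geneTab, asm_enrichment = enrich, tfbs = tf,
                summary = summary)

    if (!is.null(outDir)) {
        dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
        writeFastaGenome(study$genome, file.path(outDir, "genome.fa"))
        writeMethylome(methReads, file.path(outDir, "methylome_line1.tsv"))
        writeBsReads(study$reads, file.path(outDir, "bsreads_line1.tsv"))
        writeBed12(study$annotations$genes, file.path(outDir, "genes.bed"))
        writeExpressionTable(study$expression,
                             file.path(outDir, "expression.tsv"))
        write.table(snps, file.path(outDir, "snps.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
        write.table(ase, file.path(outDir, "ase.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
        write.table(asm, file.path(outDir, "asm_sites.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
        write.table(tf, file.path(outDir, "tfbs_motifs.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
        write.table(summary, file.path(outDir, "summary.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
    }
    res
}
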
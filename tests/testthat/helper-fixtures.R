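# in-code fixture builders shared across test files

suppressPackageStartupMessages({
    library(SummarizedExperiment)
    library(GenomicRanges)
})

# write a minimal VCF from a dose matrix (rows = SNPs; 0/1/2/NA)
write_vcf_fixture <- function(dose, pos, chrom = "Chr01",
                              ref = NULL, alt = NULL,
                              path = tempfile(fileext = ".vcf"),
                              extra_lines = NULL) {
    stopifnot(nrow(dose) == length(pos))
    if (length(chrom) == 1L) chrom <- rep(chrom, nrow(dose))
    if (is.null(ref)) ref <- rep("A", nrow(dose))
    if (is.null(alt)) alt <- rep("T", nrow(dose))
    if (is.null(colnames(dose)))
        colnames(dose) <- sprintf("S%03d", seq_len(ncol(dose)))
    gt <- matrix("./.", nrow(dose), ncol(dose))
    gt[!is.na(dose) & dose == 0] <- "0/0"
    gt[!is.na(dose) & dose == 1] <- "0/1"
    gt[!is.na(dose) & dose == 2] <- "1/1"
    lines <- c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"GT\">",
               paste0("##contig=<ID=", unique(chrom), ">"),
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", colnames(dose)),
                     collapse = "\t"),
               paste(chrom, pos, ".", ref, alt, ".", "PASS", ".", "GT",
                     apply(gt, 1, paste, collapse = "\t"), sep = "\t"))
    if (!is.null(extra_lines)) lines <- c(lines, extra_lines)
    writeLines(lines, path)
    path
}

# GenotypeData straight from a dose matrix, bypassing the VCF
make_gt <- function(dose, pos, chrom = "Chr01", subpop = NULL) {
    if (length(chrom) == 1L) chrom <- rep(chrom, nrow(dose))
    if (is.null(colnames(dose)))
        colnames(dose) <- sprintf("S%03d", seq_len(ncol(dose)))
    gr <- GRanges(chrom, IRanges(pos, width = 1L),
                  ref = rep("A", nrow(dose)), alt = rep("T", nrow(dose)))
    se <- SummarizedExperiment(
        assays = list(geno = dose), rowRanges = gr,
        colData = DataFrame(accession = colnames(dose),
                            subpop = if (is.null(subpop))
                                NA_character_ else subpop,
                            row.names = colnames(dose)))
    new("GenotypeData", se)
}

# wide allele-frequency table as alleleFrequencies() would emit it
make_freq_df <- function(locus_id, allele, ...) {
    df <- data.frame(locus_id = locus_id, allele = allele,
                     stringsAsFactors = FALSE)
    pops <- list(...)
    for (p in names(pops)) df[[p]] <- pops[[p]]
    df$overall <- rowMeans(as.data.frame(pops), na.rm = TRUE)
    df
}

manifest_file <- function(acc, labels, path = tempfile(fileext = ".tsv")) {
    writeLines(paste(acc, labels, sep = "\t"), path)
    path
}
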
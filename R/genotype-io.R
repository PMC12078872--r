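#' Read biallelic SNP genotypes from a VCF file
#'
#' Reads a VCF 4.x file of an inbred accession panel into a [GenotypeData]
#' object. Only biallelic SNV records are retained (multi-allelic sites are
#' dropped, not split, so that haplotype-block alleles are built on a uniform
#' biallelic SNP backbone). Records are then filtered on whole-sample minor
#' allele frequency, computed over non-missing calls with heterozygotes
#' contributing half a dose of each allele, and sorted by (chromosome,
#' position).
#'
#' @param path path to an (uncompressed or bgzipped) VCF file
#' @param minMaf minimum whole-sample minor allele frequency, in `[0, 0.5]`;
#'   records with MAF below this are dropped. Default 0.01, the conventional
#'   1% cut for resequencing panels.
#' @return a [GenotypeData] object
#' @examples
#' vcf <- system.file("extdata", "toy.vcf", package = "glacomp")
#' gt <- readGenotypes(vcf, minMaf = 0)
#' gt
#' @export
readGenotypes <- function(path, minMaf = 0.01) {
    if (!is.numeric(minMaf) || length(minMaf) != 1L ||
        minMaf < 0 || minMaf > 0.5)
        stop("'minMaf' must be a single value in [0, 0.5]")
    if (!file.exists(path))
        stop("VCF file not found: ", path)
    vcf <- tryCatch(
        suppressWarnings(VariantAnnotation::readVcf(path)),
        error = function(e) stop("malformed VCF '", path, "': ",
                                 conditionMessage(e), call. = FALSE))
    rr <- SummarizedExperiment::rowRanges(vcf)
    ref <- as.character(rr$REF)
    altl <- rr$ALT
    biallelic <- lengths(altl) == 1L & nchar(ref) == 1L
    alt <- rep(NA_character_, length(rr))
    alt[biallelic] <- as.character(unlist(altl[biallelic]))
    keep <- biallelic & !is.na(alt) & nchar(alt) == 1L &
        ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
    if (!any(keep))
        stop("no biallelic SNP records in ", path)

    gmat <- VariantAnnotation::geno(vcf)$GT
    if (is.null(gmat))
        stop("VCF '", path, "' has no GT genotype field")
    gmat <- gmat[keep, , drop = FALSE]
    rr <- rr[keep]
    ref <- ref[keep]
    alt <- alt[keep]

    dose <- matrix(NA_integer_, nrow(gmat), ncol(gmat),
                   dimnames = list(NULL, colnames(gmat)))
    dose[gmat %in% c("0/0", "0|0")] <- 0L
    dose[gmat %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
    dose[gmat %in% c("1/1", "1|1")] <- 2L

    maf <- .whole_sample_maf(dose)
    keep2 <- !is.na(maf) & maf >= minMaf
    if (!any(keep2))
        stop("no SNPs passed the MAF >= ", minMaf, " filter")
    dose <- dose[keep2, , drop = FALSE]
    rr <- rr[keep2]
    ref <- ref[keep2]
    alt <- alt[keep2]

    gr <- GRanges(seqnames(rr), IRanges(start(rr), width = 1L),
                  ref = ref, alt = alt)
    o <- order(as.integer(seqnames(gr)), start(gr))
    gr <- gr[o]
    dose <- dose[o, , drop = FALSE]

    dup <- duplicated(paste(seqnames(gr), start(gr)))
    if (any(dup)) {
        warning(sum(dup), " duplicate (chrom, pos) record(s) dropped")
        gr <- gr[!dup]
        dose <- dose[!dup, , drop = FALSE]
    }

    se <- SummarizedExperiment(
        assays = list(geno = dose), rowRanges = gr,
        colData = DataFrame(accession = colnames(dose),
                            subpop = NA_character_,
                            row.names = colnames(dose)))
    new("GenotypeData", se)
}

# alt-allele frequency folded to minor; NA when every call is missing
.whole_sample_maf <- function(dose) {
    nonmiss <- rowSums(!is.na(dose))
    f <- rowSums(dose, na.rm = TRUE) / (2 * nonmiss)
    f[nonmiss == 0L] <- NA_real_
    pmin(f, 1 - f)
}

#' Read a sample manifest mapping accessions to subpopulations
#'
#' The manifest is a two-column delimited table (tab, comma or whitespace):
#' accession identifier, subpopulation (stage) label. A header line is
#' allowed and detected when its first field matches none of the genotype
#' accessions (or equals `"accession"`). The order of first appearance of the
#' labels is preserved as the stage order attribute.
#'
#' @param path path to the manifest file
#' @param genotypes optional [GenotypeData]; when supplied, every genotyped
#'   accession must be present in the manifest (an error lists any that are
#'   not) and manifest rows for unknown accessions are reported via `message`.
#' @return named character vector: `labels[accession]`, with attribute
#'   `"stages"` giving labels in order of first appearance
#' @export
readManifest <- function(path, genotypes = NULL) {
    if (!file.exists(path))
        stop("manifest file not found: ", path)
    raw <- utils::read.table(path, header = FALSE, sep = "",
                             colClasses = "character",
                             comment.char = "#", quote = "\"")
    if (ncol(raw) == 1L)
        raw <- utils::read.table(path, header = FALSE, sep = ",",
                                 colClasses = "character",
                                 comment.char = "#", quote = "\"")
    if (ncol(raw) < 2L)
        stop("manifest must have two columns (accession, subpopulation)")
    raw <- raw[, 1:2]
    hdr <- identical(tolower(raw[1, 1]), "accession") ||
        (!is.null(genotypes) && !(raw[1, 1] %in% colnames(genotypes)))
    if (hdr && nrow(raw) > 1L) raw <- raw[-1, , drop = FALSE]
    acc <- raw[, 1]
    lab <- raw[, 2]
    if (anyDuplicated(acc))
        stop("duplicate accession row(s) in manifest: ",
             paste(unique(acc[duplicated(acc)]), collapse = ", "))
    if (any(!nzchar(lab)))
        stop("empty subpopulation label for accession(s): ",
             paste(acc[!nzchar(lab)], collapse = ", "))
    if (!is.null(genotypes)) {
        missing <- setdiff(colnames(genotypes), acc)
        if (length(missing))
            stop("accession(s) in VCF but not in manifest: ",
                 paste(missing, collapse = ", "))
        extra <- setdiff(acc, colnames(genotypes))
        if (length(extra))
            message(length(extra), " manifest row(s) not in the VCF: ",
                    paste(extra, collapse = ", "))
    }
    out <- stats::setNames(lab, acc)
    attr(out, "stages") <- unique(lab)
    out
}
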
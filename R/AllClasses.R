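#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<- metadata metadata<-
#' @importFrom IRanges IRanges IntegerList CharacterList
#' @importFrom GenomicRanges GRanges
#' @importFrom BiocGenerics start end width
#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowRanges colData colData<-
#' @importFrom GenomeInfoDb seqnames seqlevelsInUse
NULL

#' Container for biallelic SNP genotypes of an inbred panel
#'
#' Extends [SummarizedExperiment::RangedSummarizedExperiment]. The single
#' assay `"geno"` holds the alternate-allele dose per SNP and accession:
#' 0 (homozygous reference), 2 (homozygous alternate), 1 (heterozygous) or
#' `NA` (missing call). Row ranges are width-1 [GenomicRanges::GRanges] with
#' metadata columns `ref` and `alt`; `colData` carries the accession
#' identifiers and, once a sample manifest has been attached, the
#' subpopulation (stage) label of each accession.
#'
#' @slot .Data see [SummarizedExperiment::RangedSummarizedExperiment]
#' @seealso [readGenotypes()], [subpopulations()]
#' @export
setClass("GenotypeData", contains = "RangedSummarizedExperiment")

setValidity("GenotypeData", function(object) {
    msg <- character()
    if (!"geno" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'geno' is required")
    else {
        g <- assay(object, "geno")
        if (!all(g[!is.na(g)] %in% c(0L, 1L, 2L)))
            msg <- c(msg, "genotype doses must be 0, 1, 2 or NA")
    }
    rr <- rowRanges(object)
    if (!all(c("ref", "alt") %in% names(mcols(rr))))
        msg <- c(msg, "rowRanges must carry 'ref' and 'alt'")
    if (length(rr) && any(width(rr) != 1L))
        msg <- c(msg, "SNP ranges must have width 1")
    pos_key <- paste(seqnames(rr), start(rr))
    if (anyDuplicated(pos_key))
        msg <- c(msg, "duplicate (chrom, pos) records")
    if (length(msg)) msg else TRUE
})

#' Container for SNPLDB loci and per-accession allele calls
#'
#' Extends [SummarizedExperiment::RangedSummarizedExperiment]. Rows are
#' SNPLDB loci (multi-SNP linkage-disequilibrium blocks or singleton SNPs);
#' columns are accessions. The single assay `"allele"` stores the called
#' haplotype allele per locus and accession as a character code (a binary
#' string over the constituent SNPs, e.g. `"010"`; `"0"`/`"1"` for
#' singletons), `NA` when any constituent call is heterozygous or missing.
#'
#' Row ranges span each locus (1-based, inclusive) with metadata columns
#' `locus_id`, `n_snps`, `snp_pos` (an [IRanges::IntegerList]) and `alleles`
#' (an [IRanges::CharacterList]: the allele catalogue after rare-haplotype
#' merging, ordered by decreasing whole-sample frequency).
#'
#' @seealso [callHaplotypes()], [alleleFrequencies()]
#' @export
setClass("SnpldbSet", contains = "RangedSummarizedExperiment")

setValidity("SnpldbSet", function(object) {
    msg <- character()
    if (!"allele" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'allele' is required")
    rr <- rowRanges(object)
    need <- c("locus_id", "n_snps", "snp_pos", "alleles")
    if (!all(need %in% names(mcols(rr))))
        msg <- c(msg, sprintf("rowRanges must carry %s",
                              paste(need, collapse = ", ")))
    else {
        cat_ok <- vapply(seq_along(rr), function(i) {
            calls <- assay(object, "allele")[i, ]
            all(calls[!is.na(calls)] %in% mcols(rr)$alleles[[i]])
        }, logical(1))
        if (!all(cat_ok))
            msg <- c(msg, "allele calls outside the locus catalogue")
        if (any(lengths(mcols(rr)$alleles) < 1L))
            msg <- c(msg, "every locus needs at least one allele")
    }
    if (length(msg)) msg else TRUE
})

setMethod("show", "GenotypeData", function(object) {
    cat(sprintf("GenotypeData: %d biallelic SNPs x %d accessions\n",
                nrow(object), ncol(object)))
    sp <- colData(object)$subpop
    if (!is.null(sp) && !all(is.na(sp))) {
        tab <- table(sp)
        cat("subpopulations:",
            paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
    } else cat("subpopulations: not assigned\n")
    cat("chromosomes:",
        paste(GenomeInfoDb::seqlevelsInUse(rowRanges(object)), collapse = ", "),
        "\n")
})

setMethod("show", "SnpldbSet", function(object) {
    rr <- rowRanges(object)
    nall <- lengths(mcols(rr)$alleles)
    cat(sprintf("SnpldbSet: %d loci x %d accessions\n",
                nrow(object), ncol(object)))
    cat(sprintf("  multi-SNP blocks: %d, singleton SNPs: %d\n",
                sum(mcols(rr)$n_snps > 1L), sum(mcols(rr)$n_snps == 1L)))
    if (length(nall))
        cat(sprintf("  alleles per locus: %d-%d (mean %.2f)\n",
                    min(nall), max(nall), mean(nall)))
})

#' Accession subpopulation (stage) labels
#'
#' Get or set the subpopulation label of every accession, in column order.
#' Assigning labels expects a character vector named by accession id (as
#' returned by [readManifest()]) or an unnamed vector in column order.
#'
#' @param x a [GenotypeData] or [SnpldbSet] object
#' @param value named (by accession) or positional character vector of labels
#' @return character vector of labels, named by accession
#' @export
setGeneric("subpopulations", function(x) standardGeneric("subpopulations"))

#' @rdname subpopulations
#' @export
setGeneric("subpopulations<-",
           function(x, value) standardGeneric("subpopulations<-"))

.get_subpop <- function(x) {
    sp <- colData(x)$subpop
    if (is.null(sp)) sp <- rep(NA_character_, ncol(x))
    names(sp) <- colnames(x)
    sp
}

.set_subpop <- function(x, value) {
    if (!is.null(names(value))) {
        missing <- setdiff(colnames(x), names(value))
        if (length(missing))
            stop("no subpopulation label for accession(s): ",
                 paste(missing, collapse = ", "))
        value <- value[colnames(x)]
    } else if (length(value) != ncol(x)) {
        stop("unnamed label vector must have one entry per accession")
    }
    colData(x)$subpop <- unname(as.character(value))
    validObject(x)
    x
}

#' @rdname subpopulations
setMethod("subpopulations", "GenotypeData", .get_subpop)
#' @rdname subpopulations
setMethod("subpopulations", "SnpldbSet", .get_subpop)
#' @rdname subpopulations
setReplaceMethod("subpopulations", "GenotypeData", .set_subpop)
#' @rdname subpopulations
setReplaceMethod("subpopulations", "SnpldbSet", .set_subpop)

#' Allele catalogue of SNPLDB loci
#'
#' @param x a [SnpldbSet]
#' @return an [IRanges::CharacterList], one element per locus, holding the
#'   haplotype alleles ordered by decreasing whole-sample frequency
#' @export
alleleCatalogue <- function(x) {
    stopifnot(is(x, "SnpldbSet"))
    stats::setNames(mcols(rowRanges(x))$alleles,
                    mcols(rowRanges(x))$locus_id)
}

#' Allele call matrix of SNPLDB loci
#'
#' @param x a [SnpldbSet]
#' @return character matrix (loci x accessions) of haplotype allele codes,
#'   `NA` for missing locus calls
#' @export
alleleCalls <- function(x) {
    stopifnot(is(x, "SnpldbSet"))
    m <- assay(x, "allele")
    rownames(m) <- mcols(rowRanges(x))$locus_id
    m
}

#' Locus identifiers
#'
#' @param x a [SnpldbSet]
#' @return character vector of locus ids (`chrom:start-end`)
#' @export
lociIds <- function(x) {
    stopifnot(is(x, "SnpldbSet"))
    mcols(rowRanges(x))$locus_id
}
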
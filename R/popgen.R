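#' Unbiased nucleotide diversity at one site
#'
#' pi = n/(n-1) * (1 - sum(p_i^2)), the average pairwise difference per site
#' over haploid-equivalent calls (hets are treated as missing in an inbred
#' panel, so every usable call contributes one haplotype).
#'
#' @param counts per-allele carrier counts at the site
#' @param n number of non-missing calls (default `sum(counts)`)
#' @return diversity value; `NA` with a warning when n < 2
#' @examples
#' sitePi(c(2, 2))  # 0.6667: 4 differing pairs of 6
#' @export
sitePi <- function(counts, n = sum(counts)) {
    if (n < 2) {
        warning("fewer than 2 non-missing calls; pi undefined")
        return(NA_real_)
    }
    p <- counts / n
    n / (n - 1) * (1 - sum(p^2))
}

#' Weir-Cockerham FST from per-population allele counts
#'
#' Variance-component estimator (Weir & Cockerham 1984) for
#' haploid-equivalent samples: with r = 2 populations of sizes n_i and
#' allele frequencies p_i, per allele
#' MSP = sum n_i (p_i - p.)^2 / (r - 1), MSG = sum n_i p_i (1 - p_i) /
#' sum (n_i - 1), n_c = (sum n_i - sum n_i^2 / sum n_i) / (r - 1), and
#' theta = sum(MSP - MSG) / sum(MSP + (n_c - 1) MSG) with the sums taken
#' over alleles. Negative estimates are reported as computed unless
#' `clamp = TRUE`.
#'
#' @param counts1,counts2 per-allele carrier counts in the two populations,
#'   over a common allele vector (pad absent alleles with 0)
#' @param clamp clamp negative estimates to 0
#' @return list with `theta`, `num`, `den` (the summed variance components);
#'   `theta` is `NA` with a warning when both populations are monomorphic
#'   for the same allele (no variation to apportion)
#' @export
wcFst <- function(counts1, counts2, clamp = FALSE) {
    stopifnot(length(counts1) == length(counts2))
    n1 <- sum(counts1); n2 <- sum(counts2)
    if (n1 < 2 || n2 < 2)
        stop("both populations need >= 2 non-missing calls")
    poly <- (counts1 + counts2) > 0
    if (sum(poly) < 2) {
        warning("both populations monomorphic for the same allele; ",
                "FST undefined")
        return(list(theta = NA_real_, num = NA_real_, den = NA_real_))
    }
    p1 <- counts1 / n1; p2 <- counts2 / n2
    nsum <- n1 + n2
    n_c <- (nsum - (n1^2 + n2^2) / nsum)  # r - 1 = 1
    pbar <- (n1 * p1 + n2 * p2) / nsum
    msp <- n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2
    msg <- (n1 * p1 * (1 - p1) + n2 * p2 * (1 - p2)) / (nsum - 2)
    num <- sum(msp - msg)
    den <- sum(msp + (n_c - 1) * msg)
    theta <- if (den == 0) NA_real_ else num / den
    if (clamp && !is.na(theta)) theta <- max(theta, 0)
    list(theta = theta, num = num, den = den)
}

#' Per-locus and genome-wide nucleotide diversity
#'
#' Site pi is computed per constituent SNP from homozygous calls within each
#' subpopulation; the locus value is the mean over its SNPs and the genome
#' value the overall mean over loci.
#'
#' @param genotypes a [GenotypeData] with subpopulation labels
#' @param partition locus assignment from [partitionBlocks()]
#' @param pops subpopulations to evaluate (default: all)
#' @return list: `byLocus` (data.frame locus, chrom, start, end, one pi
#'   column per population) and `genome` (named mean over loci)
#' @export
locusDiversity <- function(genotypes, partition, pops = NULL) {
    stopifnot(is(genotypes, "GenotypeData"))
    sp <- subpopulations(genotypes)
    if (is.null(pops)) pops <- unique(unname(sp[!is.na(sp)]))
    dose <- assay(genotypes, "geno")
    gr <- rowRanges(genotypes)
    ids <- split(seq_along(partition), partition)

    snp_pi <- function(g) {
        hom <- g[!is.na(g) & g != 1L]
        if (length(hom) < 2) return(NA_real_)
        sitePi(c(sum(hom == 0L), sum(hom == 2L)))
    }
    by_locus <- data.frame(
        locus = as.integer(names(ids)),
        chrom = vapply(ids, function(r)
            as.character(seqnames(gr))[r[1]], character(1)),
        start = vapply(ids, function(r) min(start(gr)[r]), numeric(1)),
        end = vapply(ids, function(r) max(start(gr)[r]), numeric(1)),
        row.names = NULL)
    for (p in pops) {
        cols <- which(sp == p)
        by_locus[[p]] <- vapply(ids, function(rows) {
            vals <- vapply(rows, function(r) snp_pi(dose[r, cols]),
                           numeric(1))
            mean(vals, na.rm = TRUE)
        }, numeric(1))
    }
    genome <- vapply(pops, function(p)
        mean(by_locus[[p]], na.rm = TRUE), numeric(1))
    list(byLocus = by_locus, genome = genome)
}

#' Per-locus and genome-wide Weir-Cockerham FST between two subpopulations
#'
#' Variance components are computed per constituent SNP (haploid-equivalent
#' homozygous calls) and the locus value is the ratio of the summed
#' components over its SNPs; the genome value is the mean over loci.
#'
#' @param genotypes a [GenotypeData] with subpopulation labels
#' @param partition locus assignment from [partitionBlocks()]
#' @param pop1,pop2 subpopulation labels
#' @param clamp clamp negative locus estimates to 0
#' @return list: `byLocus` (data.frame locus, chrom, start, end, fst) and
#'   `genome` (mean over defined loci)
#' @export
locusFst <- function(genotypes, partition, pop1, pop2, clamp = FALSE) {
    stopifnot(is(genotypes, "GenotypeData"))
    sp <- subpopulations(genotypes)
    dose <- assay(genotypes, "geno")
    gr <- rowRanges(genotypes)
    ids <- split(seq_along(partition), partition)
    c1 <- which(sp == pop1); c2 <- which(sp == pop2)
    if (!length(c1) || !length(c2))
        stop("unknown subpopulation label(s)")

    snp_comp <- function(r) {
        g1 <- dose[r, c1]; g2 <- dose[r, c2]
        h1 <- g1[!is.na(g1) & g1 != 1L]; h2 <- g2[!is.na(g2) & g2 != 1L]
        if (length(h1) < 2 || length(h2) < 2) return(c(NA_real_, NA_real_))
        k1 <- c(sum(h1 == 0L), sum(h1 == 2L))
        k2 <- c(sum(h2 == 0L), sum(h2 == 2L))
        if (sum((k1 + k2) > 0) < 2) return(c(NA_real_, NA_real_))
        est <- wcFst(k1, k2)
        c(est$num, est$den)
    }
    fst <- vapply(ids, function(rows) {
        comp <- vapply(rows, snp_comp, numeric(2))
        num <- sum(comp[1, ], na.rm = TRUE)
        den <- sum(comp[2, ], na.rm = TRUE)
        if (all(is.na(comp[2, ])) || den == 0) return(NA_real_)
        th <- num / den
        if (clamp) max(th, 0) else th
    }, numeric(1))
    by_locus <- data.frame(
        locus = as.integer(names(ids)),
        chrom = vapply(ids, function(r)
            as.character(seqnames(gr))[r[1]], character(1)),
        start = vapply(ids, function(r) min(start(gr)[r]), numeric(1)),
        end = vapply(ids, function(r) max(start(gr)[r]), numeric(1)),
        fst = fst, row.names = NULL)
    list(byLocus = by_locus, genome = mean(fst, na.rm = TRUE))
}

#' Call selective-sweep regions from per-window scores
#'
#' Takes an externally computed per-window selection statistic (e.g. XP-CLR
#' over 100 kb windows sliding by 10 kb), selects the top fraction of
#' windows and merges overlapping or book-ended selected windows into
#' regions. The threshold is the m-th largest score with
#' m = `ceiling(topFraction * N)`; all windows scoring at or above it are
#' selected, so ties are included and at least m windows are always taken.
#'
#' @param windows data.frame with `chrom`, `start`, `end` (1-based,
#'   inclusive) and `score`
#' @param topFraction fraction of windows to select (default 0.05)
#' @return list of class `sweepRegions`: `regions` (data.frame `chrom`,
#'   `start`, `end`, `max_score`, `n_windows`), `threshold`, `n_selected`,
#'   `total_length` (bp)
#' @export
callSweepRegions <- function(windows, topFraction = 0.05) {
    need <- c("chrom", "start", "end", "score")
    if (!all(need %in% colnames(windows)))
        stop("windows need columns: ", paste(need, collapse = ", "))
    if (!nrow(windows)) stop("empty window set")
    stopifnot(topFraction > 0, topFraction < 1)
    sc <- windows$score
    m <- ceiling(topFraction * length(sc))
    thr <- sort(sc, decreasing = TRUE)[m]
    sel <- which(sc >= thr)
    gr <- GRanges(windows$chrom[sel],
                  IRanges(windows$start[sel], windows$end[sel]),
                  score = sc[sel])
    merged <- GenomicRanges::reduce(gr, ignore.strand = TRUE)
    hits <- GenomicRanges::findOverlaps(merged, gr)
    max_score <- tapply(sc[sel][S4Vectors::subjectHits(hits)],
                        S4Vectors::queryHits(hits), max)
    n_win <- tapply(S4Vectors::subjectHits(hits),
                    S4Vectors::queryHits(hits), length)
    regions <- data.frame(chrom = as.character(seqnames(merged)),
                          start = start(merged), end = end(merged),
                          max_score = as.numeric(max_score),
                          n_windows = as.integer(n_win))
    structure(list(regions = regions, threshold = thr,
                   n_selected = length(sel),
                   total_length = sum(width(merged))),
              class = "sweepRegions")
}

#' @export
print.sweepRegions <- function(x, ...) {
    cat(sprintf(
        "sweepRegions: %d region(s) from %d selected window(s), %.4g bp\n",
        nrow(x$regions), x$n_selected, x$total_length))
    cat("score threshold:", x$threshold, "\n")
    invisible(x)
}

#' Write sweep regions as BED (0-based half-open) and TSV
#'
#' @param x a `sweepRegions` object
#' @param bed,tsv destination paths (either may be `NULL`)
#' @return `x`, invisibly
#' @export
writeSweepRegions <- function(x, bed = NULL, tsv = NULL) {
    stopifnot(inherits(x, "sweepRegions"))
    if (!is.null(tsv))
        utils::write.table(x$regions, tsv, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    if (!is.null(bed)) {
        gr <- GRanges(x$regions$chrom,
                      IRanges(x$regions$start, x$regions$end),
                      score = x$regions$max_score)
        rtracklayer::export(gr, bed, format = "BED")
    }
    invisible(x)
}

#' Per-category overlap of allele fates with sweep regions
#'
#' A locus counts as inside a region when its `[start, end]` interval
#' intersects the region (containment is not required; configure with
#' `type = "within"` for containment).
#'
#' @param fates allele fate table from [classifyTransition()]
#' @param loci a [SnpldbSet] or [GenomicRanges::GRanges] with `locus_id`
#' @param regions a `sweepRegions` object, a data.frame with
#'   `chrom`/`start`/`end`, or a [GenomicRanges::GRanges]
#' @param type `"any"` (intersection, default) or `"within"` (containment)
#' @return data.frame: `category`, `n`, `n_in_region`, `pct_in_region`
#' @export
overlapFates <- function(fates, loci, regions, type = c("any", "within")) {
    type <- match.arg(type)
    gr <- .loci_granges(loci)
    if (inherits(regions, "sweepRegions")) regions <- regions$regions
    if (is.data.frame(regions))
        regions <- GRanges(regions$chrom,
                           IRanges(regions$start, regions$end))
    # disjoint seqlevels just mean zero overlap, not a user error
    inside <- suppressWarnings(
        IRanges::overlapsAny(gr, regions, type = type,
                             ignore.strand = TRUE))
    idx <- match(fates$locus_id, mcols(gr)$locus_id)
    if (anyNA(idx))
        stop("fate table references loci absent from the locus set")
    in_reg <- inside[idx]
    out <- data.frame(category = levels(fates$category))
    out$n <- as.vector(table(fates$category))
    out$n_in_region <- as.vector(table(fates$category[in_reg]))
    out$pct_in_region <- ifelse(out$n > 0,
                                round(100 * out$n_in_region / out$n, 2), NA)
    out
}
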
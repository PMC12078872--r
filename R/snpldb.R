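#' Normalised linkage disequilibrium D' from 2x2 haplotype counts
#'
#' Computes |D'| = |D| / Dmax with D = p(AB) - p(A)p(B) and Dmax the usual
#' bound given the marginal frequencies. For an inbred panel, haplotypes are
#' read directly off homozygous calls, so the counts are joint tallies of the
#' two-site haplotypes among accessions homozygous at both sites.
#'
#' @param counts numeric of length 4 (`AB`, `Ab`, `aB`, `ab`) or a 2x2 matrix
#'   with rows = first-site alleles, columns = second-site alleles
#' @param minInformative minimum number of usable joint calls for the
#'   estimate to be flagged informative
#' @return list with `value` (|D'| in `[0,1]`, `NA` when either site is
#'   monomorphic in the usable subset) and `informative` (logical)
#' @examples
#' dprime(c(AB = 40, Ab = 10, aB = 10, ab = 40))$value  # 0.6
#' @export
dprime <- function(counts, minInformative = 5L) {
    if (is.matrix(counts)) counts <- as.vector(t(counts))
    stopifnot(length(counts) == 4L, all(counts >= 0))
    n <- sum(counts)
    if (n == 0)
        return(list(value = NA_real_, informative = FALSE))
    pAB <- counts[1] / n
    pA <- (counts[1] + counts[2]) / n
    pB <- (counts[1] + counts[3]) / n
    if (pA %in% c(0, 1) || pB %in% c(0, 1))
        return(list(value = NA_real_, informative = FALSE))
    D <- pAB - pA * pB
    dmax <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB)
            else        min(pA * pB, (1 - pA) * (1 - pB))
    val <- if (dmax == 0) 0 else abs(D) / dmax
    list(value = unname(min(val, 1)),
         informative = n >= minInformative)
}

# |D'| between two dose vectors (0/1/2/NA); hets and missing are skipped
.dprime_geno <- function(g1, g2, minInformative) {
    use <- !is.na(g1) & !is.na(g2) & g1 != 1L & g2 != 1L
    a <- g1[use] == 2L
    b <- g2[use] == 2L
    dprime(c(sum(a & b), sum(a & !b), sum(!a & b), sum(!a & !b)),
           minInformative = minInformative)
}

#' Partition SNPs into linkage-disequilibrium blocks
#'
#' Greedy contiguous partition in the spirit of the Gabriel haplotype-block
#' rule: on each chromosome, a multi-SNP block is a maximal contiguous run of
#' SNPs whose genomic span does not exceed `maxSpanBp` and in which the
#' proportion of informative pairwise |D'| values that reach `strongLd` is at
#' least `strongPairProp`. The run is grown SNP by SNP and closed at the
#' first SNP whose addition violates either condition. Every SNP not in a
#' multi-SNP run becomes its own singleton locus, so the partition is
#' exhaustive and disjoint.
#'
#' @param genotypes a [GenotypeData]
#' @param maxSpanBp maximum block span in bp (default 100 kb)
#' @param strongLd |D'| threshold for a "strong" pair (default 0.70)
#' @param strongPairProp minimum proportion of informative pairs that must be
#'   strong (default 0.95)
#' @param minInformative minimum usable joint calls for a pair to count as
#'   informative (default 5)
#' @return integer vector, one entry per SNP (row of `genotypes`), giving the
#'   locus index; indices are consecutive in genome order. Attribute
#'   `"n_loci"` gives the number of loci.
#' @export
partitionBlocks <- function(genotypes, maxSpanBp = 1e5, strongLd = 0.70,
                            strongPairProp = 0.95, minInformative = 5L) {
    stopifnot(is(genotypes, "GenotypeData"))
    gr <- rowRanges(genotypes)
    dose <- assay(genotypes, "geno")
    pos <- start(gr)
    chrom <- as.character(seqnames(gr))
    locus <- integer(length(gr))
    next_id <- 1L

    for (chr in unique(chrom)) {
        idx <- which(chrom == chr)
        i <- 1L
        while (i <= length(idx)) {
            n_inf <- 0L
            n_strong <- 0L
            j <- i
            while (j < length(idx) &&
                   pos[idx[j + 1L]] - pos[idx[i]] <= maxSpanBp) {
                cand <- j + 1L
                add_inf <- 0L
                add_strong <- 0L
                for (k in i:j) {
                    dp <- .dprime_geno(dose[idx[k], ], dose[idx[cand], ],
                                       minInformative)
                    if (dp$informative && !is.na(dp$value)) {
                        add_inf <- add_inf + 1L
                        if (dp$value >= strongLd)
                            add_strong <- add_strong + 1L
                    }
                }
                t_inf <- n_inf + add_inf
                t_strong <- n_strong + add_strong
                if (t_inf == 0L || t_strong / t_inf < strongPairProp)
                    break
                n_inf <- t_inf
                n_strong <- t_strong
                j <- cand
            }
            locus[idx[i:j]] <- next_id
            next_id <- next_id + 1L
            i <- j + 1L
        }
    }
    structure(locus, n_loci = next_id - 1L)
}

#' Call multi-allelic haplotype alleles per SNPLDB locus
#'
#' For each locus of a block partition, the haplotype string over the
#' constituent SNPs (one character per SNP: `0` reference, `1` alternate) is
#' read off each accession's homozygous calls; any heterozygous or missing
#' constituent call makes the locus call missing. Haplotypes with
#' whole-sample frequency below `rareThreshold` are merged into the nearest
#' frequent haplotype by Hamming distance (ties resolved towards the more
#' frequent target, residual ties towards the lexicographically smallest).
#' Singleton loci carry the SNP's two observed alleles.
#'
#' @param genotypes a [GenotypeData]
#' @param partition integer locus assignment from [partitionBlocks()]
#' @param rareThreshold whole-sample frequency below which a haplotype is
#'   merged (default 0.01, mirroring the SNP MAF filter)
#' @param mergeRare set `FALSE` to keep rare haplotypes as distinct alleles
#' @return a [SnpldbSet]; loci whose calls are all missing are dropped with a
#'   warning
#' @export
callHaplotypes <- function(genotypes, partition, rareThreshold = 0.01,
                           mergeRare = TRUE) {
    stopifnot(is(genotypes, "GenotypeData"),
              length(partition) == nrow(genotypes))
    gr <- rowRanges(genotypes)
    dose <- assay(genotypes, "geno")
    nacc <- ncol(dose)
    ids <- split(seq_along(partition), partition)

    keep <- logical(length(ids))
    call_rows <- vector("list", length(ids))
    meta <- vector("list", length(ids))

    for (b in seq_along(ids)) {
        rows <- ids[[b]]
        sub <- dose[rows, , drop = FALSE]
        ok <- colSums(is.na(sub) | sub == 1L) == 0L
        calls <- rep(NA_character_, nacc)
        if (any(ok)) {
            bits <- matrix(as.integer(sub[, ok, drop = FALSE] == 2L),
                           nrow = length(rows))
            calls[ok] <- apply(bits, 2, paste, collapse = "")
        }
        if (all(is.na(calls))) {
            warning("locus with all calls missing dropped: ",
                    as.character(seqnames(gr))[rows[1]], ":",
                    start(gr)[rows[1]])
            next
        }
        if (mergeRare)
            calls <- .merge_rare(calls, rareThreshold)
        tab <- sort(table(calls), decreasing = TRUE)
        cat_ord <- names(tab)[order(-as.vector(tab), names(tab))]
        keep[b] <- TRUE
        call_rows[[b]] <- calls
        meta[[b]] <- list(chrom = as.character(seqnames(gr))[rows[1]],
                          start = min(start(gr)[rows]),
                          end = max(start(gr)[rows]),
                          snp_pos = start(gr)[rows],
                          alleles = cat_ord)
    }

    if (!any(keep))
        stop("no locus survived haplotype calling")
    call_rows <- call_rows[keep]
    meta <- meta[keep]

    mat <- do.call(rbind, call_rows)
    colnames(mat) <- colnames(dose)
    chrom <- vapply(meta, `[[`, character(1), "chrom")
    st <- vapply(meta, `[[`, numeric(1), "start")
    en <- vapply(meta, `[[`, numeric(1), "end")
    locus_gr <- GRanges(chrom, IRanges(st, en))
    mcols(locus_gr) <- DataFrame(
        locus_id = sprintf("%s:%d-%d", chrom, as.integer(st), as.integer(en)),
        n_snps = lengths(lapply(meta, `[[`, "snp_pos")),
        snp_pos = IntegerList(lapply(meta, `[[`, "snp_pos")),
        alleles = CharacterList(lapply(meta, `[[`, "alleles")))

    se <- SummarizedExperiment(assays = list(allele = mat),
                               rowRanges = locus_gr,
                               colData = colData(genotypes))
    new("SnpldbSet", se)
}

# merge haplotypes rarer than `threshold` (of non-missing calls) into the
# nearest frequent haplotype by Hamming distance
.merge_rare <- function(calls, threshold) {
    tab <- table(calls)
    freq <- as.vector(tab) / sum(tab)
    names(freq) <- names(tab)
    rare <- names(freq)[freq < threshold]
    frequent <- names(freq)[freq >= threshold]
    if (!length(rare) || !length(frequent))
        return(calls)
    remap <- stats::setNames(names(freq), names(freq))
    for (h in rare) {
        d <- vapply(frequent, function(f) .hamming(h, f), numeric(1))
        best <- frequent[d == min(d)]
        if (length(best) > 1L) {
            bf <- freq[best]
            best <- best[bf == max(bf)]
            best <- sort(best)[1]
        }
        remap[h] <- best
    }
    unname(remap[calls])
}

.hamming <- function(a, b) {
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

#' Per-subpopulation allele frequencies of SNPLDB loci
#'
#' For every locus and catalogue allele, the carrier frequency within each
#' subpopulation (carrier count / non-missing count) and over the whole
#' sample. The allele universe is the locus catalogue, i.e. all alleles with
#' whole-sample frequency > 0. A subpopulation with zero non-missing calls at
#' a locus gets `NA` frequencies there (undefined, treated as unclassifiable
#' downstream and reported).
#'
#' @param calls a [SnpldbSet] with subpopulation labels assigned
#' @return data.frame with columns `locus_id`, `allele`, `overall`, one
#'   frequency column per subpopulation (in stage order of first appearance),
#'   and one `n_<pop>` non-missing-count column per subpopulation. Attribute
#'   `"pops"` gives the subpopulation order.
#' @export
alleleFrequencies <- function(calls) {
    stopifnot(is(calls, "SnpldbSet"))
    sp <- subpopulations(calls)
    if (any(is.na(sp)))
        stop("subpopulation labels missing; assign them with ",
             "subpopulations(x) <- readManifest(...)")
    pops <- unique(unname(sp))
    mat <- assay(calls, "allele")
    cats <- mcols(rowRanges(calls))$alleles
    lid <- mcols(rowRanges(calls))$locus_id

    pieces <- vector("list", nrow(mat))
    for (i in seq_len(nrow(mat))) {
        al <- cats[[i]]
        row <- mat[i, ]
        df <- data.frame(locus_id = lid[i], allele = al,
                         stringsAsFactors = FALSE)
        nm <- sum(!is.na(row))
        df$overall <- as.vector(table(factor(row, levels = al))) / nm
        for (p in pops) {
            v <- row[sp == p]
            np <- sum(!is.na(v))
            df[[p]] <- if (np == 0L) NA_real_ else
                as.vector(table(factor(v, levels = al))) / np
            df[[paste0("n_", p)]] <- np
        }
        pieces[[i]] <- df
    }
    out <- do.call(rbind, pieces)
    rownames(out) <- NULL
    attr(out, "pops") <- pops
    out
}

#' Export the locus table of a SnpldbSet
#'
#' @param x a [SnpldbSet]
#' @param file TSV destination (`locus_id`, `chrom`, `start`, `end`,
#'   `n_snps`, `n_alleles`; coordinates 1-based inclusive)
#' @return the table, invisibly
#' @export
writeLocusTable <- function(x, file) {
    stopifnot(is(x, "SnpldbSet"))
    rr <- rowRanges(x)
    df <- data.frame(locus_id = mcols(rr)$locus_id,
                     chrom = as.character(seqnames(rr)),
                     start = start(rr), end = end(rr),
                     n_snps = mcols(rr)$n_snps,
                     n_alleles = lengths(mcols(rr)$alleles))
    utils::write.table(df, file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(df)
}

#' Export SNPLDB loci as BED intervals
#'
#' Coordinates are converted to BED's 0-based half-open convention.
#'
#' @param x a [SnpldbSet]
#' @param file BED destination
#' @return the [GenomicRanges::GRanges] written, invisibly
#' @export
writeLocusBed <- function(x, file) {
    stopifnot(is(x, "SnpldbSet"))
    gr <- rowRanges(x)
    names(gr) <- mcols(gr)$locus_id
    mcols(gr) <- NULL
    rtracklayer::export(gr, file, format = "BED")
    invisible(gr)
}
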
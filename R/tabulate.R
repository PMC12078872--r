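#' Frequency class labels
#'
#' The 12 classes partition `[0, 1]` as `{0}`, `(0, 0.1]`, `(0.1, 0.2]`, ...,
#' `(0.8, 0.9]`, `(0.9, 1)`, `{1}`. Exact 0 and exact 1 are their own
#' classes because they carry the zero/one (presence/fixation) information;
#' interior bins are right-closed so a boundary value such as 0.1 falls in
#' the lower-labelled class. The `"0.9-0.99"` label denotes the open interval
#' `(0.9, 1)`.
#'
#' @return character vector of the 12 class labels, in ascending order
#' @export
frequencyClassLevels <- function() {
    c("0", "0.0-0.1", "0.1-0.2", "0.2-0.3", "0.3-0.4", "0.4-0.5",
      "0.5-0.6", "0.6-0.7", "0.7-0.8", "0.8-0.9", "0.9-0.99", "1")
}

#' Bin an allele frequency into its class
#'
#' @param f numeric vector of frequencies in `[0, 1]` (`NA` allowed,
#'   propagated)
#' @return factor over [frequencyClassLevels()]
#' @examples
#' binFrequency(c(0, 0.1, 0.95, 1))
#' @export
binFrequency <- function(f) {
    if (any(f < 0 | f > 1, na.rm = TRUE))
        stop("frequencies must lie in [0, 1]")
    lv <- frequencyClassLevels()
    out <- rep(NA_character_, length(f))
    ok <- !is.na(f)
    out[ok & f == 0] <- "0"
    out[ok & f == 1] <- "1"
    mid <- ok & f > 0 & f < 1
    idx <- pmin(ceiling(f[mid] * 10), 10)  # (0,0.1]->1 ... (0.9,1)->10
    out[mid] <- lv[idx + 1L]
    factor(out, levels = lv)
}

#' Child-by-parent frequency-class cross-table of allele fates
#'
#' Counts every universe allele in the cell (child frequency class, parent
#' frequency class). The (0, 0) cell holds the `absent_both` alleles, the
#' rest of row "0" the excluded alleles, and column "0" the emerged plus
#' restored alleles; restored alleles are additionally tallied in the
#' companion matrix `restored` so the two addends can be printed separately
#' (emerged = column-0 cell minus its restored addend). Unclassifiable
#' alleles are left out and counted in the `n_unclassifiable` element.
#'
#' @param fates allele fate table from [classifyTransition()]
#' @return list of class `glacCrossTable`: `table` (12x12 integer matrix,
#'   rows = child class, cols = parent class), `restored` (same shape,
#'   restored-allele addends), `row_margin`, `col_margin`, `total`,
#'   `n_unclassifiable`, `transition`
#' @export
crossTable <- function(fates) {
    ok <- fates$category != "unclassifiable"
    rb <- binFrequency(fates$child_freq[ok])
    cb <- binFrequency(fates$parent_freq[ok])
    tab <- table(child = rb, parent = cb)
    res <- table(child = rb[fates$category[ok] == "restored"],
                 parent = cb[fates$category[ok] == "restored"])
    structure(list(table = unclass(tab), restored = unclass(res),
                   row_margin = rowSums(tab), col_margin = colSums(tab),
                   total = sum(tab), n_unclassifiable = sum(!ok),
                   transition = fates$transition[1]),
              class = "glacCrossTable")
}

#' @export
print.glacCrossTable <- function(x, ...) {
    cat("Frequency-class cross-table (child class x parent class), ",
        x$transition, "\n", sep = "")
    print(x$table)
    cat("total:", x$total,
        " unclassifiable (not shown):", x$n_unclassifiable, "\n")
    invisible(x)
}

#' Marginal zero/one totals of a cross-table
#'
#' The four "edges": excluded alleles (row "0" minus the (0,0) cell),
#' emerged + restored alleles (column "0" minus (0,0)), disappeared loci
#' (row "1" minus (1,1): alleles increased to 1) and emerged + restored loci
#' (column "1" minus (1,1): alleles first decreased from 1).
#'
#' @param x a `glacCrossTable`
#' @return named numeric: `excluded_alleles`, `emerged_plus_restored_alleles`,
#'   `disappeared_loci`, `emerged_plus_restored_loci`
#' @export
crossTableMargins <- function(x) {
    stopifnot(inherits(x, "glacCrossTable"))
    tb <- x$table
    c(excluded_alleles = sum(tb["0", ]) - tb["0", "0"],
      emerged_plus_restored_alleles = sum(tb[, "0"]) - tb["0", "0"],
      disappeared_loci = sum(tb["1", ]) - tb["1", "1"],
      emerged_plus_restored_loci = sum(tb[, "1"]) - tb["1", "1"])
}

#' Write a cross-table as TSV with labelled margins
#'
#' @param x a `glacCrossTable`
#' @param file destination path
#' @return the data.frame written, invisibly
#' @export
writeCrossTable <- function(x, file) {
    stopifnot(inherits(x, "glacCrossTable"))
    df <- as.data.frame.matrix(x$table)
    df <- cbind(child_class = rownames(x$table), df)
    df$row_total <- x$row_margin
    tot <- c("col_total", as.character(x$col_margin), as.character(x$total))
    out <- rbind(df, stats::setNames(as.list(tot), colnames(df)))
    utils::write.table(out, file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(out)
}

#' Summarise one transition: counts, percentages and per-year rates
#'
#' Produces the standard report for a transition: per-category allele counts
#' and percentages of the allele universe; the zero/one block (allele
#' exclusion/emergence, locus polymorphism disappearance/emergence) with
#' per-year and per-year-per-unit rates; fixed-locus tallies in the parent
#' and child populations; and the composite zero/one percentage (excluded +
#' emerged + LPD + LPE), computed as the sum of the 2-decimal category
#' percentages as in standard table presentation.
#'
#' @param fates allele fate table from [classifyTransition()]
#' @param locusFates locus fate table from [deriveLocusFates()]
#' @param spec the [transitionSpec()] of this transition
#' @param alleleUniverse,locusUniverse universe sizes for percentages and
#'   per-unit rates; defaults are the classifiable allele count and the
#'   locus count
#' @return list of class `glacSummary`: `alleles` (per-category data.frame),
#'   `rates` (zero/one rate block), `fixed_loci`, `zero_one_pct`,
#'   `allele_universe`, `locus_universe`, `n_unclassifiable`, `transition`
#' @export
summarizeTransition <- function(fates, locusFates, spec,
                                alleleUniverse = NULL, locusUniverse = NULL) {
    tab <- table(fates$category)
    n_unc <- tab[["unclassifiable"]]
    if (is.null(alleleUniverse)) alleleUniverse <- sum(tab) - n_unc
    ltab <- table(locusFates$category)
    if (is.null(locusUniverse))
        locusUniverse <- sum(ltab) - ltab[["absent"]]

    cats <- setdiff(alleleFateLevels(), "unclassifiable")
    alleles <- data.frame(category = cats,
                          n = as.vector(tab[cats]),
                          pct = round(100 * as.vector(tab[cats]) /
                                          alleleUniverse, 2))

    rates <- rbind(
        cbind(what = "allele_exclusion",
              perYearRates(tab[["excluded"]], spec$years, alleleUniverse)),
        cbind(what = "allele_emergence",
              perYearRates(tab[["emerged"]], spec$years, alleleUniverse)),
        cbind(what = "locus_polymorphism_disappeared",
              perYearRates(tab[["inherited_LPD"]], spec$years,
                           locusUniverse)),
        cbind(what = "locus_polymorphism_emerged",
              perYearRates(tab[["inherited_LPE"]], spec$years,
                           locusUniverse)))
    rownames(rates) <- NULL
    rates$pct_of_universe <- round(100 * rates$count / rates$universe, 2)

    # loci monomorphic within each population (exactly one allele at freq 1)
    fixed <- c(parent = .n_fixed_loci(fates, "parent_freq"),
               child = .n_fixed_loci(fates, "child_freq"))

    zero_one <- sum(round(100 * c(tab[["excluded"]], tab[["emerged"]],
                                  tab[["inherited_LPD"]],
                                  tab[["inherited_LPE"]]) /
                              alleleUniverse, 2))

    structure(list(alleles = alleles, rates = rates, fixed_loci = fixed,
                   zero_one_pct = zero_one,
                   allele_universe = alleleUniverse,
                   locus_universe = locusUniverse,
                   n_unclassifiable = n_unc,
                   transition = spec$label),
              class = "glacSummary")
}

.n_fixed_loci <- function(fates, col) {
    f <- fates[[col]]
    length(unique(fates$locus_id[!is.na(f) & f == 1]))
}

#' @export
print.glacSummary <- function(x, ...) {
    cat("Transition summary:", x$transition, "\n")
    cat("allele universe:", x$allele_universe,
        " locus universe:", x$locus_universe,
        " unclassifiable:", x$n_unclassifiable, "\n\n")
    print(x$alleles, row.names = FALSE)
    cat("\nzero/one rate block:\n")
    print(x$rates[, c("what", "count", "pct_of_universe",
                      "perYear", "perYearPerUnit")], row.names = FALSE)
    cat("\nfixed loci: parent", x$fixed_loci[["parent"]],
        " child", x$fixed_loci[["child"]], "\n")
    cat(sprintf("composite zero/one change: %.2f%%\n", x$zero_one_pct))
    invisible(x)
}

#' Chromosome-window densities of loci and fate categories
#'
#' Tiles each chromosome with windows of `windowBp` and counts, per window,
#' the SNPLDB loci (assigned to the window containing their start) and the
#' alleles of each fate category at those loci. If annotation intervals are
#' given (e.g. pericentromeres), the fraction of each window covered is
#' reported.
#'
#' @param fates allele fate table from [classifyTransition()]
#' @param loci a [SnpldbSet] (or a [GenomicRanges::GRanges] with a
#'   `locus_id` metadata column) giving locus coordinates
#' @param windowBp window width in bp
#' @param annotations optional [GenomicRanges::GRanges] or path to a BED file
#' @return data.frame: `chrom`, `start`, `end` (1-based inclusive),
#'   `n_loci`, one count column per fate category, and `annotation_frac`
#'   when annotations are supplied
#' @export
windowDensity <- function(fates, loci, windowBp, annotations = NULL) {
    stopifnot(windowBp > 0)
    gr <- .loci_granges(loci)
    if (is.character(annotations))
        annotations <- rtracklayer::import(annotations, format = "BED")

    idx <- match(fates$locus_id, mcols(gr)$locus_id)
    if (anyNA(idx))
        stop("fate table references loci absent from the locus set")

    chrom <- as.character(seqnames(gr))
    win_of <- (start(gr) - 1L) %/% windowBp
    out <- list()
    for (chr in unique(chrom)) {
        sel <- chrom == chr
        n_win <- max(win_of[sel]) + 1L
        wstart <- (seq_len(n_win) - 1L) * windowBp + 1L
        df <- data.frame(chrom = chr, start = wstart,
                         end = wstart + windowBp - 1L)
        df$n_loci <- tabulate(win_of[sel] + 1L, nbins = n_win)
        f_sel <- sel[idx]
        for (cat in levels(fates$category)) {
            in_cat <- f_sel & fates$category == cat
            df[[cat]] <- tabulate(win_of[idx][in_cat] + 1L, nbins = n_win)
        }
        if (!is.null(annotations)) {
            wgr <- GRanges(chr, IRanges(df$start, df$end))
            cov <- GenomicRanges::intersect(
                wgr, GenomicRanges::reduce(annotations), ignore.strand = TRUE)
            hits <- GenomicRanges::findOverlaps(wgr, cov)
            ov <- numeric(n_win)
            if (length(hits)) {
                w <- width(IRanges::pintersect(
                    IRanges::ranges(wgr)[S4Vectors::queryHits(hits)],
                    IRanges::ranges(cov)[S4Vectors::subjectHits(hits)]))
                ov <- as.numeric(tapply(w, factor(S4Vectors::queryHits(hits),
                                                  levels = seq_len(n_win)),
                                        sum))
                ov[is.na(ov)] <- 0
            }
            df$annotation_frac <- ov / windowBp
        }
        out[[chr]] <- df
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}

.loci_granges <- function(loci) {
    if (is(loci, "SnpldbSet")) return(rowRanges(loci))
    if (is(loci, "GRanges")) {
        if (is.null(mcols(loci)$locus_id))
            stop("GRanges loci need a 'locus_id' metadata column")
        return(loci)
    }
    stop("'loci' must be a SnpldbSet or GRanges")
}
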
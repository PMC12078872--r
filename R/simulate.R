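#' Configure a multi-stage population simulation
#'
#' Defines ordered population stages descending from a common ancestral
#' haplotype pool, with planted allele-fate events at each transition and
#' optional drift, heterozygous-call and missing-call noise. Loci are
#' SNPLDB-style blocks built from nested ("staircase") haplotypes, so all
#' constituent SNP pairs are in complete LD (|D'| = 1) and block recovery is
#' well defined; consecutive loci are spaced further apart than the default
#' maximum block span, so distinct loci can never merge.
#'
#' The defaults emulate a three-stage crop germplasm pool: wild accessions
#' (WA, n = 127), landraces (LR, n = 424) and released cultivars (RC,
#' n = 199), a 5000-year domestication transition and a 100-year modern
#' breeding transition that can restore alleles directly from WA, and
#' per-transition event numbers proportioned like the observed soybean
#' dynamics (roughly 14% of loci losing an allele and 15% fixing per
#' transition, with emergence common in domestication and rare in breeding).
#'
#' @param stages stage labels, ancestral first
#' @param sizes accessions per stage
#' @param years duration of each transition (length = stages - 1)
#' @param sources list (length = transitions) of restoration-source stage
#'   labels; a source must precede the transition's parent stage
#' @param nLoci number of SNPLDB loci
#' @param events list (length = transitions) of named integer vectors with
#'   planted event-locus counts; names among `excluded`, `emerged`,
#'   `restored`, `LPD`, `LPE`, `LPR`, `increase`, `decrease`. `NULL` for
#'   proportioned defaults.
#' @param missingRate,hetRate per-call probabilities of missing and
#'   heterozygous noise in the emitted VCF (default 0)
#' @param drift per-transition binomial drift probability applied to
#'   background (non-event) loci; drift shifts counts but is clamped so it
#'   never creates a zero/one change (default 0)
#' @param spacingBp distance between consecutive locus slots (default
#'   150 kb, above the default 100 kb block-span limit)
#' @param seed mandatory RNG seed
#' @return a `simConfig` list
#' @export
simConfig <- function(stages = c("WA", "LR", "RC"),
                      sizes = c(127L, 424L, 199L),
                      years = c(5000, 100),
                      sources = list(character(), "WA"),
                      nLoci = 300L,
                      events = NULL,
                      missingRate = 0, hetRate = 0, drift = 0,
                      spacingBp = 150000L,
                      seed) {
    if (missing(seed)) stop("'seed' is mandatory")
    nT <- length(stages) - 1L
    stopifnot(length(sizes) == length(stages), length(years) == nT,
              length(sources) == nT, all(sizes >= 10), nLoci >= 10,
              missingRate >= 0, missingRate < 1, hetRate >= 0, hetRate < 1,
              drift >= 0, drift < 1)
    for (i in seq_len(nT)) {
        bad <- setdiff(sources[[i]], stages[seq_len(i)])
        if (length(bad))
            stop("restoration source(s) not ancestral to transition ", i,
                 ": ", paste(bad, collapse = ", "))
    }
    if (is.null(events)) {
        events <- lapply(seq_len(nT), function(i) {
            first <- i == 1L
            has_src <- length(sources[[i]]) > 0L
            ev <- c(excluded = round(0.10 * nLoci),
                    emerged = round((if (first) 0.06 else 0.01) * nLoci),
                    LPD = round(0.10 * nLoci),
                    LPE = round((if (first) 0.015 else 0.005) * nLoci),
                    restored = if (has_src) round(0.02 * nLoci) else 0,
                    LPR = if (has_src) round(0.01 * nLoci) else 0,
                    increase = round(0.05 * nLoci),
                    decrease = round(0.05 * nLoci))
            ev[ev > 0]
        })
        # keep a background majority when the stage path is long
        tot <- sum(vapply(events, sum, numeric(1)))
        if (tot > 0.6 * nLoci) {
            f <- 0.6 * nLoci / tot
            events <- lapply(events, function(ev)
                stats::setNames(pmax(1L, as.integer(round(ev * f))),
                                names(ev)))
        }
    }
    valid <- c("excluded", "emerged", "restored", "LPD", "LPE", "LPR",
               "increase", "decrease")
    for (i in seq_len(nT)) {
        ev <- events[[i]]
        bad <- setdiff(names(ev), valid)
        if (length(bad))
            stop("unknown event type(s): ", paste(bad, collapse = ", "))
        if (any(c("restored", "LPR") %in% names(ev)) &&
            !length(sources[[i]]))
            stop("transition ", i, " plants restored/LPR events but has ",
                 "no restoration source")
        if (any(c("restored", "LPR") %in% names(ev))) {
            si <- match(sources[[i]][1], stages)
            if (si >= i)
                stop("transition ", i, " plants restored/LPR events but ",
                     "source stage ", sources[[i]][1],
                     " does not precede the parent stage")
        }
    }
    n_events <- sum(vapply(events, sum, numeric(1)))
    if (n_events > nLoci)
        stop("planted events (", n_events, ") exceed nLoci (", nLoci, ")")
    structure(list(stages = stages, sizes = as.integer(sizes),
                   years = years, sources = sources,
                   nLoci = as.integer(nLoci), events = events,
                   missingRate = missingRate, hetRate = hetRate,
                   drift = drift, spacingBp = as.integer(spacingBp),
                   seed = as.integer(seed)),
              class = "simConfig")
}

# rescale parent counts to child sample size, keeping every segregating
# allele segregating (no accidental zero/one change)
.rescale_counts <- function(counts, n_child) {
    pres <- counts > 0
    p <- counts / sum(counts)
    base <- floor(p * n_child)
    rem <- n_child - sum(base)
    if (rem > 0) {
        frac <- p * n_child - base
        ord <- order(-frac, seq_along(frac))
        base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1L
    }
    # keep present alleles present
    z <- which(pres & base == 0L)
    for (i in z) {
        donor <- which.max(base)
        base[i] <- 1L
        base[donor] <- base[donor] - 1L
    }
    # keep polymorphic loci polymorphic
    if (sum(pres) >= 2L && any(base == n_child)) {
        big <- which(base == n_child)
        other <- setdiff(which(pres), big)[1]
        base[big] <- base[big] - 1L
        base[other] <- base[other] + 1L
    }
    base
}

.drift_counts <- function(counts, drift) {
    pres <- which(counts > 0)
    if (length(pres) < 2L || drift <= 0) return(counts)
    n <- sum(counts)
    shift <- stats::rbinom(1L, n, drift)
    from <- sample(pres, 1L)
    to <- sample(setdiff(pres, from), 1L)
    shift <- min(shift, counts[from] - 1L)          # donor stays present
    shift <- min(shift, n - 1L - counts[to])        # target stays below 1
    counts[from] <- counts[from] - shift
    counts[to] <- counts[to] + shift
    counts
}

# fate predicate applied to planted frequencies (ground truth)
.truth_category <- function(p, cc, src) {
    if (p > 0 && cc == 0) return("excluded")
    if (p == 0 && cc == 0) return("absent_both")
    if (p == 0 && cc > 0)
        return(if (length(src) && any(src > 0)) "restored" else "emerged")
    if (p == 1 && cc == 1) return("inherited_fixed")
    if (p < 1 && cc == 1) return("inherited_LPD")
    if (p == 1 && cc < 1)
        return(if (length(src) && any(src < 1)) "inherited_LPR"
               else "inherited_LPE")
    if (p < cc) return("inherited_increase")
    if (p > cc) return("inherited_decrease")
    "inherited_unchanged"
}

#' Simulate a multi-stage population with planted allele fates
#'
#' Builds per-stage allele counts for every locus by exact-count
#' construction (planted events realise their target frequencies exactly;
#' background loci are rescaled between stages, with optional clamped
#' drift), assigns alleles to accessions, and emits a VCF, a sample
#' manifest, a stage-graph YAML and the ground-truth fate table. The output
#' is deterministic for a fixed seed and round-trips through
#' [readGenotypes()] / [partitionBlocks()] / [callHaplotypes()].
#'
#' @param config a [simConfig()]
#' @param dir output directory (created if needed)
#' @return invisibly, a list with file `paths`, the `truth` data.frame
#'   (`locus_id`, `allele`, `transition`, `category`, `parent_freq`,
#'   `child_freq`), and the `config`
#' @export
simulateHistory <- function(config, dir) {
    stopifnot(inherits(config, "simConfig"))
    set.seed(config$seed)
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    stages <- config$stages
    sizes <- config$sizes
    nS <- length(stages)
    nT <- nS - 1L
    nLoci <- config$nLoci

    # assign event loci (disjoint), remainder background
    plan <- data.frame(locus = seq_len(nLoci),
                       event = "background", transition = NA_integer_,
                       stringsAsFactors = FALSE)
    nxt <- 1L
    for (t in seq_len(nT)) {
        ev <- config$events[[t]]
        for (type in names(ev)) for (r in seq_len(ev[[type]])) {
            plan$event[nxt] <- type
            plan$transition[nxt] <- t
            nxt <- nxt + 1L
        }
    }
    # interleave events with background so they spread over chromosomes
    plan <- plan[sample.int(nLoci), ]
    plan$locus <- seq_len(nLoci)

    n_chrom <- min(20L, max(1L, ceiling(nLoci / 50)))
    chrom_of <- sprintf("Chr%02d", ((seq_len(nLoci) - 1L) %% n_chrom) + 1L)
    slot_of <- (seq_len(nLoci) - 1L) %/% n_chrom

    k_background <- rep(c(2L, 3L, 4L), length.out = sum(plan$event == "background"))
    truth <- vector("list", nLoci)
    vcf_rows <- vector("list", nLoci)
    bg_i <- 0L

    for (li in seq_len(nLoci)) {
        type <- plan$event[li]
        t_ev <- plan$transition[li]
        if (type == "background") {
            bg_i <- bg_i + 1L
            k <- k_background[bg_i]
        } else k <- switch(type,
                           excluded = 3L, emerged = 3L, restored = 3L,
                           LPD = 2L, LPE = 2L, LPR = 2L,
                           increase = 3L, decrease = 3L)
        m <- k - 1L                       # nested staircase haplotypes
        alleles <- vapply(0:(k - 1L), function(s)
            paste0(strrep("1", s), strrep("0", m - s)), character(1))
        si <- if (type %in% c("restored", "LPR"))
            match(config$sources[[t_ev]][1], stages) else NA_integer_

        counts <- matrix(0L, nrow = k, ncol = nS)
        # stage-1 composition
        init <- switch(
            type,
            emerged = c(.random_counts(sizes[1], k - 1L), 0L),
            restored = {
                a <- max(2L, round(0.2 * sizes[1]))
                c(.random_counts(sizes[1] - a, k - 1L), a)
            },
            LPE = c(sizes[1], 0L),
            LPR = {
                b <- max(2L, round(0.3 * sizes[1]))
                c(sizes[1] - b, b)
            },
            .random_counts(sizes[1], k))
        counts[, 1] <- init

        for (t in seq_len(nT)) {
            child <- .rescale_counts(counts[, t], sizes[t + 1L])
            if (!is.na(t_ev) && t == t_ev) {
                child <- .apply_event(child, type, sizes[t + 1L])
            } else if (type == "restored" && !is.na(si) && t == si) {
                # restoration allele drops out right after its source stage
                child[k] <- 0L
                child <- .rescale_counts(child, sizes[t + 1L])
            } else if (type == "LPR" && !is.na(si) &&
                       t >= si && t < t_ev) {
                child <- c(sizes[t + 1L], 0L)   # fixation before restoration
            } else if (type == "LPE" && t < t_ev) {
                child <- c(sizes[t + 1L], 0L)   # stays fixed until the event
            } else if (type == "background" && config$drift > 0) {
                child <- .drift_counts(child, config$drift)
            }
            counts[, t + 1L] <- child
        }

        pos <- slot_of[li] * config$spacingBp + 1L + (seq_len(m) - 1L) * 500L
        lid <- sprintf("%s:%d-%d", chrom_of[li], pos[1], pos[m])

        freqs <- sweep(counts, 2, sizes, "/")
        tr_rows <- vector("list", nT)
        for (t in seq_len(nT)) {
            src <- config$sources[[t]]
            src_f <- if (length(src)) freqs[, match(src, stages), drop = FALSE]
                     else NULL
            cat <- vapply(seq_len(k), function(a)
                .truth_category(freqs[a, t], freqs[a, t + 1L],
                                if (is.null(src_f)) numeric() else src_f[a, ]),
                character(1))
            tr_rows[[t]] <- data.frame(
                locus_id = lid, allele = alleles,
                transition = paste0(stages[t], "->", stages[t + 1L]),
                category = cat,
                parent_freq = freqs[, t], child_freq = freqs[, t + 1L],
                stringsAsFactors = FALSE)
        }
        truth[[li]] <- do.call(rbind, tr_rows)
        vcf_rows[[li]] <- list(chrom = chrom_of[li], pos = pos,
                               counts = counts, k = k, m = m)
    }

    truth <- do.call(rbind, truth)
    rownames(truth) <- NULL

    # realise accessions and emit the VCF
    acc <- unlist(lapply(seq_len(nS), function(s)
        sprintf("%s_%03d", stages[s], seq_len(sizes[s]))))
    labels <- rep(stages, sizes)
    dose_rows <- list()
    chroms <- character(); poss <- integer()
    for (li in seq_len(nLoci)) {
        v <- vcf_rows[[li]]
        allele_of <- unlist(lapply(seq_len(nS), function(s)
            sample(rep.int(seq_len(v$k) - 1L, v$counts[, s]))))
        # staircase bit j is 1 when the allele step >= j
        for (j in seq_len(v$m)) {
            d <- ifelse(allele_of >= j, 2L, 0L)
            dose_rows[[length(dose_rows) + 1L]] <- d
            chroms <- c(chroms, v$chrom)
            poss <- c(poss, v$pos[j])
        }
    }
    dose <- do.call(rbind, dose_rows)
    colnames(dose) <- acc

    if (config$hetRate > 0) {
        flip <- stats::runif(length(dose)) < config$hetRate
        dose[flip] <- 1L
    }
    if (config$missingRate > 0) {
        miss <- stats::runif(length(dose)) < config$missingRate
        dose[miss] <- NA_integer_
    }

    o <- order(chroms, poss)
    dose <- dose[o, , drop = FALSE]
    chroms <- chroms[o]; poss <- poss[o]

    paths <- list(vcf = file.path(dir, "genotypes.vcf"),
                  manifest = file.path(dir, "manifest.tsv"),
                  truth = file.path(dir, "truth.tsv"),
                  stage_graph = file.path(dir, "stage_graph.yaml"))
    .write_vcf(paths$vcf, chroms, poss, dose)
    utils::write.table(data.frame(accession = acc, subpop = labels),
                       paths$manifest, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    utils::write.table(truth, paths$truth, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    yaml::write_yaml(list(transitions = lapply(seq_len(nT), function(t)
        list(parent = stages[t], child = stages[t + 1L],
             years = config$years[t],
             sources = as.list(config$sources[[t]])))),
        paths$stage_graph)
    invisible(list(paths = paths, truth = truth, config = config))
}

.random_counts <- function(n, k) {
    if (k == 1L) return(n)
    w <- stats::runif(k, 0.5, 1.5)
    cnt <- .rescale_counts(as.integer(round(w / sum(w) * n)) + 1L, n)
    cnt
}

.apply_event <- function(child, type, n) {
    k <- length(child)
    switch(type,
        excluded = {
            child[k] <- 0L
            .rescale_counts(child, n)
        },
        emerged = {
            a <- max(2L, round(0.2 * n))
            out <- .rescale_counts(child[-k], n - a)
            c(out, a)
        },
        restored = {
            a <- max(2L, round(0.15 * n))
            out <- .rescale_counts(child[-k], n - a)
            c(out, a)
        },
        LPD = c(n, 0L),
        LPE = {
            b <- max(2L, round(0.2 * n))
            c(n - b, b)
        },
        LPR = {
            b <- max(2L, round(0.1 * n))
            c(n - b, b)
        },
        increase = {
            d <- max(1L, round(0.15 * n))
            d <- min(d, n - 1L - child[1])
            child[1] <- child[1] + d
            .redistribute(child, n, keep = 1L)
        },
        decrease = {
            d <- max(1L, round(0.15 * n))
            d <- min(d, child[1] - 1L)
            child[1] <- child[1] - d
            .redistribute(child, n, keep = 1L)
        })
}

# bring counts back to sum n by adjusting alleles other than `keep`,
# without creating a zero/one change
.redistribute <- function(counts, n, keep) {
    diff <- n - sum(counts)
    others <- setdiff(which(counts > 0), keep)
    while (diff != 0L && length(others)) {
        step <- sign(diff)
        for (i in others) {
            if (diff == 0L) break
            if (step > 0 || counts[i] > 1L) {
                counts[i] <- counts[i] + step
                diff <- diff - step
            }
        }
    }
    counts
}

.write_vcf <- function(path, chroms, poss, dose) {
    gt <- matrix("./.", nrow(dose), ncol(dose))
    gt[!is.na(dose) & dose == 0L] <- "0/0"
    gt[!is.na(dose) & dose == 1L] <- "0/1"
    gt[!is.na(dose) & dose == 2L] <- "1/1"
    refs <- rep(c("A", "C", "G", "T"), length.out = nrow(dose))
    alts <- rep(c("G", "T", "A", "C"), length.out = nrow(dose))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("##fileformat=VCFv4.2",
                 "##source=glacomp-simulateHistory",
                 "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
                 paste0("##contig=<ID=", unique(chroms), ">"),
                 paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                         "FILTER", "INFO", "FORMAT", colnames(dose)),
                       collapse = "\t")), con)
    body <- paste(chroms, poss, ".", refs, alts, ".", "PASS", ".", "GT",
                  apply(gt, 1, paste, collapse = "\t"), sep = "\t")
    writeLines(body, con)
}

#' Compare called fates against the simulation ground truth
#'
#' Joins the pipeline's allele fate table with the simulator's truth table
#' on (locus, allele, transition) and tabulates a planted-vs-called
#' confusion matrix. Called `unclassifiable` alleles (from missing-data
#' noise) are reported separately and excluded from the recovery rate
#' denominator.
#'
#' @param truth truth data.frame from [simulateHistory()] (or read back from
#'   `truth.tsv`)
#' @param fates allele fate table from [classifyTransition()] (rows for one
#'   or more transitions)
#' @return list: `confusion` (table planted x called), `n`, `n_mismatch`,
#'   `recovery_pct`, `n_unclassifiable_called`, `mismatches` (data.frame)
#' @export
verifyRecovery <- function(truth, fates) {
    key_t <- paste(truth$locus_id, truth$allele, truth$transition)
    key_f <- paste(fates$locus_id, fates$allele, fates$transition)
    trans <- unique(truth$transition)
    key_f_in <- key_f[fates$transition %in% trans]
    miss_f <- setdiff(key_t, key_f)
    miss_t <- setdiff(key_f_in, key_t)
    if (length(miss_f) || length(miss_t))
        stop("locus/allele identifier mismatch between truth and fates; ",
             "e.g. ", paste(utils::head(c(miss_f, miss_t), 3),
                            collapse = "; "))
    idx <- match(key_t, key_f)
    called <- as.character(fates$category[idx])
    planted <- as.character(truth$category)
    unc <- called == "unclassifiable"
    conf <- table(planted = planted[!unc], called = called[!unc])
    n <- sum(!unc)
    n_mis <- sum(planted[!unc] != called[!unc])
    mm <- which(planted != called & !unc)
    list(confusion = conf, n = n, n_mismatch = n_mis,
         recovery_pct = if (n) round(100 * (n - n_mis) / n, 2) else NA,
         n_unclassifiable_called = sum(unc),
         mismatches = data.frame(
             locus_id = truth$locus_id[mm], allele = truth$allele[mm],
             transition = truth$transition[mm],
             planted = planted[mm], called = called[mm]))
}
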
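# independent reference implementations used as oracles

# average pairwise difference over all carrier pairs, by enumeration
pi_bruteforce <- function(counts) {
    alleles <- rep(seq_along(counts), counts)
    n <- length(alleles)
    if (n < 2) return(NA_real_)
    diffs <- 0L
    pairs <- 0L
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
        diffs <- diffs + (alleles[i] != alleles[j])
        pairs <- pairs + 1L
    }
    diffs / pairs
}

# Weir-Cockerham theta via explicit individual-level sums of squares
fst_anova_oracle <- function(c1, c2) {
    n1 <- sum(c1); n2 <- sum(c2); r <- 2
    nc <- (n1 + n2 - (n1^2 + n2^2) / (n1 + n2)) / (r - 1)
    num <- 0; den <- 0
    for (a in seq_along(c1)) {
        x1 <- rep(c(1, 0), c(c1[a], n1 - c1[a]))
        x2 <- rep(c(1, 0), c(c2[a], n2 - c2[a]))
        xbar <- mean(c(x1, x2))
        ssb <- n1 * (mean(x1) - xbar)^2 + n2 * (mean(x2) - xbar)^2
        ssw <- sum((x1 - mean(x1))^2) + sum((x2 - mean(x2))^2)
        msp <- ssb / (r - 1)
        msg <- ssw / (n1 + n2 - r)
        num <- num + (msp - msg)
        den <- den + (msp + (nc - 1) * msg)
    }
    num / den
}

# |D'| by direct evaluation of the definition on a 2x2 table
dprime_oracle <- function(ab, aB, Ab, AB = NULL) {
    # accepts a length-4 vector (AB, Ab, aB, ab) like dprime()
    if (is.null(AB)) { v <- ab; ab <- v[4]; aB <- v[3]; Ab <- v[2]; AB <- v[1] }
    n <- AB + Ab + aB + ab
    pA <- (AB + Ab) / n; pB <- (AB + aB) / n
    D <- AB / n - pA * pB
    dmax <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB) else
        min(pA * pB, (1 - pA) * (1 - pB))
    if (dmax == 0) 0 else abs(D) / dmax
}

# merge 1-based inclusive intervals (overlapping or book-ended), by scan
merge_intervals_oracle <- function(chrom, start, end) {
    o <- order(chrom, start, end)
    chrom <- chrom[o]; start <- start[o]; end <- end[o]
    out <- list()
    cur <- NULL
    for (i in seq_along(start)) {
        if (!is.null(cur) && chrom[i] == cur$chrom &&
            start[i] <= cur$end + 1L) {
            cur$end <- max(cur$end, end[i])
        } else {
            if (!is.null(cur)) out[[length(out) + 1L]] <- cur
            cur <- list(chrom = chrom[i], start = start[i], end = end[i])
        }
    }
    out[[length(out) + 1L]] <- cur
    data.frame(chrom = vapply(out, `[[`, "", "chrom"),
               start = vapply(out, `[[`, 0, "start"),
               end = vapply(out, `[[`, 0, "end"))
}

# does interval [s1, e1] intersect any of the regions? by loop
in_any_region_oracle <- function(s1, e1, reg_start, reg_end) {
    for (k in seq_along(reg_start))
        if (s1 <= reg_end[k] && e1 >= reg_start[k]) return(TRUE)
    FALSE
}

hamming_oracle <- function(a, b)
    sum(utf8ToInt(a) != utf8ToInt(b))

# enumerate all count compositions of n into k non-negative parts
compositions <- function(n, k) {
    if (k == 1) return(matrix(n, 1, 1))
    out <- NULL
    for (i in 0:n) {
        sub <- compositions(n - i, k - 1)
        out <- rbind(out, cbind(i, sub))
    }
    unname(out)
}
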
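test_that("site pi equals brute-force pairwise difference (n <= 8)", {
    expect_equal(sitePi(c(5, 0)), 0)
    expect_equal(sitePi(c(1, 1)), 1)
    expect_equal(sitePi(c(2, 2)), 2 / 3, tolerance = 1e-12)
    expect_warning(expect_true(is.na(sitePi(c(1, 0)))), "undefined")

    for (n in 2:8) for (k in 2:3) {
        comps <- compositions(n, k)
        for (i in seq_len(nrow(comps))) {
            cnt <- comps[i, ]
            expect_equal(sitePi(cnt), pi_bruteforce(cnt),
                         tolerance = 1e-12)
        }
    }
})

test_that("Weir-Cockerham FST matches an independent ANOVA evaluation", {
    # alternatively fixed populations
    expect_equal(wcFst(c(50, 0), c(0, 50))$theta, 1)
    # identical frequencies give an estimate at (or just below) zero
    near0 <- wcFst(c(10, 30), c(10, 30))$theta
    expect_lt(abs(near0), 0.05)
    # same-allele monomorphism is undefined, never silently 0
    expect_warning(est <- wcFst(c(20, 0), c(30, 0)), "monomorphic")
    expect_true(is.na(est$theta))

    set.seed(77)
    for (i in 1:100) {
        k <- sample(2:4, 1)
        repeat {
            c1 <- rmultinom(1, sample(4:60, 1), runif(k))[, 1]
            c2 <- rmultinom(1, sample(4:60, 1), runif(k))[, 1]
            if (sum((c1 + c2) > 0) >= 2) break
        }
        est <- wcFst(c1, c2)
        expect_equal(est$theta, fst_anova_oracle(c1, c2),
                     tolerance = 1e-10)
    }
})

test_that("locus-level pi and FST aggregate constituent SNPs", {
    # two-SNP locus, two populations with planted frequencies
    pop <- rep(c("A", "B"), each = 20)
    d1 <- c(rep(2L, 4), rep(0L, 16), rep(2L, 16), rep(0L, 4))  # p 0.2 / 0.8
    d2 <- c(rep(2L, 10), rep(0L, 10), rep(2L, 10), rep(0L, 10)) # p 0.5 / 0.5
    gt <- make_gt(rbind(d1, d2), pos = c(100, 200), subpop = pop)
    part <- c(1L, 1L)

    pi_res <- locusDiversity(gt, part)
    pi_a1 <- sitePi(c(4, 16))
    pi_a2 <- sitePi(c(10, 10))
    expect_equal(pi_res$byLocus$A, mean(c(pi_a1, pi_a2)), tolerance = 1e-12)
    expect_equal(unname(pi_res$genome["A"]), pi_res$byLocus$A)

    fst_res <- locusFst(gt, part, "A", "B")
    o1 <- wcFst(c(4, 16), c(16, 4))
    o2 <- wcFst(c(10, 10), c(10, 10))
    expect_equal(fst_res$byLocus$fst,
                 (o1$num + o2$num) / (o1$den + o2$den), tolerance = 1e-12)
})

test_that("sweep calling selects the top fraction with ties and merges", {
    # 100 windows, the 5 highest adjacent -> one merged region
    win <- data.frame(chrom = "Chr01",
                      start = (0:99) * 10000 + 1,
                      end = (0:99) * 10000 + 100000,
                      score = c(rep(1, 40), 10, 11, 12, 13, 14,
                                rep(1, 55)))
    sw <- callSweepRegions(win, topFraction = 0.05)
    expect_equal(sw$n_selected, 5)
    expect_equal(nrow(sw$regions), 1)
    expect_equal(sw$regions$start, 40 * 10000 + 1)
    expect_equal(sw$regions$end, 44 * 10000 + 100000)
    expect_equal(sw$regions$max_score, 14)

    # 5 highest mutually non-adjacent -> 5 regions
    win2 <- win
    win2$score <- rep(1, 100)
    win2$score[c(1, 20, 40, 60, 99)] <- 5
    win2$start <- (0:99) * 200000 + 1          # disjoint windows
    win2$end <- win2$start + 99999
    sw2 <- callSweepRegions(win2, topFraction = 0.05)
    expect_equal(nrow(sw2$regions), 5)

    # all scores tied -> every window selected, one region per run
    win3 <- win
    win3$score <- 7
    sw3 <- callSweepRegions(win3, topFraction = 0.05)
    expect_equal(sw3$n_selected, 100)
    expect_equal(nrow(sw3$regions), 1)

    expect_error(callSweepRegions(win[0, ]), "empty")
})

test_that("merged sweep regions match an interval-merge oracle", {
    set.seed(13)
    win <- data.frame(chrom = sample(c("Chr01", "Chr02"), 400,
                                     replace = TRUE))
    win$start <- sample.int(5e6, 400)
    win$end <- win$start + 99999
    win$score <- rnorm(400)
    sw <- callSweepRegions(win, topFraction = 0.1)
    sel <- win[win$score >= sw$threshold, ]
    oracle <- merge_intervals_oracle(sel$chrom, sel$start, sel$end)
    got <- sw$regions[order(sw$regions$chrom, sw$regions$start), ]
    expect_equal(got$chrom, oracle$chrom)
    expect_equal(got$start, oracle$start)
    expect_equal(got$end, oracle$end)
    expect_gte(sw$n_selected, ceiling(0.1 * 400))
    expect_equal(sum(sw$regions$n_windows), sw$n_selected)
})

test_that("fate-by-region overlap matches brute-force intersection", {
    gr <- GRanges("Chr01", IRanges((0:9) * 1000 + 1, width = 500),
                  locus_id = sprintf("L%02d", 1:10))
    fates <- data.frame(locus_id = sprintf("L%02d", 1:10), allele = "A",
                        transition = "t",
                        category = factor("excluded",
                                          levels = alleleFateLevels()),
                        parent_freq = 0.5, child_freq = 0)
    # regions covering loci 1-3 -> 30%
    reg <- data.frame(chrom = "Chr01", start = 1, end = 2600)
    ov <- overlapFates(fates, gr, reg)
    expect_equal(ov$pct_in_region[ov$category == "excluded"], 30)

    # all loci inside one region -> 100%; none -> 0%
    expect_equal(overlapFates(fates, gr,
                              data.frame(chrom = "Chr01", start = 1,
                                         end = 1e6)
                              )$pct_in_region[1], 100)
    expect_equal(overlapFates(fates, gr,
                              data.frame(chrom = "Chr02", start = 1,
                                         end = 1e6)
                              )$pct_in_region[1], 0)

    # random mixes agree with the interval oracle, independent of region
    # order and of splitting a region between loci
    set.seed(99)
    regs <- data.frame(chrom = "Chr01",
                       start = sort(sample.int(9000, 3)) + c(0, 2000, 4000))
    regs$end <- regs$start + 800
    inside <- vapply(seq_along(gr), function(i)
        in_any_region_oracle(start(gr)[i], end(gr)[i],
                             regs$start, regs$end), logical(1))
    ov2 <- overlapFates(fates, gr, regs)
    expect_equal(ov2$n_in_region[ov2$category == "excluded"], sum(inside))
    ov3 <- overlapFates(fates, gr, regs[c(3, 1, 2), ])
    expect_equal(ov3$n_in_region, ov2$n_in_region)
})
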
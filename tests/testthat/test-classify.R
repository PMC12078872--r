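test_that("the frequency-predicate taxonomy classifies every case", {
    cases <- data.frame(
        p   = c(0.4, 0.0, 0.0, 0.0, 0.6, 1.0, 1.0, 1.0, 0.2, 0.8, 0.3, 0.0),
        c   = c(0.0, 0.2, 0.2, 0.0, 1.0, 1.0, 0.95, 0.95, 0.5, 0.4, 0.3, 0.0),
        src = c(0.0, 0.0, 0.5, 0.0, 0.7, 1.0, 1.0, 0.9, 0.2, 0.8, 0.3, 0.5),
        expected = c("excluded", "emerged", "restored", "absent_both",
                     "inherited_LPD", "inherited_fixed", "inherited_LPE",
                     "inherited_LPR", "inherited_increase",
                     "inherited_decrease", "inherited_unchanged",
                     "absent_both"))
    freqs <- make_freq_df(sprintf("L%02d", seq_len(nrow(cases))), "A",
                          WA = cases$src, LR = cases$p, RC = cases$c)
    spec <- transitionSpec("LR", "RC", years = 100, sources = "WA")
    fates <- classifyTransition(freqs, spec)
    expect_equal(as.character(fates$category), cases$expected)
    expect_equal(fates$transition, rep("LR->RC", nrow(cases)))

    # without restoration sources there is no restored / LPR class
    spec0 <- transitionSpec("LR", "RC", years = 100)
    f0 <- classifyTransition(freqs, spec0)
    expect_equal(as.character(f0$category[3]), "emerged")
    expect_equal(as.character(f0$category[8]), "inherited_LPE")

    # undefined frequency -> unclassifiable
    freqs$LR[1] <- NA
    fu <- classifyTransition(freqs, spec)
    expect_equal(as.character(fu$category[1]), "unclassifiable")
})

test_that("fate counts partition the allele universe on random tables", {
    set.seed(21)
    for (rep_i in 1:5) {
        n_loci <- 60
        rows <- lapply(seq_len(n_loci), function(l) {
            k <- sample(2:4, 1)
            f <- function() {
                x <- c(runif(k - 1), 0, 1)[sample.int(k + 1, k)]
                x <- x[seq_len(k)]
                if (all(x == 0)) x[1] <- 1
                x / sum(x)
            }
            data.frame(locus_id = sprintf("L%03d", l),
                       allele = sprintf("a%d", seq_len(k)),
                       WA = f(), LR = f(), RC = f())
        })
        freqs <- do.call(rbind, rows)
        spec <- transitionSpec("LR", "RC", years = 100, sources = "WA")
        fates <- classifyTransition(freqs, spec)
        tab <- table(fates$category)

        # partition identity: every universe allele classified exactly once
        expect_equal(sum(tab), nrow(freqs))
        # child allele count identity
        inherited <- sum(tab[c("inherited_fixed", "inherited_LPD",
                               "inherited_LPE", "inherited_LPR",
                               "inherited_increase", "inherited_decrease",
                               "inherited_unchanged")])
        expect_equal(sum(fates$child_freq > 0, na.rm = TRUE),
                     inherited + tab[["emerged"]] + tab[["restored"]])

        # locus-fate coupling
        lf <- deriveLocusFates(fates)
        ltab <- table(lf$category)
        expect_equal(ltab[["polymorphism_disappeared"]],
                     tab[["inherited_LPD"]])
        expect_equal(ltab[["polymorphism_emerged"]],
                     tab[["inherited_LPE"]])

        # monotonicity: moving a child frequency off 0 never creates an
        # exclusion
        bump <- freqs
        z <- which(bump$RC == 0)[1]
        if (!is.na(z)) {
            bump$RC[z] <- 0.05
            f2 <- classifyTransition(bump, spec)
            expect_false(as.character(f2$category[z]) == "excluded")
        }
    }
})

test_that("locus fates follow their allele fates", {
    # 2-allele locus: one excluded, partner to 1 -> polymorphism disappeared
    freqs <- make_freq_df(rep(c("L1", "L2", "L3", "L4"),
                              times = c(2, 2, 3, 2)),
                          c("a", "b", "a", "b", "a", "b", "c", "a", "b"),
                          P = c(0.6, 0.4, 1.0, 0.0, 0.5, 0.3, 0.2, 1.0, 0.0),
                          C = c(1.0, 0.0, 0.7, 0.3, 0.6, 0.4, 0.0, 0.0, 1.0))
    spec <- transitionSpec("P", "C", years = 10)
    fates <- classifyTransition(freqs, spec)
    lf <- deriveLocusFates(fates)
    expect_equal(as.character(lf$category[lf$locus_id == "L1"]),
                 "polymorphism_disappeared")
    # monomorphic parent gaining a second allele -> polymorphism emerged
    expect_equal(as.character(lf$category[lf$locus_id == "L2"]),
                 "polymorphism_emerged")
    # 3-allele locus losing one allele but still segregating
    expect_equal(as.character(lf$category[lf$locus_id == "L3"]),
                 "polymorphic_kept")
    # parent fixed for a, child fixed for b
    expect_equal(as.character(lf$category[lf$locus_id == "L4"]),
                 "fixed_replaced")
})

test_that("fate chains flag successive allele changes along a path", {
    freqs <- make_freq_df(
        sprintf("L%d", 1:5), "A",
        WA = c(0.3, 0.0, 0.5, 0.4, 0.2),
        LR = c(0.0, 0.1, 0.0, 0.2, 0.5),
        RC = c(0.0, 0.2, 0.3, 0.0, 1.0))
    specs <- list(transitionSpec("WA", "LR", 5000),
                  transitionSpec("LR", "RC", 100, sources = "WA"))
    ch <- chainFates(freqs, specs)
    expect_equal(as.character(ch[["WA->LR"]]),
                 c("excluded", "emerged", "excluded",
                   "inherited_decrease", "inherited_increase"))
    expect_equal(as.character(ch[["LR->RC"]]),
                 c("absent_both", "inherited_increase", "restored",
                   "excluded", "inherited_LPD"))
    # an exclusion at the final transition is vacuously permanent
    expect_equal(ch$permanently_excluded,
                 c(TRUE, FALSE, FALSE, TRUE, FALSE))
    expect_equal(ch$emerged_then_inherited,
                 c(FALSE, TRUE, FALSE, FALSE, FALSE))
    expect_equal(ch$exclusion_after_decrease,
                 c(FALSE, FALSE, FALSE, TRUE, FALSE))
    expect_equal(ch$fixation_after_increase,
                 c(FALSE, FALSE, FALSE, FALSE, TRUE))

    # a non-contiguous spec list is a config error
    bad <- list(transitionSpec("WA", "LR", 5000),
                transitionSpec("RC", "XX", 100))
    expect_error(chainFates(freqs, bad), "path")
})

test_that("per-year rates divide counts by years and universe", {
    r1 <- perYearRates(76866, 5000, 559611)
    expect_equal(r1$perYear, 15.37)
    expect_equal(r1$perYearPerUnit, 2.75e-5)
    r2 <- perYearRates(79573, 100, 559611)
    expect_equal(r2$perYear, 795.73)
    expect_equal(r2$perYearPerUnit, 1.42e-3)
    r0 <- perYearRates(0, 100, 10)
    expect_equal(r0$perYear, 0)
    expect_equal(r0$perYearPerUnit, 0)
    expect_error(perYearRates(-1, 100, 10), "non-negative")
})

test_that("motivator grouping pools allele and locus zero/one changes", {
    cats <- rep(c("excluded", "inherited_LPD", "emerged", "inherited_LPE",
                  "restored", "inherited_LPR", "inherited_increase",
                  "inherited_decrease", "absent_both", "inherited_fixed"),
                times = c(10, 4, 6, 2, 3, 1, 30, 24, 12, 8))
    fates <- data.frame(locus_id = seq_along(cats), allele = "A",
                        transition = "P->C",
                        category = factor(cats,
                                          levels = alleleFateLevels()),
                        parent_freq = 0.5, child_freq = 0.5)
    ms <- motivatorSummary(fates)
    expect_equal(attr(ms, "universe"), 100)
    expect_equal(ms$n_total[ms$group == "Exclusion"], 14)
    expect_equal(ms$pct_allele[ms$group == "Exclusion"], 10)
    expect_equal(ms$pct_allele_star[ms$group == "Exclusion"], 4)
    expect_equal(ms$n_total[ms$group == "Emergence"], 8)
    expect_equal(ms$n_total[ms$group == "Restoration"], 4)
    expect_equal(ms$n_total[ms$group == "Ordinary"], 54)
    expect_equal(ms$n_total[ms$group == "NoChange"], 20)

    # all alleles keeping fixation -> NoChange 100%
    f2 <- fates
    f2$category[] <- "inherited_fixed"
    ms2 <- motivatorSummary(f2)
    expect_equal(ms2$pct_total[ms2$group == "NoChange"], 100)
})
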
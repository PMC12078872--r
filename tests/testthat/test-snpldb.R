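test_that("D' matches direct evaluation on canonical and random tables", {
    expect_equal(dprime(c(50, 0, 0, 50))$value, 1.0)
    expect_equal(dprime(c(25, 25, 25, 25))$value, 0.0)
    # D = 0.4 - 0.25 = 0.15, Dmax = 0.25
    expect_equal(dprime(c(40, 10, 10, 40))$value, 0.6)

    mono <- dprime(c(10, 0, 10, 0))
    expect_true(is.na(mono$value))
    expect_false(mono$informative)
    expect_false(dprime(c(2, 1, 0, 1), minInformative = 5)$informative)

    set.seed(11)
    for (i in 1:200) {
        tab <- rmultinom(1, sample(10:200, 1), prob = runif(4))[, 1]
        est <- dprime(tab)
        if (is.na(est$value)) {
            pA <- (tab[1] + tab[2]) / sum(tab)
            pB <- (tab[1] + tab[3]) / sum(tab)
            expect_true(pA %in% c(0, 1) || pB %in% c(0, 1))
        } else {
            expect_equal(est$value, dprime_oracle(tab), tolerance = 1e-12)
            expect_gte(est$value, 0)
            expect_lte(est$value, 1)
        }
    }
})

# two haplotype backgrounds in complete LD across the listed SNPs
ld_block_doses <- function(n_snps, n_acc = 40) {
    hap <- rep(c(0L, 2L), length.out = n_acc)
    matrix(rep(hap, each = n_snps), nrow = n_snps)
}

test_that("block partition groups tight LD and splits on weak LD or span", {
    # 3 SNPs, all pairwise D' = 1, span 5 kb -> one block
    gt <- make_gt(ld_block_doses(3), pos = c(1000, 3000, 6000))
    p <- partitionBlocks(gt)
    expect_equal(as.integer(p), c(1L, 1L, 1L))
    expect_equal(attr(p, "n_loci"), 1L)

    # independent SNPs -> all singletons
    set.seed(5)
    ind <- matrix(sample(c(0L, 2L), 4 * 40, replace = TRUE), nrow = 4)
    gt2 <- make_gt(ind, pos = c(1, 2, 3, 4) * 1000)
    p2 <- partitionBlocks(gt2, strongLd = 0.99)
    expect_equal(attr(p2, "n_loci"), 4L)

    # 3 SNPs in complete LD plus one unlinked -> block + singleton
    set.seed(7)
    weak <- sample(rep(c(0L, 2L), each = 20))
    gt3 <- make_gt(rbind(ld_block_doses(3), weak),
                   pos = c(1000, 2000, 3000, 4000))
    p3 <- partitionBlocks(gt3)
    expect_equal(as.integer(p3), c(1L, 1L, 1L, 2L))

    # identical SNPs too far apart cannot form a block
    gt4 <- make_gt(ld_block_doses(2), pos = c(1000, 250000))
    expect_equal(attr(partitionBlocks(gt4), "n_loci"), 2L)

    # partition is exhaustive and disjoint
    for (p_i in list(p, p2, p3)) {
        expect_false(anyNA(p_i))
        expect_true(all(diff(as.integer(p_i)) %in% c(0L, 1L)))
    }
})

test_that("haplotype calling reads alleles off homozygous calls", {
    # block of 2 SNPs; accessions 00, 00, 11
    dose <- matrix(c(0L, 0L, 0L, 0L, 2L, 2L), nrow = 2)
    gt <- make_gt(dose, pos = c(100, 200),
                  subpop = rep("P", 3))
    calls <- callHaplotypes(gt, partition = c(1L, 1L))
    expect_s4_class(calls, "SnpldbSet")
    cat1 <- alleleCatalogue(calls)[[1]]
    expect_setequal(cat1, c("00", "11"))
    expect_equal(cat1[1], "00")  # ordered by descending frequency
    expect_equal(unname(alleleCalls(calls)[1, ]), c("00", "00", "11"))

    # a het at one constituent SNP makes the locus call missing
    dose_het <- dose
    dose_het[1, 2] <- 1L
    gt_h <- make_gt(dose_het, pos = c(100, 200), subpop = rep("P", 3))
    calls_h <- callHaplotypes(gt_h, partition = c(1L, 1L))
    expect_true(is.na(alleleCalls(calls_h)[1, 2]))

    # locus id and coordinates span the constituent SNPs
    expect_equal(lociIds(calls), "Chr01:100-200")
})

test_that("rare haplotypes merge into the Hamming-nearest frequent allele", {
    # 200 accessions: "11" x 120, "00" x 79, "10" x 1 (freq 0.005)
    doses <- cbind(matrix(2L, 2, 120), matrix(0L, 2, 79), c(2L, 0L))
    gt <- make_gt(doses, pos = c(100, 200), subpop = rep("P", 200))
    calls <- callHaplotypes(gt, partition = c(1L, 1L), rareThreshold = 0.01)
    cat1 <- alleleCatalogue(calls)[[1]]
    expect_setequal(cat1, c("11", "00"))
    # "10" is Hamming distance 1 from "11" and 2 from "00" -> merged to "11"
    expect_equal(hamming_oracle("10", "11"), 1)
    expect_equal(unname(alleleCalls(calls)[1, 200]), "11")
    # merging never changes the non-missing call count
    expect_equal(sum(!is.na(alleleCalls(calls)[1, ])), 200)

    # merging can be disabled
    calls_nm <- callHaplotypes(gt, partition = c(1L, 1L), mergeRare = FALSE)
    expect_setequal(alleleCatalogue(calls_nm)[[1]], c("11", "00", "10"))
})

test_that("allele frequencies tally carriers per subpopulation", {
    # locus with alleles 0/1; WA: 3 of 10 carry "1"; LR: 0 of 8; one LR NA
    dose <- matrix(c(rep(2L, 3), rep(0L, 7), rep(0L, 7), NA), nrow = 1)
    gt <- make_gt(dose, pos = 500,
                  subpop = rep(c("WA", "LR"), c(10, 8)))
    calls <- callHaplotypes(gt, partition = 1L)
    fr <- alleleFrequencies(calls)
    expect_equal(attr(fr, "pops"), c("WA", "LR"))
    expect_equal(fr$WA[fr$allele == "1"], 0.30)
    expect_equal(fr$LR[fr$allele == "1"], 0.0)
    expect_equal(fr$n_LR, rep(7, 2))

    # per-(locus, subpopulation) frequencies sum to 1 when defined
    set.seed(9)
    sim <- simulateHistory(simConfig(nLoci = 20, seed = 3,
                                     sizes = c(30L, 40L, 30L)),
                           tempfile("sim"))
    gt2 <- readGenotypes(sim$paths$vcf)
    subpopulations(gt2) <- readManifest(sim$paths$manifest, gt2)
    fr2 <- alleleFrequencies(callHaplotypes(gt2, partitionBlocks(gt2)))
    for (p in attr(fr2, "pops")) {
        sums <- tapply(fr2[[p]], fr2$locus_id, sum)
        expect_true(all(abs(sums - 1) < 1e-12, na.rm = TRUE))
    }
    sums_all <- tapply(fr2$overall, fr2$locus_id, sum)
    expect_true(all(abs(sums_all - 1) < 1e-12))
    # frequency > 0 iff at least one carrier: universe alleles all observed
    expect_true(all(fr2$overall > 0))
})

test_that("a subpopulation with no non-missing calls is flagged undefined", {
    dose <- matrix(c(rep(0L, 3), rep(2L, 2), NA, NA), nrow = 1)
    gt <- make_gt(dose, pos = 100,
                  subpop = rep(c("A", "B"), c(5, 2)))
    fr <- alleleFrequencies(callHaplotypes(gt, partition = 1L))
    expect_true(all(is.na(fr$B)))
    expect_equal(fr$n_B, rep(0, 2))
    expect_false(anyNA(fr$A))
})
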
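test_that("clone correction keeps one representative per multilocus genotype", {
    set.seed(1)
    g <- randomPanel(18, 5, nAlleles = 4, missingRate = 0.05)
    # duplicate two samples (including their missing pattern)
    a1 <- cbind(alleleCalls(g, 1), alleleCalls(g, 1)[, c(3, 3)])
    a2 <- cbind(alleleCalls(g, 2), alleleCalls(g, 2)[, c(3, 3)])
    colnames(a1)[19:20] <- colnames(a2)[19:20] <- c("D1", "D2")
    g20 <- SsrGenotypes(a1, a2)
    cc <- cloneCorrect(g20)
    expect_identical(ncol(cc), 18L)
    expect_false(any(c("D1", "D2") %in% sampleIds(cc)))
    # all-distinct matrix is unchanged
    expect_identical(sampleIds(cloneCorrect(g)), sampleIds(g))
    # brute force: pairwise comparison of retained samples finds no clones
    keys <- mlgKeys(cc)
    for (i in seq_along(keys)) for (j in seq_len(i - 1))
        expect_false(keys[i] == keys[j])
})

test_that("clone correction retains first occurrences in input order", {
    g <- genoFromPairs(list(L1 = list(c(1, 2), c(3, 3), c(1, 2), c(3, 3), c(5, 6))))
    cc <- cloneCorrect(g)
    expect_identical(sampleIds(cc), c("S1", "S2", "S5"))
})

test_that("allele frequencies count copies over non-missing genotypes", {
    g <- locusFromCounts(list(pair = c(203, 203), n = 17),
                         list(pair = c(203, 205), n = 2))
    sp <- alleleFrequencies(g, "L1")
    expect_identical(sp@n, 19L)
    expect_equal(unname(sp@freqs), c(36 / 38, 2 / 38))
    # single heterozygote
    g1 <- genoFromPairs(list(L1 = list(c(1, 2))))
    expect_equal(unname(alleleFrequencies(g1, "L1")@freqs), c(0.5, 0.5))
    # invariant under sample reordering
    set.seed(3)
    g2 <- randomPanel(12, 1, missingRate = 0.1)
    perm <- sample(ncol(g2))
    expect_equal(sort(alleleFrequencies(g2[, perm], "L1")@freqs),
                 sort(alleleFrequencies(g2, "L1")@freqs))
    # entirely-missing locus signals an empty-locus condition
    gm <- genoFromPairs(list(L1 = list(NA, NA)))
    expect_error(alleleFrequencies(gm, "L1"), "no genotyped samples")
})

test_that("Shannon index matches closed forms and the worked example", {
    mono <- alleleFrequencies(genoFromPairs(list(L = list(c(7, 7), c(7, 7)))), "L")
    expect_identical(shannonIndex(mono), 0)
    four <- locusFromCounts(list(pair = c(1, 2), n = 1), list(pair = c(3, 4), n = 1))
    expect_equal(shannonIndex(alleleFrequencies(four, "L1")), log(4))
    skew <- locusFromCounts(list(pair = c(203, 203), n = 17),
                            list(pair = c(203, 205), n = 2))
    expect_equal(round(shannonIndex(alleleFrequencies(skew, "L1")), 2), 0.21)
})

test_that("observed heterozygosity is the het fraction of genotyped samples", {
    g <- locusFromCounts(list(pair = c(203, 203), n = 17),
                         list(pair = c(203, 205), n = 2))
    expect_equal(round(observedHet(g, "L1"), 2), 0.11)
    hom <- genoFromPairs(list(L = list(c(1, 1), c(2, 2), c(3, 3))))
    expect_identical(observedHet(hom, "L"), 0)
    het16 <- locusFromCounts(list(pair = c(1, 2), n = 16), list(pair = c(1, 1), n = 3))
    expect_equal(round(observedHet(het16, "L1"), 2), 0.84)
})

test_that("expected heterozygosity uses Nei's unbiased correction", {
    mono <- alleleFrequencies(genoFromPairs(list(L = list(c(7, 7), c(7, 7)))), "L")
    expect_identical(expectedHet(mono), 0)
    # single heterozygote: estimator upper edge (2/1) * (1 - 0.5) = 1
    one <- alleleFrequencies(genoFromPairs(list(L = list(c(1, 2)))), "L")
    expect_identical(expectedHet(one), 1)
    # 12 + 7 opposite homozygotes of 19
    g <- locusFromCounts(list(pair = c(203, 203), n = 12),
                         list(pair = c(205, 205), n = 7))
    expect_equal(round(expectedHet(alleleFrequencies(g, "L1")), 2), 0.48)
})

test_that("He equals the draw-two-without-replacement enumeration oracle", {
    set.seed(11)
    for (rep in 1:20) {
        K <- sample(2:5, 1)
        counts <- as.vector(rmultinom(1, size = 2 * sample(5:15, 1),
                                      prob = runif(K) + 0.1))
        counts <- counts[counts > 0]
        if (sum(counts) %% 2 == 1) counts[1] <- counts[1] + 1
        copies <- rep(seq_along(counts), counts)
        n <- length(copies) / 2
        spec <- new("AlleleSpectrum", locusId = "L", n = as.integer(n),
                    counts = as.integer(counts),
                    freqs = counts / sum(counts))
        expect_equal(expectedHet(spec), oracleHe(copies), tolerance = 1e-12)
    }
})

test_that("diversity indices are invariant under allele relabeling", {
    set.seed(21)
    g <- randomPanel(15, 1, nAlleles = 4)
    sp <- alleleFrequencies(g, "L1")
    # relabel alleles by an arbitrary strictly increasing map
    a1 <- alleleCalls(g, 1) * 3L + 7L
    a2 <- alleleCalls(g, 2) * 3L + 7L
    g2 <- SsrGenotypes(a1, a2)
    sp2 <- alleleFrequencies(g2, "L1")
    expect_equal(shannonIndex(sp2), shannonIndex(sp))
    expect_equal(expectedHet(sp2), expectedHet(sp))
    expect_equal(observedHet(g2, "L1"), observedHet(g, "L1"))
})

test_that("He estimates recover the generating diversity on large panels", {
    p <- c("100" = 0.5, "102" = 0.3, "104" = 0.2)
    sim <- simulateGenotypes(500, list(L1 = p), seed = 404)
    sp <- alleleFrequencies(sim$genotypes, "L1")
    n <- sp@n
    target <- (2 * n / (2 * n - 1)) * (1 - sum(p^2))
    se <- sqrt(sum(p^2) * (1 - sum(p^2)) / (2 * n))  # rough binomial scale
    expect_lt(abs(expectedHet(sp) - target), 2 * 2 * se)
})

test_that("percent missing matches the printed arithmetic", {
    mk <- function(nMiss) {
        pairs <- c(rep(list(c(1, 1)), 19 - nMiss), rep(list(NA), nMiss))
        genoFromPairs(list(L1 = pairs))
    }
    expect_equal(round(percentMissing(mk(1), "L1"), 2), 5.26)
    expect_equal(round(percentMissing(mk(0), "L1"), 2), 0.00)
    expect_equal(round(percentMissing(mk(4), "L1"), 2), 21.05)
})

test_that("summaries carry per-locus rows plus an unweighted mean row", {
    g <- genoFromPairs(list(
        L1 = list(c(1, 1), c(1, 2), c(2, 2), c(1, 1)),
        L2 = list(c(5, 5), c(5, 5), NA, c(5, 7))))
    s <- summarizeLoci(g)
    expect_identical(s$locus, c("L1", "L2", "Mean"))
    expect_equal(s$N[3], mean(s$N[1:2]))
    expect_equal(s$Ho[3], mean(s$Ho[1:2]))
    expect_equal(attr(s, "overallMissingPct"), 100 * 1 / 8)
    expect_identical(attr(s, "totalAlleles"), 4L)
    # single-locus matrix: mean row equals the locus row
    s1 <- summarizeLoci(g[1, ])
    expect_equal(unlist(s1[2, -1]), unlist(s1[1, -1]), ignore_attr = TRUE)
})
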
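test_that("per-locus pair distances take the codominant 0/0.5/1 values", {
    g <- genoFromPairs(list(L = list(c(203, 205), c(203, 205), c(203, 203),
                                     c(201, 207), NA)))
    d <- locusDistances(g, "L")
    # pair order follows combn(5, 2): (1,2) identical, (1,3) one shared, ...
    expect_identical(d[1], 0)
    expect_identical(d[2], 0.5)
    expect_identical(d[3], 1)
    expect_true(all(is.na(d[c(4, 7, 9, 10)])))
    expect_error(locusDistances(g[, 1], "L"), "2 samples")
})

test_that("pair distances equal the multiset-intersection oracle", {
    set.seed(55)
    for (rep in 1:100) {
        g <- randomPanel(sample(4:8, 1), 1, nAlleles = sample(2:4, 1),
                         missingRate = 0.1)
        d <- locusDistances(g, "L1")
        a1 <- alleleCalls(g, 1); a2 <- alleleCalls(g, 2)
        cb <- combn(ncol(g), 2)
        for (k in seq_len(ncol(cb))) {
            i <- cb[1, k]; j <- cb[2, k]
            if (is.na(a1[1, i]) || is.na(a1[1, j])) {
                expect_true(is.na(d[k]))
            } else {
                expect_identical(d[k], oracleDist(c(a1[1, i], a2[1, i]),
                                                  c(a1[1, j], a2[1, j])))
            }
        }
    }
})

test_that("a locus paired with its exact duplicate gives rbarD = 1", {
    set.seed(8)
    g <- randomPanel(20, 1, nAlleles = 3)
    a1 <- alleleCalls(g, 1); a2 <- alleleCalls(g, 2)
    gdup <- SsrGenotypes(rbind(A = a1[1, ], B = a1[1, ]),
                         rbind(A = a2[1, ], B = a2[1, ]))
    r <- rbarD(gdup)
    expect_equal(r@rbarD, 1)
    expect_gt(r@IA, 0)
})

test_that("rbarD and IA equal the brute-force pair-distance oracle", {
    set.seed(123)
    tried <- 0
    while (tried < 20) {
        g <- randomPanel(sample(5:8, 1), sample(2:4, 1),
                         nAlleles = sample(2:3, 1), missingRate = 0.08)
        res <- tryCatch(rbarD(g), error = function(e) NULL)
        if (is.null(res)) next     # degenerate draw (zero variance)
        tried <- tried + 1
        orc <- oracleRbarD(g)
        expect_equal(res@rbarD, orc$rbarD, tolerance = 1e-12)
        expect_equal(res@IA, orc$IA, tolerance = 1e-12)
        expect_identical(res@nPairs, as.integer(orc$nPairs))
    }
})

test_that("zero distance variance is signalled, never reported as zero", {
    g <- genoFromPairs(list(
        mono = list(c(1, 1), c(1, 1), c(1, 1), c(1, 1)),
        poly = list(c(2, 4), c(2, 2), c(4, 4), c(2, 4))))
    expect_error(rbarD(g), class = "ssrZeroVarianceError")
    pw <- pairwiseRbarD(g)
    expect_true(is.na(pw["mono", "poly"]))
    expect_identical(attr(pw, "undefined"), "mono:poly")
})

test_that("independent loci give rbarD near zero on average", {
    set.seed(61)
    vals <- replicate(200, {
        sim <- simulateGenotypes(50, list(
            L1 = c("100" = 0.5, "102" = 0.5),
            L2 = c("200" = 0.5, "204" = 0.5)))
        tryCatch(rbarD(sim$genotypes)@rbarD, error = function(e) NA_real_)
    })
    vals <- vals[!is.na(vals)]
    se <- sd(vals) / sqrt(length(vals))
    expect_lt(abs(mean(vals)), 3 * se + 0.01)
})

test_that("rbarD is invariant under allele relabeling within loci", {
    set.seed(77)
    g <- randomPanel(12, 3, nAlleles = 3)
    r1 <- rbarD(g)@rbarD
    g2 <- SsrGenotypes(alleleCalls(g, 1) * 2L + 11L,
                       alleleCalls(g, 2) * 2L + 11L)
    expect_equal(rbarD(g2)@rbarD, r1)
})

test_that("pairwise table is symmetric, consistent and order-invariant", {
    set.seed(91)
    g <- randomPanel(15, 3, nAlleles = 3)
    pw <- pairwiseRbarD(g)
    expect_identical(pw, t(pw), ignore_attr = TRUE)
    expect_true(all(is.na(diag(pw))))
    # two-locus matrix: single off-diagonal equals rbarD directly
    expect_equal(pw["L1", "L2"], rbarD(g, c("L1", "L2"))@rbarD)
    # locus reordering permutes the table
    perm <- c(3, 1, 2)
    pw2 <- pairwiseRbarD(g[perm, ])
    expect_equal(pw2[rownames(pw), colnames(pw)], pw, ignore_attr = TRUE)
})

test_that("a planted duplicated locus stands out in the pairwise table", {
    set.seed(14)
    sim <- simulateGenotypes(60, list(
        A = c("100" = 0.4, "102" = 0.3, "104" = 0.3),
        B = c("200" = 0.4, "202" = 0.3, "204" = 0.3),
        C = c("300" = 0.5, "302" = 0.5)),
        linkedPairs = list(list("A", "B", 1.0)))
    pw <- pairwiseRbarD(sim$genotypes)
    expect_equal(pw["A", "B"], 1)
    expect_lt(abs(pw["A", "C"]), 0.3)
    expect_lt(abs(pw["B", "C"]), 0.3)
})

test_that("the permutation test is seeded, reproducible and calibrated", {
    set.seed(33)
    g <- randomPanel(12, 2, nAlleles = 3)
    p1 <- ldPermutationTest(g, nPerm = 99, seed = 7)@pValue
    p2 <- ldPermutationTest(g, nPerm = 99, seed = 7)@pValue
    expect_identical(p1, p2)
    expect_gte(p1, 1 / 100)
    expect_error(ldPermutationTest(g, nPerm = 0), "nPerm")
})

test_that("a duplicated locus pair reaches the minimal permutation p-value", {
    set.seed(19)
    g <- randomPanel(20, 1, nAlleles = 4)
    gdup <- SsrGenotypes(rbind(A = alleleCalls(g, 1)[1, ], B = alleleCalls(g, 1)[1, ]),
                         rbind(A = alleleCalls(g, 2)[1, ], B = alleleCalls(g, 2)[1, ]))
    res <- ldPermutationTest(gdup, nPerm = 999, seed = 5)
    expect_equal(res@pValue, 1 / 1000)
})

test_that("LD tables are written in long format", {
    set.seed(44)
    g <- randomPanel(10, 3, nAlleles = 3)
    pw <- pairwiseRbarD(g)
    tsv <- withr::local_tempfile(fileext = ".tsv")
    writeLdTable(pw, tsv)
    df <- read.delim(tsv)
    expect_identical(nrow(df), 3L)
    expect_identical(colnames(df), c("locus_a", "locus_b", "rbar_d", "p_value"))
    expect_equal(df$rbar_d[df$locus_a == "L1" & df$locus_b == "L2"], pw["L1", "L2"])
})
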
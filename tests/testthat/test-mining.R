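test_that("canonical motif classes collapse rotation and strand", {
    expect_identical(canonicalMotif("TA"), "AT")
    expect_identical(canonicalMotif("AT"), "AT")
    expect_identical(canonicalMotif("GA"), "AG")
    # brute force: all 12 valid (non-homopolymer) dinucleotides fall into
    # exactly the four classes
    dinucs <- apply(expand.grid(c("A","C","G","T"), c("A","C","G","T")), 1, paste0, collapse = "")
    dinucs <- dinucs[substr(dinucs, 1, 1) != substr(dinucs, 2, 2)]
    expect_length(dinucs, 12)
    expect_setequal(unique(canonicalMotif(dinucs)), c("AC", "AG", "AT", "CG"))
    expect_error(canonicalMotif("ATX"), "motif")
    expect_error(canonicalMotif("A"), "motif")
})

test_that("maximal perfect runs are mined at the repeat-count thresholds", {
    gr <- findSSRs(c(s1 = paste0("CC", strrep("AT", 6), "GG")))
    expect_length(gr, 1)
    expect_identical(gr$motif, "AT")
    expect_identical(gr$repeatCount, 6L)
    expect_identical(GenomicRanges::width(gr), 12L)
    # below threshold: 5 copies of a dinucleotide is not reported
    expect_length(findSSRs(c(s1 = paste0("CCGGC", strrep("AT", 5), "GGCCG"))), 0)
    # tetra threshold is 4
    expect_length(findSSRs(c(s1 = paste0("G", strrep("AAAT", 4), "C"))), 1)
})

test_that("partial trailing unit copies are ignored", {
    gr <- findSSRs(c(s1 = paste0("CC", strrep("AT", 6), "ACC")))
    expect_identical(gr$repeatCount, 6L)
    expect_identical(GenomicRanges::end(gr), 14L)  # full copies only
})

test_that("runs are reported once under their shortest period", {
    gr <- findSSRs(c(s1 = paste0("GC", strrep("AT", 12), "CG")))
    expect_length(gr, 1)
    expect_identical(gr$motifLength, 2L)
    expect_identical(gr$repeatCount, 12L)
    # homopolymers are never motifs
    expect_length(findSSRs(c(s1 = strrep("A", 40))), 0)
})

test_that("masked bases break runs", {
    clean <- paste0("CC", strrep("AT", 8), "GG")
    gr <- findSSRs(c(s1 = clean))
    expect_length(gr, 1)
    # lowercase one base inside the run
    chars <- strsplit(clean, "")[[1]]
    chars[9] <- tolower(chars[9])
    masked <- paste(chars, collapse = "")
    hits <- findSSRs(c(s1 = masked))
    expect_true(all(hits$repeatCount < 8))
    # N also breaks
    chars[9] <- "N"
    hits2 <- findSSRs(c(s1 = paste(chars, collapse = "")))
    expect_true(all(hits2$repeatCount < 8))
})

test_that("mining recovers planted SSRs exactly with no spurious calls", {
    sim <- simulateGenome(nScaffolds = 20, scaffoldLen = 2000,
                          spec = ssrSpec(compoundFraction = 0.25,
                                         maskedFraction = 0.05,
                                         perScaffold = 5),
                          seed = 101)
    mined <- flagCompound(findSSRs(sim$scaffolds))
    expect_identical(length(mined), length(sim$truth))
    expect_identical(GenomicRanges::start(mined), GenomicRanges::start(sim$truth))
    expect_identical(GenomicRanges::end(mined), GenomicRanges::end(sim$truth))
    expect_identical(mined$motif, sim$truth$motif)
    expect_identical(mined$repeatCount, sim$truth$repeatCount)
    expect_identical(mined$compound, sim$truth$compound)
})

test_that("compound flagging uses a strict 15 bp gap with chaining", {
    mk <- function(gaps) {
        # plant AT6 / AAG6 / AAAT4 alternating, separated by the given gaps
        motifs <- c("AT", "AAG", "AAAT")
        counts <- c(6, 6, 4)
        seq <- "GG"
        for (i in seq_along(gaps)) {
            seq <- paste0(seq, strrep(motifs[(i - 1) %% 3 + 1], counts[(i - 1) %% 3 + 1]),
                          strrep("C", gaps[i]))
        }
        seq <- paste0(seq, strrep(motifs[(length(gaps)) %% 3 + 1],
                                  counts[(length(gaps)) %% 3 + 1]), "GG")
        findSSRs(c(s = seq))
    }
    two10 <- flagCompound(mk(10))
    expect_identical(two10$compound, c(TRUE, TRUE))
    two15 <- flagCompound(mk(15))
    expect_identical(two15$compound, c(FALSE, FALSE))
    chain <- flagCompound(mk(c(5, 5)))
    expect_identical(chain$compound, c(TRUE, TRUE, TRUE))
    # unsorted input is refused
    expect_error(flagCompound(rev(mk(10))), "sorted")
})

test_that("motif tabulation conserves counts and is strand-symmetric", {
    empty <- tabulateMotifs(findSSRs(c(s = "ACGTT")))
    expect_true(all(empty$byLength$count == 0))
    seq <- paste0("GG", strrep("AT", 6), strrep("C", 30), strrep("TA", 7),
                  strrep("G", 25), strrep("AT", 8), strrep("C", 30),
                  strrep("AG", 6), strrep("T", 25), strrep("GA", 9), "CC")
    gr <- findSSRs(c(s = seq))
    tab <- tabulateMotifs(gr)
    expect_identical(sum(tab$byClass$count), length(gr))
    expect_identical(tab$byLength$count[tab$byLength$motif_length == 2], 5L)
    expect_identical(tab$byClass$count[tab$byClass$canonical_class == "AT"], 3L)
    expect_identical(tab$byClass$count[tab$byClass$canonical_class == "AG"], 2L)
    # per-length totals equal the sum of their class counts
    agg <- aggregate(count ~ motif_length, tab$byClass, sum)
    expect_identical(agg$count,
                     tab$byLength$count[tab$byLength$count > 0])
    # mining the reverse complement yields identical canonical class counts
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
    tabRC <- tabulateMotifs(findSSRs(c(s = rc)))
    expect_identical(tabRC$byClass, tab$byClass)
})

test_that("mined catalogs are deterministic and loci satisfy invariants", {
    sim <- simulateGenome(nScaffolds = 6, scaffoldLen = 1500, seed = 5)
    f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
    writeSsrCatalog(flagCompound(findSSRs(sim$scaffolds)), f1)
    writeSsrCatalog(flagCompound(findSSRs(sim$scaffolds)), f2)
    expect_identical(readLines(f1), readLines(f2))
    gr <- findSSRs(sim$scaffolds)
    expect_true(all(GenomicRanges::width(gr) == gr$motifLength * gr$repeatCount))
    expect_true(all(gr$repeatCount >= ifelse(gr$motifLength == 4, 4L, 6L)))
    expect_true(all(nchar(gr$motif) == gr$motifLength))
})

test_that("class frequencies in a planted genome match planted proportions", {
    spec <- ssrSpec(motifs = c("AT", "AC"), weights = c(0.8, 0.2),
                    perScaffold = 5)
    sim <- simulateGenome(nScaffolds = 40, scaffoldLen = 2500, spec = spec,
                          seed = 77)
    tab <- tabulateMotifs(findSSRs(sim$scaffolds))
    n <- sum(tab$byClass$count)
    pAT <- tab$byClass$count[tab$byClass$canonical_class == "AT"] / n
    se <- sqrt(0.8 * 0.2 / n)
    expect_lt(abs(pAT - 0.8), 3.5 * se)
})
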
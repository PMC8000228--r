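#' Specification for planting SSRs in simulated scaffolds
#'
#' @param motifs character vector of repeat units to plant (primitive, 2-4 bp)
#' @param weights sampling weights over `motifs` (default uniform)
#' @param repeatRange named list mapping motif length (`"2"`, `"3"`, `"4"`) to
#'   an inclusive repeat-count range; defaults honour the mining thresholds
#'   (at least 6 copies for di/tri, 4 for tetra)
#' @param perScaffold number of planting events per scaffold
#' @param compoundFraction probability that a planting event is a compound
#'   pair (two SSRs separated by fewer than 15 bp) instead of a single SSR
#' @param maskedFraction approximate fraction of inter-SSR background to
#'   soft-mask (lowercase)
#' @return a list consumed by [simulateGenome()]
#' @export
ssrSpec <- function(motifs = c("AT", "AC", "AG", "AAT", "AAG", "AAAT", "ATCC"),
                    weights = NULL,
                    repeatRange = list("2" = c(6L, 12L), "3" = c(6L, 10L),
                                       "4" = c(4L, 8L)),
                    perScaffold = 2L,
                    compoundFraction = 0,
                    maskedFraction = 0) {
    stopifnot(all(grepl("^[ACGT]{2,4}$", motifs)))
    if (!all(vapply(motifs, .isPrimitive, TRUE)))
        stop("planted motifs must be primitive (not repeats of a shorter unit)")
    if (is.null(weights)) weights <- rep(1, length(motifs))
    repeatRange <- lapply(repeatRange, as.integer)
    list(motifs = motifs, weights = weights, repeatRange = repeatRange,
         perScaffold = as.integer(perScaffold),
         compoundFraction = compoundFraction,
         maskedFraction = maskedFraction)
}

#' Simulate scaffolds with planted perfect SSRs
#'
#' Background sequence is i.i.d. uniform over `{A,C,G,T}` (GC = 0.5, which
#' keeps accidental repeats rare). Planted SSRs are non-overlapping, each
#' separated from its neighbours by at least 20 bp unless deliberately
#' planted as a compound pair (gap below 15 bp), and are protected by guard
#' bases so a planted run can neither extend nor shift phase into the
#' background. Optional soft-masked stretches (lowercase) are placed in
#' inter-SSR background only.
#'
#' @param nScaffolds number of scaffolds
#' @param scaffoldLen length of each scaffold (bp)
#' @param spec planting specification from [ssrSpec()]
#' @param seed integer seed; fully determines the output
#' @return list with `scaffolds` (a named [Biostrings::BStringSet]) and
#'   `truth` (a [GenomicRanges::GRanges] of the planted loci in
#'   [findSSRs()] catalog form, compound flags set)
#' @export
simulateGenome <- function(nScaffolds = 5L, scaffoldLen = 2000L,
                           spec = ssrSpec(), seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    maxUnit <- max(vapply(names(spec$repeatRange), function(m)
        as.integer(m) * spec$repeatRange[[m]][2], numeric(1)))
    worst <- spec$perScaffold * (2L * maxUnit + 14L + 2L + 20L) + 22L
    if (worst > scaffoldLen)
        stop("infeasible packing: ", spec$perScaffold,
             " planting events do not fit in ", scaffoldLen, " bp")
    seqs <- character(nScaffolds)
    truth <- list()
    for (i in seq_len(nScaffolds)) {
        id <- sprintf("scf%03d", i)
        chars <- sample(c("A", "C", "G", "T"), scaffoldLen, replace = TRUE)
        cursor <- 21L
        planted <- list()
        for (ev in seq_len(spec$perScaffold)) {
            pair <- stats::runif(1) < spec$compoundFraction
            nUnits <- if (pair) 2L else 1L
            units <- list()
            for (u in seq_len(nUnits)) {
                motif <- sample(spec$motifs, 1, prob = spec$weights)
                m <- nchar(motif)
                rng <- spec$repeatRange[[as.character(m)]]
                count <- rng[1] + sample.int(rng[2] - rng[1] + 1L, 1) - 1L
                units[[u]] <- list(motif = motif, m = m, count = count,
                                   len = m * count)
            }
            gap <- if (pair) sample(2:14, 1) else 0L
            evLen <- sum(vapply(units, `[[`, 0L, "len")) + gap
            # random spacing >= 20 bp from the previous plant
            cursor <- cursor + 20L + sample(0:20, 1)
            if (cursor + evLen + 1L > scaffoldLen)
                stop("infeasible packing on scaffold ", id)
            at <- cursor
            for (u in seq_len(nUnits)) {
                un <- units[[u]]
                runChars <- strsplit(strrep(un$motif, un$count), "")[[1]]
                chars[at:(at + un$len - 1L)] <- runChars
                # guards: left base must not extend the run's phase leftwards,
                # right base must not append another unit character
                lg <- setdiff(c("A", "C", "G", "T"),
                              substr(un$motif, un$m, un$m))[1]
                rg <- setdiff(c("A", "C", "G", "T"),
                              substr(un$motif, 1, 1))[1]
                chars[at - 1L] <- lg
                chars[at + un$len] <- rg
                planted[[length(planted) + 1L]] <- data.frame(
                    start = at, end = at + un$len - 1L, motif = un$motif,
                    m = un$m, count = un$count)
                at <- at + un$len + if (u < nUnits) gap else 0L
            }
            cursor <- at + 1L
        }
        pl <- if (length(planted)) do.call(rbind, planted) else NULL
        if (spec$maskedFraction > 0) {
            free <- rep(TRUE, scaffoldLen)
            if (!is.null(pl)) for (r in seq_len(nrow(pl)))
                free[max(1, pl$start[r] - 1L):min(scaffoldLen, pl$end[r] + 1L)] <- FALSE
            target <- round(spec$maskedFraction * scaffoldLen)
            freeIdx <- which(free)
            if (length(freeIdx) && target > 0) {
                pick <- sort(sample(freeIdx, min(target, length(freeIdx))))
                chars[pick] <- tolower(chars[pick])
            }
        }
        seqs[i] <- paste(chars, collapse = "")
        if (!is.null(pl)) {
            pl$scaffold <- id
            truth[[length(truth) + 1L]] <- pl
        }
    }
    scaffolds <- BStringSet(seqs)
    names(scaffolds) <- sprintf("scf%03d", seq_len(nScaffolds))
    tdf <- if (length(truth)) do.call(rbind, truth) else NULL
    if (is.null(tdf)) {
        gr <- findSSRs(character(0))  # empty catalog shape
    } else {
        tdf <- tdf[order(tdf$scaffold, tdf$start), ]
        gr <- GRanges(tdf$scaffold, IRanges(tdf$start, tdf$end))
        gr$motif <- tdf$motif
        gr$canonicalClass <- canonicalMotif(tdf$motif)
        gr$motifLength <- as.integer(tdf$m)
        gr$repeatCount <- as.integer(tdf$count)
        gr$compound <- FALSE
        gr <- flagCompound(gr)
    }
    list(scaffolds = scaffolds, truth = gr)
}

#' Simulate a diploid genotype panel from known allele frequencies
#'
#' Genotypes are drawn per locus from Hardy-Weinberg proportions adjusted by
#' an inbreeding-style heterozygote-deficit parameter `fis`: with probability
#' `fis` one allele is drawn and duplicated (forcing a homozygote), otherwise
#' two copies are drawn independently. Loci are independent unless listed in
#' `linkedPairs`, where the second locus copies the first locus's genotype
#' draw (mapped through the allele-index correspondence) with the stated
#' probability — planting a linkage-disequilibrium signal without modelling
#' recombination. Entries are set missing i.i.d. at `missingRate`.
#'
#' @param nSamples number of diploid samples
#' @param freqSpec named list: locus id -> named numeric vector of allele
#'   frequencies (names are integer allele labels, values sum to 1)
#' @param fis heterozygote-deficit parameter in \[0, 1\] (default 0 = HWE)
#' @param missingRate per-cell missing probability in \[0, 1)
#' @param linkedPairs optional list of `list(a, b, rho)` entries: locus `b`
#'   copies locus `a`'s draw with probability `rho`; allele indices wrap when
#'   the two loci have different allele counts
#' @param seed integer seed; fully determines the output
#' @return list with `genotypes` (an \linkS4class{SsrGenotypes}) and `truth`
#'   (the generating parameters plus the pre-missingness genotype matrix)
#' @export
simulateGenotypes <- function(nSamples, freqSpec, fis = 0, missingRate = 0,
                              linkedPairs = NULL, seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    stopifnot(nSamples >= 1, fis >= 0, fis <= 1,
              missingRate >= 0, missingRate < 1)
    for (lc in names(freqSpec)) {
        p <- freqSpec[[lc]]
        if (abs(sum(p) - 1) > 1e-8 || any(p < 0))
            stop("allele frequencies at locus ", lc, " must be a distribution")
        if (is.null(names(p)))
            stop("allele frequencies at locus ", lc, " must be named by label")
    }
    loci <- names(freqSpec)
    copyFrom <- setNames(rep(NA_character_, length(loci)), loci)
    copyRho <- setNames(rep(0, length(loci)), loci)
    for (lp in linkedPairs) {
        a <- as.character(lp[[1]]); b <- as.character(lp[[2]])
        stopifnot(a %in% loci, b %in% loci)
        copyFrom[b] <- a
        copyRho[b] <- lp[[3]]
    }
    idx1 <- idx2 <- matrix(0L, length(loci), nSamples,
                           dimnames = list(loci, NULL))
    for (lc in loci) {
        p <- freqSpec[[lc]]
        K <- length(p)
        hom <- stats::runif(nSamples) < fis
        i1 <- sample.int(K, nSamples, replace = TRUE, prob = p)
        i2 <- ifelse(hom, i1, sample.int(K, nSamples, replace = TRUE, prob = p))
        if (!is.na(copyFrom[lc])) {
            src <- copyFrom[lc]
            take <- stats::runif(nSamples) < copyRho[lc]
            # allele-index correspondence wraps when the two loci have
            # different allele counts
            i1[take] <- (idx1[src, take] - 1L) %% K + 1L
            i2[take] <- (idx2[src, take] - 1L) %% K + 1L
        }
        idx1[lc, ] <- i1
        idx2[lc, ] <- i2
    }
    a1 <- a2 <- matrix(NA_integer_, length(loci), nSamples,
                       dimnames = list(loci, paste0("S", seq_len(nSamples))))
    for (lc in loci) {
        labels <- as.integer(names(freqSpec[[lc]]))
        a1[lc, ] <- labels[idx1[lc, ]]
        a2[lc, ] <- labels[idx2[lc, ]]
    }
    full <- SsrGenotypes(a1, a2)
    if (missingRate > 0) {
        drop <- matrix(stats::runif(length(a1)) < missingRate, nrow(a1))
        a1[drop] <- NA_integer_
        a2[drop] <- NA_integer_
    }
    list(genotypes = SsrGenotypes(a1, a2),
         truth = list(freqSpec = freqSpec, fis = fis,
                      missingRate = missingRate, linkedPairs = linkedPairs,
                      fullGenotypes = full, seed = seed))
}

#' Simulate raw fragment sizes from a genotype panel
#'
#' Emulates capillary-electrophoresis sizing: each allele copy's measured
#' size is `offset + label + Gaussian(0, noiseSd)`, with independent noise
#' draws for the two copies of a homozygote. Missing genotypes stay missing.
#'
#' @param genotypes an \linkS4class{SsrGenotypes} (the sizing truth)
#' @param offsets named numeric vector: per-locus sizing offset in bp
#'   (fractional drift off the integer grid); default 0 for every locus
#' @param noiseSd Gaussian sizing noise standard deviation in bp (>= 0)
#' @param seed integer seed
#' @return a \linkS4class{RawSizePanel}
#' @export
simulateFragmentSizes <- function(genotypes, offsets = NULL, noiseSd = 0.25,
                                  seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    stopifnot(is(genotypes, "SsrGenotypes"), noiseSd >= 0)
    loci <- rownames(genotypes)
    if (is.null(offsets)) offsets <- setNames(rep(0, length(loci)), loci)
    stopifnot(all(loci %in% names(offsets)))
    a1 <- assay(genotypes, "a1"); a2 <- assay(genotypes, "a2")
    off <- matrix(offsets[loci], nrow(a1), ncol(a1))
    s1 <- off + a1 + matrix(stats::rnorm(length(a1), 0, noiseSd), nrow(a1))
    s2 <- off + a2 + matrix(stats::rnorm(length(a2), 0, noiseSd), nrow(a2))
    s1[is.na(a1)] <- NA_real_
    s2[is.na(a2)] <- NA_real_
    dimnames(s1) <- dimnames(s2) <- dimnames(a1)
    RawSizePanel(s1, s2)
}
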
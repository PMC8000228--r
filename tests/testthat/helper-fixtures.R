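# Shared fixture builders and independent brute-force oracles.
# Oracles are written as plain enumerations, independent of the package's
# vectorized implementations.

# Build an SsrGenotypes from a list: locus id -> list of length-2 allele
# vectors (or NA for missing), one per sample.
genoFromPairs <- function(pairs) {
    loci <- names(pairs)
    ns <- length(pairs[[1]])
    a1 <- a2 <- matrix(NA_integer_, length(loci), ns,
                       dimnames = list(loci, paste0("S", seq_len(ns))))
    for (i in seq_along(loci)) {
        for (s in seq_len(ns)) {
            p <- pairs[[i]][[s]]
            if (length(p) == 1 && is.na(p)) next
            a1[i, s] <- as.integer(min(p))
            a2[i, s] <- as.integer(max(p))
        }
    }
    SsrGenotypes(a1, a2)
}

# One locus built from genotype counts, e.g. list(c(203, 203) = 17, ...)
locusFromCounts <- function(..., locusId = "L1") {
    specs <- list(...)
    pairs <- list()
    for (sp in specs) pairs <- c(pairs, rep(list(sp$pair), sp$n))
    g <- list(pairs)
    names(g) <- locusId
    genoFromPairs(g)
}

# Oracle: shared allele copies between two unordered diploid pairs, via
# explicit multiset intersection.
oracleShared <- function(p1, p2) {
    shared <- 0
    left <- p2
    for (a in p1) {
        hit <- match(a, left)
        if (!is.na(hit)) {
            shared <- shared + 1
            left <- left[-hit]
        }
    }
    shared
}

oracleDist <- function(p1, p2) (2 - oracleShared(p1, p2)) / 2

# Oracle: unbiased gene diversity by enumerating every unordered pair of
# distinct allele copies and counting unequal draws.
oracleHe <- function(copies) {
    n <- length(copies)
    diff <- 0; tot <- 0
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
        tot <- tot + 1
        if (copies[i] != copies[j]) diff <- diff + 1
    }
    diff / tot
}

# Oracle: I_A and rbarD by building the full pair-distance table with
# explicit double loops (population variances/covariances).
oracleRbarD <- function(x, loci = rownames(x)) {
    a1 <- alleleCalls(x, 1); a2 <- alleleCalls(x, 2)
    n <- ncol(x)
    rows <- list()
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
        d <- numeric(length(loci))
        ok <- TRUE
        for (l in seq_along(loci)) {
            lc <- loci[l]
            if (is.na(a1[lc, i]) || is.na(a1[lc, j])) { ok <- FALSE; break }
            d[l] <- oracleDist(c(a1[lc, i], a2[lc, i]),
                               c(a1[lc, j], a2[lc, j]))
        }
        if (ok) rows[[length(rows) + 1]] <- d
    }
    D <- do.call(rbind, rows)
    popvar <- function(v) mean(v^2) - mean(v)^2
    popcov <- function(u, v) mean(u * v) - mean(u) * mean(v)
    varJ <- apply(D, 2, popvar)
    VO <- popvar(rowSums(D))
    VE <- sum(varJ)
    sumCov <- 0; sumSd <- 0
    L <- ncol(D)
    for (j in seq_len(L - 1)) for (k in (j + 1):L) {
        sumCov <- sumCov + popcov(D[, j], D[, k])
        sumSd <- sumSd + sqrt(varJ[j] * varJ[k])
    }
    list(IA = VO / VE - 1, rbarD = sumCov / sumSd, nPairs = nrow(D))
}

# Random small genotype panel for property tests (no missing unless asked).
randomPanel <- function(nSamples, nLoci, nAlleles = 3, missingRate = 0) {
    pairs <- list()
    for (l in seq_len(nLoci)) {
        labels <- 100L * l + 2L * (seq_len(nAlleles) - 1L)
        col <- lapply(seq_len(nSamples), function(s) {
            if (missingRate > 0 && runif(1) < missingRate) return(NA)
            sample(labels, 2, replace = TRUE)
        })
        pairs[[paste0("L", l)]] <- col
    }
    genoFromPairs(pairs)
}
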
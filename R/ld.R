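#' Per-locus pairwise genetic distances
#'
#' Codominant diploid distance between two samples at one locus: half the
#' number of unshared allele copies between the two unordered pairs, i.e. 0
#' for identical genotypes, 0.5 when one copy is shared, 1 when none is.
#' Sample pairs in which either call is missing are `NA` (pairwise deletion).
#'
#' @param x an \linkS4class{SsrGenotypes} with at least 2 samples
#' @param locus locus id (or row index)
#' @return numeric vector over the `choose(n, 2)` unordered sample pairs, in
#'   `combn(n, 2)` column order
#' @export
locusDistances <- function(x, locus) {
    stopifnot(is(x, "SsrGenotypes"))
    if (ncol(x) < 2) stop("at least 2 samples are required")
    a1 <- assay(x, "a1")[locus, ]; a2 <- assay(x, "a2")[locus, ]
    idx <- .pairIndex(ncol(x))
    unname(.pairDist(a1[idx$i], a2[idx$i], a1[idx$j], a2[idx$j]))
}

.pairIndex <- function(n) {
    cb <- utils::combn(n, 2)
    list(i = cb[1, ], j = cb[2, ])
}

# shared allele copies between sorted pairs (x1<=x2), vectorized
.pairDist <- function(x1, x2, y1, y2) {
    shared <- ifelse(x1 == y1, 1L + (x2 == y2),
              ifelse(x1 == y2, 1L + (x2 == y1),
                     (x2 == y1 | x2 == y2) + 0L))
    (2 - shared) / 2
}

.zeroVarianceError <- function(loci) {
    stop(structure(class = c("ssrZeroVarianceError", "error", "condition"),
                   list(message = paste0(
                       "rbarD undefined: zero distance variance at locus ",
                       paste(loci, collapse = ", ")),
                       call = sys.call(-1))))
}

# Core: distance matrix (complete pairs x loci) -> LdResult
.ldFromDistances <- function(D, loci, nPairs) {
    P <- nPairs
    sj <- colSums(D)
    varJ <- colSums(D^2) - sj^2 / P        # sum-of-squares (population) form
    names(varJ) <- loci
    if (any(varJ <= 1e-12))
        .zeroVarianceError(loci[varJ <= 1e-12])
    XtX <- crossprod(D)
    covJK <- XtX - tcrossprod(sj) / P
    dimnames(covJK) <- list(loci, loci)
    VE <- sum(varJ)
    sumCov <- sum(covJK[upper.tri(covJK)])
    VO <- VE + 2 * sumCov
    sdprod <- sqrt(outer(varJ, varJ))
    denom <- sum(sdprod[upper.tri(sdprod)])
    new("LdResult",
        loci = loci, nPairs = as.integer(P),
        VO = VO, VE = VE, varJ = varJ, covJK = covJK,
        IA = VO / VE - 1,
        rbarD = sumCov / denom,
        pValue = NA_real_, nPerm = 0L)
}

#' Index of association and standardized rbarD
#'
#' Multilocus linkage disequilibrium over a locus subset. Per-locus pairwise
#' distances (see [locusDistances()]) are restricted to sample pairs observed
#' at every locus in the subset (complete-pair deletion), then
#' `IA = VO/VE - 1` where `VO` is the variance of the summed distances and
#' `VE` the sum of per-locus variances, and
#' `rbarD = sum(cov_jk) / sum(sqrt(var_j * var_k))` over locus pairs `j < k`.
#' `rbarD` corrects `IA`'s dependence on the number of loci and lies in
#' `[-1, 1]`. Variance ratios use the population sum-of-squares form; the
#' shared divisor cancels.
#'
#' A locus with zero distance variance in the subset makes the statistic
#' undefined; this is signalled as an error of class `ssrZeroVarianceError`,
#' never silently reported as 0.
#'
#' @param x an \linkS4class{SsrGenotypes}
#' @param loci character vector of locus ids (default: all loci; at least 2)
#' @return an \linkS4class{LdResult}
#' @examples
#' set.seed(1)
#' g <- simulateGenotypes(20, list(L1 = c("100" = .5, "102" = .5),
#'                                 L2 = c("200" = .5, "204" = .5)), seed = 1)$genotypes
#' rbarD(g)
#' @export
rbarD <- function(x, loci = locusIds(x)) {
    stopifnot(is(x, "SsrGenotypes"), length(loci) >= 2)
    D <- vapply(loci, function(lc) locusDistances(x, lc),
                numeric(choose(ncol(x), 2)))
    keep <- stats::complete.cases(D)
    if (sum(keep) < 3)
        stop("fewer than 3 complete sample pairs across the locus subset")
    .ldFromDistances(D[keep, , drop = FALSE], loci, sum(keep))
}

#' Pairwise rbarD table over all locus pairs
#'
#' Entry `(j, k)` is `rbarD` computed on the subset `{j, k}`; the matrix is
#' symmetric with an undefined (`NA`) diagonal. Pairs for which the statistic
#' is undefined (zero variance, too few complete pairs) are `NA` and listed
#' in the `undefined` attribute rather than silently zeroed.
#'
#' @param x an \linkS4class{SsrGenotypes} with at least 2 loci
#' @return symmetric numeric matrix (loci x loci) with attribute `undefined`,
#'   a character vector of "locusA:locusB" labels for undefined entries
#' @export
pairwiseRbarD <- function(x) {
    stopifnot(is(x, "SsrGenotypes"), nrow(x) >= 2)
    loci <- rownames(x)
    L <- length(loci)
    out <- matrix(NA_real_, L, L, dimnames = list(loci, loci))
    undef <- character()
    for (j in seq_len(L - 1)) for (k in (j + 1):L) {
        r <- tryCatch(rbarD(x, c(loci[j], loci[k]))@rbarD,
                      error = function(e) NA_real_)
        if (is.na(r)) undef <- c(undef, paste0(loci[j], ":", loci[k]))
        out[j, k] <- out[k, j] <- r
    }
    attr(out, "undefined") <- undef
    out
}

#' Permutation test for multilocus linkage disequilibrium
#'
#' Each permutation independently shuffles every locus's genotype column
#' across samples, preserving per-locus allele and missing composition while
#' destroying inter-locus association, and recomputes `rbarD`. The one-sided
#' upper-tail p-value with add-one correction is
#' `p = (1 + #\{perm rbarD >= observed\}) / (1 + nPerm)`.
#'
#' @param x an \linkS4class{SsrGenotypes}
#' @param loci locus subset (default all; at least 2)
#' @param nPerm number of permutations (default 999)
#' @param seed integer seed making the permutation stream reproducible
#' @return the observed \linkS4class{LdResult} with `pValue` and `nPerm` set
#' @export
ldPermutationTest <- function(x, loci = locusIds(x), nPerm = 999L,
                              seed = NULL) {
    stopifnot(is(x, "SsrGenotypes"), length(loci) >= 2)
    nPerm <- as.integer(nPerm)
    if (nPerm < 1) stop("nPerm must be at least 1")
    n <- ncol(x)
    obs <- rbarD(x, loci)
    # full per-locus pair-distance vectors; a permutation of samples is a
    # reindexing of pair distances, so distances are computed once
    D0 <- vapply(loci, function(lc) locusDistances(x, lc),
                 numeric(choose(n, 2)))
    pidx <- .pairIndex(n)
    M <- matrix(0L, n, n)
    M[cbind(pidx$i, pidx$j)] <- seq_along(pidx$i)
    M[cbind(pidx$j, pidx$i)] <- seq_along(pidx$i)
    if (!is.null(seed)) {
        old <- if (exists(".Random.seed", .GlobalEnv))
            get(".Random.seed", .GlobalEnv) else NULL
        on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
        set.seed(seed)
    }
    permStats <- numeric(nPerm)
    for (b in seq_len(nPerm)) {
        Db <- D0
        for (l in seq_along(loci)) {
            sig <- sample.int(n)
            Db[, l] <- D0[M[cbind(sig[pidx$i], sig[pidx$j])], l]
        }
        keep <- stats::complete.cases(Db)
        permStats[b] <- if (sum(keep) < 3) -Inf else
            tryCatch(.ldFromDistances(Db[keep, , drop = FALSE], loci,
                                      sum(keep))@rbarD,
                     ssrZeroVarianceError = function(e) -Inf)
    }
    p <- (1 + sum(permStats >= obs@rbarD)) / (1 + nPerm)
    obs@pValue <- p
    obs@nPerm <- nPerm
    obs
}

#' Write a pairwise rbarD table (long format) to TSV
#'
#' @param mat matrix from [pairwiseRbarD()]
#' @param path output path
#' @param pvals optional matching matrix of permutation p-values
#' @return `path`, invisibly
#' @export
writeLdTable <- function(mat, path, pvals = NULL) {
    loci <- rownames(mat)
    rows <- list()
    for (j in seq_len(nrow(mat) - 1)) for (k in (j + 1):ncol(mat)) {
        rows[[length(rows) + 1L]] <- data.frame(
            locus_a = loci[j], locus_b = loci[k],
            rbar_d = mat[j, k],
            p_value = if (is.null(pvals)) NA_real_ else pvals[j, k])
    }
    df <- do.call(rbind, rows)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
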
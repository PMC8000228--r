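#' Clone-correct a genotype panel
#'
#' Samples that are genetically identical at every locus (including
#' missing-status) are reduced to a single representative — the first
#' occurrence in input order — so that downstream diversity indices are
#' computed over unique multilocus genotypes.
#'
#' @param x an \linkS4class{SsrGenotypes}
#' @return the panel restricted to unique multilocus genotypes
#' @export
cloneCorrect <- function(x) {
    stopifnot(is(x, "SsrGenotypes"))
    keys <- mlgKeys(x)
    x[, !duplicated(keys)]
}

#' Allele frequency spectrum of a locus
#'
#' Missing genotypes are excluded locus-wise (pairwise deletion): `n` is the
#' number of genotyped individuals at this locus, and allele copies are
#' counted over the `2n` observed chromosomes.
#'
#' @param x an \linkS4class{SsrGenotypes}
#' @param locus locus id (or row index)
#' @return an \linkS4class{AlleleSpectrum}
#' @export
alleleFrequencies <- function(x, locus) {
    stopifnot(is(x, "SsrGenotypes"))
    a1 <- assay(x, "a1")[locus, ]; a2 <- assay(x, "a2")[locus, ]
    ok <- !is.na(a1)
    if (!any(ok))
        stop("locus '", locus, "' has no genotyped samples")
    copies <- c(a1[ok], a2[ok])
    tab <- table(copies)
    counts <- as.integer(tab)
    names(counts) <- names(tab)
    new("AlleleSpectrum",
        locusId = as.character(locus),
        n = sum(ok),
        counts = counts,
        freqs = counts / sum(counts))
}

#' Shannon's diversity index of allele frequencies
#'
#' `H' = -sum(p * ln p)` over the allele frequencies (natural log, nats).
#'
#' @param spec an \linkS4class{AlleleSpectrum}
#' @return numeric H'
#' @examples
#' # 19 genotypes: 17 A/A homozygotes and 2 A/B heterozygotes
#' g <- SsrGenotypes(a1 = matrix(rep(203L, 19), 1), a2 = matrix(c(rep(203L, 17), 205L, 205L), 1))
#' shannonIndex(alleleFrequencies(g, 1))  # 0.206
#' @export
shannonIndex <- function(spec) {
    stopifnot(is(spec, "AlleleSpectrum"))
    p <- spec@freqs[spec@freqs > 0]
    -sum(p * log(p))
}

#' Nei's unbiased expected heterozygosity
#'
#' The small-sample-corrected gene diversity
#' `He = (2n / (2n - 1)) * (1 - sum(p^2))`, with `n` the number of genotyped
#' individuals at the locus. This equals the probability that two allele
#' copies drawn without replacement from the sample differ.
#'
#' @param spec an \linkS4class{AlleleSpectrum}
#' @return numeric He in \[0, 1\]
#' @export
expectedHet <- function(spec) {
    stopifnot(is(spec, "AlleleSpectrum"))
    n <- spec@n
    (2 * n / (2 * n - 1)) * (1 - sum(spec@freqs^2))
}

#' Observed heterozygosity of a locus
#'
#' Fraction of non-missing genotypes that are heterozygous.
#'
#' @param x an \linkS4class{SsrGenotypes}
#' @param locus locus id (or row index)
#' @return numeric Ho in \[0, 1\]
#' @export
observedHet <- function(x, locus) {
    stopifnot(is(x, "SsrGenotypes"))
    a1 <- assay(x, "a1")[locus, ]; a2 <- assay(x, "a2")[locus, ]
    ok <- !is.na(a1)
    if (!any(ok))
        stop("locus '", locus, "' has no genotyped samples")
    sum(a1[ok] != a2[ok]) / sum(ok)
}

#' Percent missing data at a locus
#'
#' `100 * (# missing genotypes) / (# samples)`, full precision (round only
#' when reporting).
#'
#' @param x an \linkS4class{SsrGenotypes}
#' @param locus locus id (or row index)
#' @return numeric percentage in \[0, 100\]
#' @export
percentMissing <- function(x, locus) {
    stopifnot(is(x, "SsrGenotypes"))
    a1 <- assay(x, "a1")[locus, ]
    100 * sum(is.na(a1)) / length(a1)
}

#' Per-locus diversity summary with mean row
#'
#' Computes, per locus, the number of alleles `N`, percent missing data,
#' Shannon's diversity index `H'` (natural log), observed heterozygosity `Ho`
#' and Nei's unbiased expected heterozygosity `He`, and appends the unweighted
#' arithmetic mean of each column as a final `Mean` row. The overall dataset
#' missing percentage (missing cells over samples x loci) is attached as
#' attribute `overallMissingPct`, and the total allele count as
#' `totalAlleles`.
#'
#' @param x an \linkS4class{SsrGenotypes}
#' @return data.frame with columns `locus`, `N`, `missing_pct`, `shannon`,
#'   `Ho`, `He`; values at full precision (round at reporting time)
#' @export
summarizeLoci <- function(x) {
    stopifnot(is(x, "SsrGenotypes"), nrow(x) >= 1)
    rows <- lapply(rownames(x), function(lc) {
        spec <- alleleFrequencies(x, lc)
        data.frame(locus = lc,
                   N = length(spec@counts),
                   missing_pct = percentMissing(x, lc),
                   shannon = shannonIndex(spec),
                   Ho = observedHet(x, lc),
                   He = expectedHet(spec))
    })
    df <- do.call(rbind, rows)
    df <- appendMeanRow(df)
    attr(df, "overallMissingPct") <- 100 * mean(isMissing(x))
    attr(df, "totalAlleles") <- as.integer(sum(df$N[df$locus != "Mean"]))
    df
}

#' Append the unweighted column-mean row to a locus summary table
#'
#' @param df data.frame with columns `locus`, `N`, `missing_pct`, `shannon`,
#'   `Ho`, `He` (one row per locus, no mean row)
#' @return `df` with a final `Mean` row holding arithmetic column means
#' @export
appendMeanRow <- function(df) {
    stopifnot(all(c("locus", "N", "missing_pct", "shannon", "Ho", "He")
                  %in% colnames(df)))
    mean_row <- data.frame(locus = "Mean",
                           N = mean(df$N),
                           missing_pct = mean(df$missing_pct),
                           shannon = mean(df$shannon),
                           Ho = mean(df$Ho),
                           He = mean(df$He))
    out <- rbind(df[, c("locus", "N", "missing_pct", "shannon", "Ho", "He")],
                 mean_row)
    rownames(out) <- NULL
    out
}

#' Write a locus summary table to TSV
#'
#' Values are rounded to `digits` decimals at write time only.
#'
#' @param df output of [summarizeLoci()]
#' @param path output path
#' @param digits decimals in the report (default 2)
#' @return `path`, invisibly
#' @export
writeLocusSummary <- function(df, path, digits = 2) {
    out <- df
    num <- vapply(out, is.numeric, TRUE)
    out[num] <- lapply(out[num], round, digits = digits)
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
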
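#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- SimpleList
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays assayNames
NULL

.MISSING_CODE <- "NA"

#' Diploid SSR genotype panel
#'
#' An [SummarizedExperiment::SummarizedExperiment-class] with loci as rows,
#' samples as columns, and two integer assays `a1` and `a2` holding the
#' unordered allele pair of each diploid call (stored sorted so that
#' `a1 <= a2`). Missing genotypes are `NA` in both assays. Allele labels are
#' integer fragment sizes in bp (allelic classes after binning).
#'
#' @slot .. see \linkS4class{SummarizedExperiment}
#' @export
setClass("SsrGenotypes", contains = "SummarizedExperiment")

setValidity("SsrGenotypes", function(object) {
    msg <- character()
    if (!all(c("a1", "a2") %in% assayNames(object)))
        msg <- c(msg, "assays 'a1' and 'a2' are required")
    else {
        a1 <- assay(object, "a1"); a2 <- assay(object, "a2")
        if (!is.integer(a1) || !is.integer(a2))
            msg <- c(msg, "allele assays must be integer matrices")
        if (!identical(is.na(a1), is.na(a2)))
            msg <- c(msg, "missingness must agree between the two allele assays")
        ok <- !is.na(a1)
        if (any(a1[ok] > a2[ok]))
            msg <- c(msg, "allele pairs must be stored sorted (a1 <= a2)")
    }
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "duplicate locus ids")
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "duplicate sample ids")
    if (length(msg)) msg else TRUE
})

#' Construct an SsrGenotypes panel
#'
#' @param a1,a2 integer matrices (loci x samples) holding the two allele
#'   labels of each diploid call; `NA` in both marks a missing genotype. The
#'   pair is unordered: the constructor sorts each call so `a1 <= a2`.
#' @param locusIds,sampleIds character vectors of row / column identifiers;
#'   default to the dimnames of `a1`.
#' @return An \linkS4class{SsrGenotypes} object.
#' @examples
#' g <- SsrGenotypes(a1 = matrix(c(203L, 203L), 1, 2),
#'                   a2 = matrix(c(203L, 205L), 1, 2),
#'                   locusIds = "L1", sampleIds = c("S1", "S2"))
#' nLoci(g)
#' @export
SsrGenotypes <- function(a1, a2,
                         locusIds = rownames(a1),
                         sampleIds = colnames(a1)) {
    a1 <- .as_int_matrix(a1); a2 <- .as_int_matrix(a2)
    stopifnot(identical(dim(a1), dim(a2)))
    if (is.null(locusIds)) locusIds <- paste0("L", seq_len(nrow(a1)))
    if (is.null(sampleIds)) sampleIds <- paste0("S", seq_len(ncol(a1)))
    lo <- pmin(a1, a2); hi <- pmax(a1, a2)
    dimnames(lo) <- dimnames(hi) <- list(locusIds, sampleIds)
    se <- SummarizedExperiment(assays = SimpleList(a1 = lo, a2 = hi))
    new("SsrGenotypes", se)
}

.as_int_matrix <- function(x) {
    x <- as.matrix(x)
    storage.mode(x) <- "integer"
    x
}

#' Raw fragment-size panel
#'
#' A [SummarizedExperiment::SummarizedExperiment-class] with loci as rows and
#' samples as columns; numeric assays `s1` and `s2` carry the unordered pair
#' of raw fragment sizes (bp) measured for a diploid genotype (homozygotes
#' repeat the same size). Missing entries are `NA` in both assays.
#'
#' @export
setClass("RawSizePanel", contains = "SummarizedExperiment")

setValidity("RawSizePanel", function(object) {
    msg <- character()
    if (!all(c("s1", "s2") %in% assayNames(object)))
        msg <- c(msg, "assays 's1' and 's2' are required")
    else {
        s1 <- assay(object, "s1"); s2 <- assay(object, "s2")
        if (!identical(is.na(s1), is.na(s2)))
            msg <- c(msg, "missingness must agree between the two size assays")
        ok <- !is.na(s1)
        if (any(s1[ok] <= 0) || any(s2[!is.na(s2)] <= 0))
            msg <- c(msg, "fragment sizes must be strictly positive")
        if (any(s1[ok] > s2[ok]))
            msg <- c(msg, "size pairs must be stored sorted (s1 <= s2)")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a RawSizePanel
#'
#' @param s1,s2 numeric matrices (loci x samples) of raw fragment sizes in bp;
#'   the pair is unordered and is stored sorted.
#' @param locusIds,sampleIds identifiers, defaulting to the dimnames of `s1`.
#' @return A \linkS4class{RawSizePanel}.
#' @export
RawSizePanel <- function(s1, s2,
                         locusIds = rownames(s1),
                         sampleIds = colnames(s1)) {
    s1 <- as.matrix(s1); s2 <- as.matrix(s2)
    storage.mode(s1) <- storage.mode(s2) <- "double"
    stopifnot(identical(dim(s1), dim(s2)))
    if (is.null(locusIds)) locusIds <- paste0("L", seq_len(nrow(s1)))
    if (is.null(sampleIds)) sampleIds <- paste0("S", seq_len(ncol(s1)))
    lo <- pmin(s1, s2); hi <- pmax(s1, s2)
    dimnames(lo) <- dimnames(hi) <- list(locusIds, sampleIds)
    se <- SummarizedExperiment(assays = SimpleList(s1 = lo, s2 = hi))
    new("RawSizePanel", se)
}

#' Per-locus allele binning model
#'
#' Converts raw fragment sizes to integer allelic classes on the motif-length
#' grid: classes sit at `offset + k * motifLength`. `quality` is the largest
#' circular deviation (bp) of any fitted size from its assigned class.
#'
#' @export
setClass("BinModel", representation(
    locusId     = "character",
    motifLength = "integer",
    offset      = "numeric",
    binCenters  = "numeric",
    quality     = "numeric"
))

setValidity("BinModel", function(object) {
    m <- object@motifLength
    msg <- character()
    if (!(m %in% 2:4)) msg <- c(msg, "motifLength must be 2, 3 or 4")
    if (object@offset < 0 || object@offset >= m)
        msg <- c(msg, "offset must lie in [0, motifLength)")
    if (is.unsorted(object@binCenters, strictly = TRUE))
        msg <- c(msg, "binCenters must be strictly increasing")
    if (length(object@binCenters) > 1) {
        k <- diff(object@binCenters) / m
        if (any(abs(k - round(k)) > 1e-6))
            msg <- c(msg, "binCenters must be motifLength bp apart on a shared grid")
    }
    if (length(msg)) msg else TRUE
})

setMethod("show", "BinModel", function(object) {
    cat(sprintf("BinModel for locus %s (m = %d): offset %.2f bp, %d classes [%s], max deviation %.3f bp\n",
                object@locusId, object@motifLength, object@offset,
                length(object@binCenters),
                paste(round(object@binCenters), collapse = ", "),
                object@quality))
})

#' Allele frequency spectrum of one locus
#'
#' Counts and relative frequencies of allele copies among the non-missing
#' diploid genotypes of one locus; `n` is the number of genotyped individuals,
#' so copy counts sum to `2n`.
#'
#' @export
setClass("AlleleSpectrum", representation(
    locusId = "character",
    n       = "integer",
    counts  = "integer",
    freqs   = "numeric"
))

setValidity("AlleleSpectrum", function(object) {
    msg <- character()
    if (sum(object@counts) != 2L * object@n)
        msg <- c(msg, "allele copy counts must sum to 2n")
    if (abs(sum(object@freqs) - 1) > 1e-12)
        msg <- c(msg, "frequencies must sum to 1")
    if (length(msg)) msg else TRUE
})

setMethod("show", "AlleleSpectrum", function(object) {
    cat(sprintf("AlleleSpectrum for locus %s: n = %d genotypes, %d alleles\n",
                object@locusId, object@n, length(object@counts)))
    print(rbind(count = object@counts, freq = round(object@freqs, 4)))
})

#' Index-of-association result
#'
#' Holds the observed variance of summed per-locus pair distances (`VO`), its
#' no-association expectation (`VE`, the sum of per-locus variances), the
#' per-locus variances and pairwise covariances, and the derived statistics
#' `IA = VO/VE - 1` and `rbarD`, plus an optional permutation p-value.
#'
#' @export
setClass("LdResult", representation(
    loci    = "character",
    nPairs  = "integer",
    VO      = "numeric",
    VE      = "numeric",
    varJ    = "numeric",
    covJK   = "matrix",
    IA      = "numeric",
    rbarD   = "numeric",
    pValue  = "numeric",
    nPerm   = "integer"
))

setMethod("show", "LdResult", function(object) {
    cat(sprintf("LdResult over %d loci (%d complete sample pairs)\n",
                length(object@loci), object@nPairs))
    cat(sprintf("  I_A = %.4f, rbarD = %.4f", object@IA, object@rbarD))
    if (!is.na(object@pValue))
        cat(sprintf(", p = %.4g (%d permutations)", object@pValue, object@nPerm))
    cat("\n")
})
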
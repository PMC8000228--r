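#' @rdname SsrGenotypes
#' @param x an `SsrGenotypes` or `RawSizePanel` object
#' @export
setGeneric("locusIds", function(x) standardGeneric("locusIds"))

#' @rdname SsrGenotypes
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname SsrGenotypes
#' @export
setGeneric("nLoci", function(x) standardGeneric("nLoci"))

#' @rdname SsrGenotypes
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @rdname SsrGenotypes
#' @export
setGeneric("isMissing", function(x) standardGeneric("isMissing"))

#' @describeIn SsrGenotypes locus identifiers (row names)
#' @export
setMethod("locusIds", "SummarizedExperiment", function(x) rownames(x))

#' @describeIn SsrGenotypes sample identifiers (column names)
#' @export
setMethod("sampleIds", "SummarizedExperiment", function(x) colnames(x))

#' @describeIn SsrGenotypes number of loci
#' @export
setMethod("nLoci", "SummarizedExperiment", function(x) nrow(x))

#' @describeIn SsrGenotypes number of samples
#' @export
setMethod("nSamples", "SummarizedExperiment", function(x) ncol(x))

#' @describeIn SsrGenotypes logical loci x samples matrix marking missing calls
#' @export
setMethod("isMissing", "SsrGenotypes", function(x) is.na(assay(x, "a1")))

#' @describeIn RawSizePanel logical loci x samples matrix marking missing entries
#' @export
setMethod("isMissing", "RawSizePanel", function(x) is.na(assay(x, "s1")))

#' Allele call matrices
#'
#' Extract one of the two sorted allele-label matrices (loci x samples).
#'
#' @param x an \linkS4class{SsrGenotypes}
#' @param which 1 or 2, the lower or upper allele of each sorted pair
#' @return an integer matrix with `NA` for missing calls
#' @export
alleleCalls <- function(x, which = 1) {
    stopifnot(is(x, "SsrGenotypes"), which %in% 1:2)
    assay(x, if (which == 1) "a1" else "a2")
}

#' Multilocus genotype keys
#'
#' One string per sample encoding its allele pair at every locus (missing
#' calls included), used for clone correction: samples with equal keys are
#' identical multilocus genotypes.
#'
#' @param x an \linkS4class{SsrGenotypes}
#' @return named character vector, one element per sample
#' @export
mlgKeys <- function(x) {
    a1 <- assay(x, "a1"); a2 <- assay(x, "a2")
    cell <- ifelse(is.na(a1), .MISSING_CODE, paste0(a1, "/", a2))
    keys <- apply(cell, 2, paste, collapse = ";")
    names(keys) <- colnames(x)
    keys
}

setMethod("show", "SsrGenotypes", function(object) {
    cat(sprintf("SsrGenotypes: %d loci x %d samples (%.1f%% missing)\n",
                nrow(object), ncol(object),
                100 * mean(is.na(assay(object, "a1")))))
    callNextMethod()
})

setMethod("show", "RawSizePanel", function(object) {
    cat(sprintf("RawSizePanel: %d loci x %d samples (%.1f%% missing)\n",
                nrow(object), ncol(object),
                100 * mean(is.na(assay(object, "s1")))))
    callNextMethod()
})
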
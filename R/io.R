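#' @importFrom Biostrings readBStringSet writeXStringSet BStringSet DNAString
#'   reverseComplement
#' @importFrom utils read.csv write.csv read.delim write.table
NULL

.SEQ_ALPHABET <- c("A", "C", "G", "T", "N", "a", "c", "g", "t", "n")

#' Read assembled scaffolds from FASTA
#'
#' Scaffolds are read case-preserving: lowercase bases (soft masking) and `N`
#' are treated as masked by the downstream SSR scan. Sequences are validated
#' against the `{A,C,G,T,N}` alphabet in either case.
#'
#' @param path path to a (multi-record, optionally soft-masked) FASTA file
#' @return a [Biostrings::BStringSet] named by scaffold id, in file order
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">s1", "acgtACGT"), fa)
#' readScaffolds(fa)
#' @export
readScaffolds <- function(path) {
    stopifnot(file.exists(path))
    seqs <- readBStringSet(path)
    if (length(seqs) == 0)
        stop("no sequence records in ", path)
    ids <- sub("\\s.*$", "", names(seqs))
    if (any(!nzchar(ids)))
        stop("malformed FASTA header (empty id) in ", path)
    if (anyDuplicated(ids))
        stop("duplicate scaffold id in ", path, ": ",
             ids[anyDuplicated(ids)][1])
    names(seqs) <- ids
    w <- Biostrings::width(seqs)
    if (any(w == 0))
        stop("empty sequence for record '", ids[which(w == 0)[1]], "'")
    bad <- !grepl("^[ACGTNacgtn]+$", as.character(seqs))
    if (any(bad))
        stop("invalid characters in record '", ids[which(bad)[1]],
             "' (alphabet is A,C,G,T,N upper or lower case)")
    seqs
}

#' Write scaffolds to FASTA
#'
#' @param seqs a named [Biostrings::BStringSet] (case preserved)
#' @param path output path
#' @return `path`, invisibly
#' @export
writeScaffolds <- function(seqs, path) {
    writeXStringSet(seqs, path)
    invisible(path)
}

#' Read a diploid genotype matrix from CSV
#'
#' Expected dialect: first column `sample`, then one column per locus holding
#' `"a/b"` integer allele pairs (order-free; `"205/203"` equals `"203/205"`)
#' or the missing code `"NA"`.
#'
#' @param path path to the CSV file
#' @return an \linkS4class{SsrGenotypes} (loci as rows, samples as columns)
#' @export
readGenotypes <- function(path) {
    stopifnot(file.exists(path))
    df <- read.csv(path, check.names = FALSE, colClasses = "character",
                   na.strings = NULL)
    if (ncol(df) < 2)
        stop("genotype table needs a sample column plus at least one locus")
    samples <- df[[1]]
    if (anyDuplicated(samples))
        stop("duplicate sample id: ", samples[duplicated(samples)][1])
    loci <- colnames(df)[-1]
    a1 <- a2 <- matrix(NA_integer_, nrow = length(loci), ncol = length(samples),
                       dimnames = list(loci, samples))
    for (j in seq_along(loci)) {
        cell <- df[[j + 1]]
        miss <- cell == .MISSING_CODE | cell == ""
        pair <- regmatches(cell, regexec("^([0-9]+)/([0-9]+)$", cell))
        bad <- !miss & lengths(pair) != 3L
        if (any(bad))
            stop("malformed genotype '", cell[which(bad)[1]], "' at locus ",
                 loci[j], ", sample ", samples[which(bad)[1]])
        a <- vapply(pair, function(p) if (length(p)) as.integer(p[2]) else NA_integer_, 0L)
        b <- vapply(pair, function(p) if (length(p)) as.integer(p[3]) else NA_integer_, 0L)
        a1[j, ] <- a
        a2[j, ] <- b
    }
    SsrGenotypes(a1, a2)
}

#' Write a genotype matrix to CSV
#'
#' Inverse of [readGenotypes()]: allele pairs are written sorted as `"a/b"`,
#' missing calls as `"NA"`.
#'
#' @param x an \linkS4class{SsrGenotypes}
#' @param path output path
#' @return `path`, invisibly
#' @export
writeGenotypes <- function(x, path) {
    a1 <- assay(x, "a1"); a2 <- assay(x, "a2")
    cell <- ifelse(is.na(a1), .MISSING_CODE, paste0(a1, "/", a2))
    df <- data.frame(sample = colnames(x), t(cell), check.names = FALSE)
    write.csv(df, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' Read a raw fragment-size panel from CSV
#'
#' Same layout as the genotype CSV but entries are real-valued size pairs
#' `"203.4/205.1"` in bp, or `"NA"`.
#'
#' @param path path to the CSV file
#' @return a \linkS4class{RawSizePanel}
#' @export
readSizePanel <- function(path) {
    stopifnot(file.exists(path))
    df <- read.csv(path, check.names = FALSE, colClasses = "character",
                   na.strings = NULL)
    samples <- df[[1]]
    if (anyDuplicated(samples))
        stop("duplicate sample id: ", samples[duplicated(samples)][1])
    loci <- colnames(df)[-1]
    s1 <- s2 <- matrix(NA_real_, nrow = length(loci), ncol = length(samples),
                       dimnames = list(loci, samples))
    num <- "[0-9]+(?:\\.[0-9]+)?"
    pat <- sprintf("^(%s)/(%s)$", num, num)
    for (j in seq_along(loci)) {
        cell <- df[[j + 1]]
        miss <- cell == .MISSING_CODE | cell == ""
        pair <- regmatches(cell, regexec(pat, cell))
        bad <- !miss & lengths(pair) != 3L
        if (any(bad))
            stop("malformed size entry '", cell[which(bad)[1]], "' at locus ",
                 loci[j])
        s1[j, ] <- vapply(pair, function(p) if (length(p)) as.numeric(p[2]) else NA_real_, 0)
        s2[j, ] <- vapply(pair, function(p) if (length(p)) as.numeric(p[3]) else NA_real_, 0)
    }
    RawSizePanel(s1, s2)
}

#' Write a raw fragment-size panel to CSV
#'
#' @param x a \linkS4class{RawSizePanel}
#' @param path output path
#' @param digits decimal places for sizes (default 2)
#' @return `path`, invisibly
#' @export
writeSizePanel <- function(x, path, digits = 2) {
    s1 <- assay(x, "s1"); s2 <- assay(x, "s2")
    fmt <- function(v) formatC(v, format = "f", digits = digits)
    cell <- ifelse(is.na(s1), .MISSING_CODE, paste0(fmt(s1), "/", fmt(s2)))
    df <- data.frame(sample = colnames(x), t(cell), check.names = FALSE)
    write.csv(df, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

.CATALOG_COLS <- c("scaffold", "start", "end", "motif", "canonical_class",
                   "motif_length", "repeat_count", "compound_flag")

#' Write an SSR catalog to TSV
#'
#' Coordinates are emitted 1-based inclusive. Input must be sorted by
#' (scaffold, start) with no duplicated locus positions.
#'
#' @param loci a [GenomicRanges::GRanges] as returned by [findSSRs()]
#' @param path output path
#' @return `path`, invisibly
#' @export
writeSsrCatalog <- function(loci, path) {
    stopifnot(is(loci, "GRanges"))
    df <- .catalogFrame(loci)
    if (nrow(df) > 1) {
        o <- order(df$scaffold, df$start)
        if (!identical(o, seq_len(nrow(df))))
            stop("catalog loci must be sorted by (scaffold, start)")
        if (anyDuplicated(df[, c("scaffold", "start")]))
            stop("duplicate loci in catalog")
    }
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

.catalogFrame <- function(loci) {
    data.frame(
        scaffold = as.character(GenomicRanges::seqnames(loci)),
        start = GenomicRanges::start(loci),
        end = GenomicRanges::end(loci),
        motif = loci$motif,
        canonical_class = loci$canonicalClass,
        motif_length = loci$motifLength,
        repeat_count = loci$repeatCount,
        compound_flag = loci$compound,
        stringsAsFactors = FALSE
    )
}

#' Read an SSR catalog written by [writeSsrCatalog()]
#'
#' @param path path to the TSV catalog
#' @return a [GenomicRanges::GRanges] with the catalog metadata columns
#' @export
readSsrCatalog <- function(path) {
    stopifnot(file.exists(path))
    df <- read.delim(path, stringsAsFactors = FALSE)
    if (!identical(colnames(df), .CATALOG_COLS))
        stop("unexpected catalog columns in ", path)
    gr <- GenomicRanges::GRanges(
        seqnames = df$scaffold,
        ranges = IRanges::IRanges(start = df$start, end = df$end)
    )
    gr$motif <- df$motif
    gr$canonicalClass <- df$canonical_class
    gr$motifLength <- as.integer(df$motif_length)
    gr$repeatCount <- as.integer(df$repeat_count)
    gr$compound <- as.logical(df$compound_flag)
    gr
}
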
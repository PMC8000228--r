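#' @importFrom GenomicRanges GRanges seqnames start end
#' @importFrom IRanges IRanges
NULL

#' Canonical motif class of a repeat unit
#'
#' Tandem-repeat motifs that differ only by reading frame or strand describe
#' the same repeat, so class tabulation collapses them: the canonical label is
#' the lexicographically smallest string among all cyclic rotations of the
#' motif and all cyclic rotations of its reverse complement. `"TA"`, `"AT"`
#' and their complements all report as `"AT"`.
#'
#' @param motif character vector of repeat units, each 2-4 bp over `{A,C,G,T}`
#' @return character vector of canonical class labels
#' @examples
#' canonicalMotif(c("TA", "GA", "TTTA"))
#' @export
canonicalMotif <- function(motif) {
    vapply(motif, .canonical1, "", USE.NAMES = FALSE)
}

.canonical1 <- function(motif) {
    if (is.na(motif) || !grepl("^[ACGT]{2,4}$", motif))
        stop("motif must be 2-4 bp over {A,C,G,T}: '", motif, "'")
    rc <- as.character(reverseComplement(DNAString(motif)))
    min(c(.rotations(motif), .rotations(rc)))
}

.rotations <- function(s) {
    n <- nchar(s)
    vapply(seq_len(n), function(i)
        paste0(substr(s, i, n), substr(s, 1, i - 1)), "")
}

.isPrimitive <- function(motif) {
    m <- nchar(motif)
    for (d in seq_len(m - 1)) {
        if (m %% d != 0) next
        if (strrep(substr(motif, 1, d), m / d) == motif) return(FALSE)
    }
    TRUE
}

#' Mine perfect SSRs from scaffolds
#'
#' Scans each scaffold (forward strand) for maximal perfect runs of di-, tri-
#' and tetra-nucleotide motifs meeting the minimum repeat-count thresholds.
#' Runs containing any masked base (lowercase or `N`) are not reported. A run
#' is reported once under its shortest period: a `(AT)x12` run is a single
#' di-nucleotide SSR, never a tetra-nucleotide `ATAT` repeat, and homopolymer
#' "motifs" such as `AA` are never emitted. Partial trailing unit copies are
#' ignored (the repeat count is whole copies only).
#'
#' @param seqs a named [Biostrings::BStringSet] of scaffolds (or a single
#'   character string, for convenience)
#' @param minRepeats named integer vector: minimum whole-unit copies per motif
#'   length; default `c("2" = 6, "3" = 6, "4" = 4)`
#' @return a [GenomicRanges::GRanges] (1-based inclusive coordinates) sorted
#'   by (scaffold, start), with metadata columns `motif`, `canonicalClass`,
#'   `motifLength`, `repeatCount` and `compound` (initialised `FALSE`; see
#'   [flagCompound()])
#' @examples
#' findSSRs(c(s1 = paste0("CC", strrep("AT", 6), "GG")))
#' @export
findSSRs <- function(seqs, minRepeats = c("2" = 6L, "3" = 6L, "4" = 4L)) {
    if (is.character(seqs)) {
        ids <- names(seqs)
        if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
        seqs <- BStringSet(seqs)
        if (length(seqs)) names(seqs) <- ids
    }
    stopifnot(all(c("2", "3", "4") %in% names(minRepeats)))
    hits <- lapply(seq_along(seqs), function(i)
        .scanOne(names(seqs)[i], as.character(seqs[[i]]), minRepeats))
    hits <- do.call(rbind, hits)
    if (is.null(hits) || nrow(hits) == 0) {
        gr <- GRanges()
        gr$motif <- character()
        gr$canonicalClass <- character()
        gr$motifLength <- integer()
        gr$repeatCount <- integer()
        gr$compound <- logical()
        return(gr)
    }
    hits <- hits[order(hits$scaffold, hits$start), , drop = FALSE]
    gr <- GRanges(hits$scaffold, IRanges(hits$start, hits$end))
    gr$motif <- hits$motif
    gr$canonicalClass <- canonicalMotif(hits$motif)
    gr$motifLength <- hits$m
    gr$repeatCount <- hits$count
    gr$compound <- FALSE
    gr
}

# Scan one scaffold for all motif lengths; coordinates 1-based inclusive.
.scanOne <- function(id, seq, minRepeats) {
    chars <- strsplit(seq, "", fixed = TRUE)[[1]]
    n <- length(chars)
    masked <- chars %in% c("a", "c", "g", "t", "n", "N")
    up <- toupper(chars)
    out <- list()
    for (m in 2:4) {
        minrep <- as.integer(minRepeats[as.character(m)])
        if (n < m * minrep) next
        idx <- seq_len(n - m)
        eq <- up[idx] == up[idx + m]
        eq[masked[idx] | masked[idx + m]] <- FALSE
        r <- rle(eq)
        ends <- cumsum(r$lengths)
        starts <- ends - r$lengths + 1L
        keep <- r$values & r$lengths + m >= m * minrep
        for (k in which(keep)) {
            s <- starts[k]                       # first base of the run
            span <- r$lengths[k] + m             # run length incl. final unit
            count <- span %/% m
            if (count < minrep) next
            motif <- paste(up[s:(s + m - 1L)], collapse = "")
            if (!.isPrimitive(motif)) next       # shortest-period reporting
            out[[length(out) + 1L]] <- data.frame(
                scaffold = id, start = s, end = s + m * count - 1L,
                motif = motif, m = m, count = count,
                stringsAsFactors = FALSE)
        }
    }
    if (length(out)) do.call(rbind, out) else NULL
}

#' Flag compound SSRs
#'
#' Two SSRs separated by fewer than `maxGap` intervening bases form a
#' compound SSR; the relation chains, so every member of a run of closely
#' spaced SSRs is flagged. The boundary is strict: exactly `maxGap` bases
#' between two SSRs does not make them compound.
#'
#' @param loci a [GenomicRanges::GRanges] from [findSSRs()], sorted by
#'   (scaffold, start)
#' @param maxGap integer, default 15 bp
#' @return `loci` with the `compound` metadata column set
#' @export
flagCompound <- function(loci, maxGap = 15L) {
    stopifnot(is(loci, "GRanges"))
    if (length(loci) < 2) return(loci)
    sc <- as.character(seqnames(loci))
    st <- start(loci); en <- end(loci)
    if (!identical(order(sc, st), seq_along(loci)))
        stop("loci must be sorted by (scaffold, start)")
    comp <- rep(FALSE, length(loci))
    for (i in seq_len(length(loci) - 1)) {
        if (sc[i] != sc[i + 1]) next
        gap <- st[i + 1] - en[i] - 1L   # intervening bases
        if (gap < maxGap) comp[c(i, i + 1)] <- TRUE
    }
    loci$compound <- comp
    loci
}

#' Tabulate mined SSRs by motif class and motif length
#'
#' @param loci a [GenomicRanges::GRanges] from [findSSRs()]
#' @return a list with `byClass` (data.frame: canonical class, motif length,
#'   count) and `byLength` (data.frame: motif length, count); per-length
#'   totals equal the sum of their class counts by construction
#' @export
tabulateMotifs <- function(loci) {
    stopifnot(is(loci, "GRanges"))
    if (length(loci) == 0) {
        return(list(
            byClass = data.frame(canonical_class = character(),
                                 motif_length = integer(), count = integer()),
            byLength = data.frame(motif_length = c(2L, 3L, 4L),
                                  count = c(0L, 0L, 0L))))
    }
    byClass <- as.data.frame(
        table(canonical_class = loci$canonicalClass,
              motif_length = loci$motifLength),
        responseName = "count", stringsAsFactors = FALSE)
    byClass$motif_length <- as.integer(byClass$motif_length)
    byClass <- byClass[byClass$count > 0, , drop = FALSE]
    byClass <- byClass[order(byClass$motif_length, byClass$canonical_class), ]
    rownames(byClass) <- NULL
    cnt <- vapply(2:4, function(m) sum(loci$motifLength == m), 0L)
    list(byClass = byClass,
         byLength = data.frame(motif_length = c(2L, 3L, 4L), count = cnt))
}
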
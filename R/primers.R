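#' Default primer screening constraints
#'
#' The screen is a deliberately simple, fully specified surrogate for a
#' thermodynamic designer: fixed length and GC windows, Wallace-rule melting
#' temperature (`Tm = 2(A+T) + 4(G+C)` degrees C), a 100-400 bp product-size
#' window spanning the full SSR, and no masked base inside a primer. It is
#' not Primer3-equivalent and does not model hairpins or dimers.
#'
#' @param primerLen integer range of primer lengths (nt)
#' @param gc numeric range of allowed GC fraction
#' @param tm numeric range of allowed Wallace Tm (degrees C)
#' @param product numeric range of allowed product sizes (bp)
#' @param maxCandidates cap on candidates returned per locus
#' @return a named list of constraints for [screenPrimers()]
#' @export
primerConstraints <- function(primerLen = c(18L, 27L),
                              gc = c(0.40, 0.60),
                              tm = c(50, 65),
                              product = c(100L, 400L),
                              maxCandidates = 20L) {
    list(primerLen = as.integer(primerLen), gc = gc, tm = tm,
         product = as.numeric(product), maxCandidates = as.integer(maxCandidates))
}

.revComp <- function(s) {
    as.character(reverseComplement(DNAString(toupper(s))))
}

#' Extract SSR flanking sequence
#'
#' Returns up to `maxFlank` bp of flank on each side of a locus, truncated at
#' the first masked base (lowercase or `N`) so that returned flanks are fully
#' unmasked. The left flank is reported 5'->3' on the forward strand; the
#' right flank is reported 5'->3' on the reverse strand (reverse-complemented),
#' i.e. both flanks read toward the repeat as a primer would.
#'
#' @param record a single scaffold as a [Biostrings::BString]-like object or
#'   character string
#' @param locus a length-1 [GenomicRanges::GRanges] lying within the record
#' @param maxFlank maximum flank length in bp (default 400)
#' @return list with elements `left` and `right` (character; possibly empty
#'   at scaffold edges)
#' @export
extractFlanks <- function(record, locus, maxFlank = 400L) {
    seq <- as.character(record)
    stopifnot(length(locus) == 1)
    s <- start(locus); e <- end(locus); n <- nchar(seq)
    if (s < 1 || e > n) stop("locus out of scaffold bounds")
    chars <- strsplit(seq, "", fixed = TRUE)[[1]]
    masked <- chars %in% c("a", "c", "g", "t", "n", "N")
    ls <- max(1L, s - maxFlank)
    left <- if (s > 1) chars[ls:(s - 1L)] else character()
    if (length(left)) {
        mk <- which(masked[ls:(s - 1L)])
        if (length(mk)) left <- left[seq_along(left) > max(mk)]
    }
    re <- min(n, e + maxFlank)
    right <- if (e < n) chars[(e + 1L):re] else character()
    if (length(right)) {
        mk <- which(masked[(e + 1L):re])
        if (length(mk)) right <- right[seq_along(right) < min(mk)]
    }
    leftStr <- paste(left, collapse = "")
    rightStr <- paste(right, collapse = "")
    list(left = leftStr,
         right = if (nzchar(rightStr)) .revComp(rightStr) else rightStr)
}

.primerStats <- function(seqsMat) {
    # seqsMat: character matrix of single bases, one primer per row
    gcn <- rowSums(seqsMat == "G" | seqsMat == "C")
    atn <- rowSums(seqsMat == "A" | seqsMat == "T")
    list(gc = gcn / ncol(seqsMat), tm = 2 * atn + 4 * gcn)
}

#' Screen primer candidates flanking an SSR locus
#'
#' Enumerates every forward/reverse primer pair whose amplicon spans the full
#' SSR and satisfies the constraint set (see [primerConstraints()]), ranked
#' by product size closest to the middle of the product window (250 bp for
#' the default 100-400 bp window) and then by the smallest forward/reverse Tm
#' difference. Compound SSR loci are refused: no primers are designed for
#' compound SSRs.
#'
#' @param record one scaffold (character or [Biostrings::BString]-like)
#' @param locus a length-1 [GenomicRanges::GRanges] with a `compound` column
#' @param constraints list from [primerConstraints()]
#' @return data.frame with one row per candidate: `forward_seq`,
#'   `reverse_seq` (5'->3' on the reverse strand), `forward_start`,
#'   `reverse_end` (1-based scaffold coordinates of the amplicon ends),
#'   `product_size`, `gc_forward`, `gc_reverse`, `tm_forward`, `tm_reverse`.
#'   Zero rows when no pair satisfies the constraints.
#' @export
screenPrimers <- function(record, locus, constraints = primerConstraints()) {
    stopifnot(length(locus) == 1)
    if (!is.null(locus$compound) && isTRUE(locus$compound))
        stop("compound SSR: primers are not designed for compound loci")
    seq <- as.character(record)
    n <- nchar(seq)
    s <- start(locus); e <- end(locus)
    if (s < 1 || e > n) stop("locus out of scaffold bounds")
    chars <- strsplit(seq, "", fixed = TRUE)[[1]]
    masked <- chars %in% c("a", "c", "g", "t", "n", "N")
    up <- toupper(chars)
    empty <- data.frame(forward_seq = character(), reverse_seq = character(),
                        forward_start = integer(), reverse_end = integer(),
                        product_size = integer(), gc_forward = numeric(),
                        gc_reverse = numeric(), tm_forward = numeric(),
                        tm_reverse = numeric())
    fwd <- .sidePrimers(up, masked, lo = max(1L, s - 400L), hi = s - 1L,
                        constraints)
    rev <- .sidePrimers(up, masked, lo = e + 1L, hi = min(n, e + 400L),
                        constraints)
    if (nrow(fwd) == 0 || nrow(rev) == 0) return(empty)
    grid <- expand.grid(f = seq_len(nrow(fwd)), r = seq_len(nrow(rev)))
    psize <- rev$end[grid$r] - fwd$start[grid$f] + 1L
    ok <- psize >= constraints$product[1] & psize <= constraints$product[2]
    if (!any(ok)) return(empty)
    grid <- grid[ok, , drop = FALSE]; psize <- psize[ok]
    mid <- mean(constraints$product)
    tmF <- fwd$tm[grid$f]; tmR <- rev$tm[grid$r]
    o <- order(abs(psize - mid), abs(tmF - tmR),
               fwd$start[grid$f], rev$end[grid$r])
    o <- utils::head(o, constraints$maxCandidates)
    grid <- grid[o, , drop = FALSE]
    data.frame(
        forward_seq = fwd$seq[grid$f],
        reverse_seq = vapply(rev$seq[grid$r], .revComp, "", USE.NAMES = FALSE),
        forward_start = fwd$start[grid$f],
        reverse_end = rev$end[grid$r],
        product_size = psize[o],
        gc_forward = fwd$gc[grid$f],
        gc_reverse = rev$gc[grid$r],
        tm_forward = fwd$tm[grid$f],
        tm_reverse = rev$tm[grid$r],
        row.names = NULL
    )
}

# Enumerate constraint-satisfying primer windows inside [lo, hi] (forward
# strand coordinates). Returns start/end/seq/gc/tm per window.
.sidePrimers <- function(up, masked, lo, hi, constraints) {
    none <- data.frame(start = integer(), end = integer(), seq = character(),
                       gc = numeric(), tm = numeric())
    if (hi < lo) return(none)
    res <- list()
    for (L in seq(constraints$primerLen[1], constraints$primerLen[2])) {
        if (hi - L + 1L < lo) next
        starts <- seq.int(lo, hi - L + 1L)
        ends <- starts + L - 1L
        # drop windows containing a masked base
        cm <- cumsum(masked)
        nmask <- cm[ends] - c(0, cm)[starts]
        keep <- nmask == 0
        if (!any(keep)) next
        starts <- starts[keep]; ends <- ends[keep]
        mat <- matrix(up[rep(starts, each = L) + seq_len(L) - 1L],
                      ncol = L, byrow = TRUE)
        st <- .primerStats(mat)
        ok <- st$gc >= constraints$gc[1] & st$gc <= constraints$gc[2] &
              st$tm >= constraints$tm[1] & st$tm <= constraints$tm[2]
        if (!any(ok)) next
        res[[length(res) + 1L]] <- data.frame(
            start = starts[ok], end = ends[ok],
            seq = vapply(which(ok), function(i)
                paste(mat[i, ], collapse = ""), ""),
            gc = st$gc[ok], tm = st$tm[ok])
    }
    if (length(res)) do.call(rbind, res) else none
}
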
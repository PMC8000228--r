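#' Fit a per-locus allele-binning offset
#'
#' Raw capillary-electrophoresis fragment sizes drift off the integer
#' motif-length grid by a locus-specific offset. The offset `phi` in
#' `[0, m)` is fitted by grid search (step `gridStep` bp) minimizing the sum
#' of squared circular deviations of the sizes from the grid
#' `phi + k * m`; ties break toward the smallest `phi`.
#'
#' @param sizes numeric vector of raw fragment sizes (bp), at least one
#' @param m motif length (2, 3 or 4)
#' @param locusId optional locus identifier recorded in the model
#' @param gridStep grid-search resolution in bp (default 0.05)
#' @return a \linkS4class{BinModel}; `binCenters` are the grid classes
#'   realized in `sizes`, `quality` the largest circular deviation observed
#' @examples
#' fitBinOffset(c(200.4, 202.4, 206.4), m = 2)
#' @export
fitBinOffset <- function(sizes, m, locusId = "locus", gridStep = 0.05) {
    if (length(sizes) == 0 || all(is.na(sizes)))
        stop("at least one fragment size is required")
    stopifnot(m %in% 2:4)
    sizes <- sizes[!is.na(sizes)]
    if (any(sizes <= 0)) stop("fragment sizes must be strictly positive")
    phis <- seq(0, m, by = gridStep)
    phis <- phis[phis < m - 1e-9]
    dev <- function(phi) {
        r <- (sizes - phi) %% m
        pmin(r, m - r)
    }
    score <- vapply(phis, function(phi) sum(dev(phi)^2), 0)
    phi <- phis[which.min(score)]          # first minimum = smallest phi
    centers <- phi + m * round((sizes - phi) / m)
    new("BinModel",
        locusId = as.character(locusId),
        motifLength = as.integer(m),
        offset = phi,
        binCenters = sort(unique(centers)),
        quality = max(dev(phi)))
}

#' Assign fragment sizes to integer allelic classes
#'
#' Each size is snapped to the fitted grid: the label is
#' `round(phi + m * round((size - phi) / m))`. A size farther than `m/2` from
#' every class realized when the model was fitted is still labeled but
#' flagged off-grid rather than silently accepted — off-grid calls surface
#' sizing failures.
#'
#' @param sizes numeric vector of fragment sizes (bp); `NA` passes through
#' @param model a \linkS4class{BinModel} for the same motif length
#' @return integer vector of allele labels with a logical attribute
#'   `offGrid` marking flagged calls
#' @export
assignAlleles <- function(sizes, model) {
    stopifnot(is(model, "BinModel"))
    phi <- model@offset; m <- model@motifLength
    labels <- as.integer(round(phi + m * round((sizes - phi) / m)))
    off <- rep(FALSE, length(sizes))
    ok <- !is.na(sizes)
    if (length(model@binCenters) && any(ok)) {
        d <- abs(outer(sizes[ok], model@binCenters, "-"))
        off[ok] <- apply(d, 1, min) > m / 2
    }
    attr(labels, "offGrid") <- off
    labels
}

#' Bin a raw fragment-size panel into a genotype matrix
#'
#' Fits an independent \linkS4class{BinModel} per locus, assigns every size
#' pair to integer allelic classes, and returns the binned diploid genotype
#' panel. Loci with no non-missing sizes are dropped with a warning. The
#' fitted models and a per-locus report (offset, number of classes, allele
#' size range, max deviation, off-grid count) are carried in
#' `metadata(result)`.
#'
#' @param panel a \linkS4class{RawSizePanel}
#' @param motifLengths named integer vector mapping every locus id in the
#'   panel to its motif length (2, 3 or 4)
#' @param gridStep grid-search resolution passed to [fitBinOffset()]
#' @return an \linkS4class{SsrGenotypes}; `metadata(x)$binModels` is a named
#'   list of \linkS4class{BinModel}s and `metadata(x)$binReport` a data.frame
#' @export
binPanel <- function(panel, motifLengths, gridStep = 0.05) {
    stopifnot(is(panel, "RawSizePanel"))
    loci <- rownames(panel)
    miss <- setdiff(loci, names(motifLengths))
    if (length(miss))
        stop("no motif length configured for locus: ",
             paste(miss, collapse = ", "))
    s1 <- assay(panel, "s1"); s2 <- assay(panel, "s2")
    keep <- rowSums(!is.na(s1)) > 0
    if (any(!keep))
        warning("dropping loci with no genotyped samples: ",
                paste(loci[!keep], collapse = ", "))
    loci <- loci[keep]
    a1 <- a2 <- matrix(NA_integer_, length(loci), ncol(panel),
                       dimnames = list(loci, colnames(panel)))
    models <- list()
    rep_rows <- list()
    for (lc in loci) {
        m <- as.integer(motifLengths[[lc]])
        sz <- c(s1[lc, ], s2[lc, ])
        model <- fitBinOffset(sz, m, locusId = lc, gridStep = gridStep)
        l1 <- assignAlleles(s1[lc, ], model)
        l2 <- assignAlleles(s2[lc, ], model)
        a1[lc, ] <- pmin(l1, l2)
        a2[lc, ] <- pmax(l1, l2)
        nOff <- sum(attr(l1, "offGrid")) + sum(attr(l2, "offGrid"))
        models[[lc]] <- model
        rng <- range(model@binCenters)
        rep_rows[[lc]] <- data.frame(
            locus = lc, motif_length = m, offset = model@offset,
            n_classes = length(model@binCenters),
            size_min = round(rng[1]), size_max = round(rng[2]),
            size_range = round(rng[2]) - round(rng[1]),
            max_deviation = model@quality, n_off_grid = nOff)
    }
    g <- SsrGenotypes(a1, a2)
    metadata(g)$binModels <- models
    metadata(g)$binReport <- do.call(rbind, c(rep_rows, make.row.names = FALSE))
    g
}
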
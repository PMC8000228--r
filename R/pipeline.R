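#' @importFrom stats setNames runif rnorm complete.cases
NULL

#' Published per-locus summary of the 15 V. farreri gSSR markers
#'
#' The published per-locus characteristics of the 15 genomic SSR markers
#' (motif, allele size range, number of alleles, percent missing data,
#' Shannon's diversity index, observed and expected heterozygosity over the
#' clone-corrected 19-sample panel), shipped as a plain-text reference table.
#' The underlying genotype matrix is not public, so this table is annotation
#' and reference only.
#'
#' @return data.frame with one row per marker locus
#' @export
vf20ReferenceSummary <- function() {
    path <- system.file("extdata", "vf20_locus_reference.tsv",
                        package = "ssrmarkers", mustWork = TRUE)
    read.delim(path, stringsAsFactors = FALSE)
}

#' Default per-locus allele frequency specification for simulations
#'
#' Builds a 15-locus frequency specification emulating the published marker
#' panel: the per-locus allele counts (2-8, 67 alleles in total), allele
#' labels on each locus's motif-length grid starting at its published minimum
#' size, and geometrically decaying allele frequencies (ratio `decay`), which
#' gives the uneven spectra typical of SSR data.
#'
#' @param decay geometric decay of successive allele frequencies (default 0.6)
#' @return named list suitable for [simulateGenotypes()]; attribute
#'   `motifLengths` maps each locus to its motif length and `offsets` to 0
#' @export
referenceFreqSpec <- function(decay = 0.6) {
    ref <- vf20ReferenceSummary()
    spec <- list()
    for (i in seq_len(nrow(ref))) {
        N <- ref$N[i]
        m <- nchar(ref$motif[i])
        labels <- ref$size_min[i] + m * (seq_len(N) - 1)
        p <- decay^(seq_len(N) - 1)
        spec[[ref$locus[i]]] <- setNames(p / sum(p), labels)
    }
    attr(spec, "motifLengths") <- setNames(nchar(ref$motif), ref$locus)
    spec
}

#' Pipeline run configuration
#'
#' Collects every tunable parameter with its default: mining thresholds
#' (minimum 6 copies for di- and tri-nucleotide motifs, 4 for
#' tetra-nucleotide), the 15 bp compound-SSR gap, the 100-400 bp primer
#' product window, the 0.05 bp binning grid step, permutation count, seed,
#' and reporting precision.
#'
#' @param seed single integer driving every stochastic stage
#' @param outDir directory for artifacts (created if absent)
#' @param minRepeats named minimum repeat counts per motif length
#' @param compoundGap compound-SSR maximum gap (bp, exclusive)
#' @param primer constraint list from [primerConstraints()]
#' @param gridStep allele-binning grid resolution (bp)
#' @param nPerm permutations for the LD test
#' @param nSamples,fis,missingRate,noiseSd,linkedPairs genotype/sizing
#'   simulation parameters (defaults emulate the study panel: 19 unique
#'   multilocus genotypes plus one clone, heterozygote deficit, ~4% missing
#'   data, one linked locus pair)
#' @param digits decimals in written reports
#' @return a `list` of configuration values for [runPipeline()]
#' @export
runConfig <- function(seed = 1L,
                      outDir = tempfile("ssr_run_"),
                      minRepeats = c("2" = 6L, "3" = 6L, "4" = 4L),
                      compoundGap = 15L,
                      primer = primerConstraints(),
                      gridStep = 0.05,
                      nPerm = 999L,
                      nSamples = 19L,
                      fis = 0.6,
                      missingRate = 0.039,
                      noiseSd = 0.25,
                      linkedPairs = list(list("VF20_37", "VF20_44", 0.8)),
                      digits = 2) {
    list(seed = as.integer(seed), outDir = outDir, minRepeats = minRepeats,
         compoundGap = as.integer(compoundGap), primer = primer,
         gridStep = gridStep, nPerm = as.integer(nPerm),
         nSamples = as.integer(nSamples), fis = fis,
         missingRate = missingRate, noiseSd = noiseSd,
         linkedPairs = linkedPairs, digits = digits)
}

#' Run the full simulate-mine-screen-bin-stats-LD pipeline
#'
#' One-command demonstration run: simulates scaffolds with planted SSRs,
#' mines and screens them; simulates a diploid genotype panel (the configured
#' number of unique multilocus genotypes plus one clone) under the reference
#' frequency specification, adds sizing noise, bins the raw sizes back to
#' allelic classes, clone-corrects, and writes the per-locus diversity
#' summary and the pairwise rbarD table. All randomness flows from
#' `config$seed`; identical configuration and seed reproduce identical
#' artifacts.
#'
#' @param config list from [runConfig()]
#' @param quiet suppress progress messages (default TRUE)
#' @return invisibly, a named list of artifact file paths plus the in-memory
#'   results (`catalog`, `primers`, `genotypes`, `summary`, `ld`)
#' @export
runPipeline <- function(config = runConfig(), quiet = TRUE) {
    dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
    say <- function(...) if (!quiet) message("[ssrmarkers] ", ...)
    paths <- list()
    say("seed = ", config$seed)

    ## genome stage: simulate -> mine -> compound -> screen
    sim <- simulateGenome(nScaffolds = 5L, scaffoldLen = 2000L,
                          spec = ssrSpec(compoundFraction = 0.2),
                          seed = config$seed)
    catalog <- flagCompound(findSSRs(sim$scaffolds, config$minRepeats),
                            maxGap = config$compoundGap)
    paths$catalog <- file.path(config$outDir, "catalog.tsv")
    writeSsrCatalog(catalog, paths$catalog)
    motifSummary <- tabulateMotifs(catalog)
    paths$motifs <- file.path(config$outDir, "motifs.tsv")
    write.table(motifSummary$byClass, paths$motifs, sep = "\t",
                quote = FALSE, row.names = FALSE)
    say(length(catalog), " SSRs mined")
    primers <- list()
    for (i in seq_along(catalog)) {
        loc <- catalog[i]
        if (isTRUE(loc$compound)) next
        sc <- as.character(GenomicRanges::seqnames(loc))
        cand <- screenPrimers(sim$scaffolds[[sc]], loc, config$primer)
        if (nrow(cand)) {
            cand <- cbind(locus_id = paste0(sc, "_", start(loc)),
                          scaffold = sc, ssr_start = start(loc),
                          ssr_end = end(loc), cand)
            primers[[length(primers) + 1L]] <- utils::head(cand, 1)
        }
    }
    primers <- if (length(primers)) do.call(rbind, primers) else NULL
    paths$primers <- file.path(config$outDir, "primers.tsv")
    if (!is.null(primers))
        write.table(primers, paths$primers, sep = "\t", quote = FALSE,
                    row.names = FALSE)
    say(if (is.null(primers)) 0 else nrow(primers), " loci with primers")

    ## genotype stage: simulate -> sizes -> bin -> clone-correct -> stats/LD
    freqSpec <- referenceFreqSpec()
    gsim <- simulateGenotypes(config$nSamples, freqSpec, fis = config$fis,
                              missingRate = config$missingRate,
                              linkedPairs = config$linkedPairs,
                              seed = config$seed + 1L)
    geno <- gsim$genotypes
    # append one clone of the first sample: clone correction must remove it
    a1 <- cbind(assay(geno, "a1"), clone = assay(geno, "a1")[, 1])
    a2 <- cbind(assay(geno, "a2"), clone = assay(geno, "a2")[, 1])
    colnames(a1)[ncol(a1)] <- colnames(a2)[ncol(a2)] <- "S_clone"
    geno <- SsrGenotypes(a1, a2)
    sizes <- simulateFragmentSizes(geno, noiseSd = config$noiseSd,
                                   seed = config$seed + 2L)
    paths$sizes <- file.path(config$outDir, "sizes.csv")
    writeSizePanel(sizes, paths$sizes)
    binned <- binPanel(sizes, attr(freqSpec, "motifLengths"),
                       gridStep = config$gridStep)
    paths$binReport <- file.path(config$outDir, "binmodels.tsv")
    write.table(metadata(binned)$binReport, paths$binReport, sep = "\t",
                quote = FALSE, row.names = FALSE)
    cc <- cloneCorrect(binned)
    say(ncol(binned), " samples -> ", ncol(cc), " after clone correction")
    paths$genotypes <- file.path(config$outDir, "genotypes.csv")
    writeGenotypes(cc, paths$genotypes)
    summ <- summarizeLoci(cc)
    paths$summary <- file.path(config$outDir, "summary.tsv")
    writeLocusSummary(summ, paths$summary, digits = config$digits)
    ld <- pairwiseRbarD(cc)
    pv <- matrix(NA_real_, nrow(ld), ncol(ld), dimnames = dimnames(ld))
    top <- ldPermutationTest(cc, nPerm = config$nPerm,
                             seed = config$seed + 3L)
    paths$ld <- file.path(config$outDir, "rbard.tsv")
    writeLdTable(ld, paths$ld, pvals = pv)
    say(sprintf("overall rbarD = %.3f (p = %.3g)", top@rbarD, top@pValue))

    invisible(list(paths = paths, catalog = catalog, primers = primers,
                   genotypes = cc, summary = summ, ld = ld, overall = top))
}
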
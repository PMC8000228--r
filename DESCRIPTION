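Package: ssrmarkers
Title: Genomic SSR Marker Mining, Allele Binning, and Diversity Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reusable pipeline for developing and characterizing genomic
    simple sequence repeat (SSR) markers from assembled scaffolds. Mines
    perfect di-, tri- and tetra-nucleotide repeats from soft-masked FASTA,
    flags compound SSRs, screens primer-flank candidates under a product-size
    window, statistically bins raw capillary-electrophoresis fragment sizes
    into allelic classes on the motif-length grid, clone-corrects multilocus
    genotypes, and computes per-locus diversity indices (number of alleles,
    percent missing, Shannon's diversity index, observed heterozygosity and
    Nei's unbiased expected heterozygosity) together with multilocus linkage
    disequilibrium via the index of association and its standardized form
    rbarD with a permutation null. A seeded synthetic-data generator produces
    scaffolds with planted repeats, diploid genotype panels and noisy
    fragment-size tables so every stage can be verified against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
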
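---
title: "Developing and characterizing genomic SSR markers with ssrmarkers"
author: "ssrmarkers authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Developing and characterizing genomic SSR markers with ssrmarkers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssrmarkers)
```

# Scope and model

`ssrmarkers` implements the computational side of genomic simple sequence
repeat (SSR, microsatellite) marker development for a diploid plant
collection: mining perfect tandem repeats from assembled scaffolds,
screening primer flanks, converting raw capillary-electrophoresis fragment
sizes into integer allelic classes, and characterizing the resulting
markers with standard population-genetic diversity and linkage
disequilibrium statistics. The reference use case is a small panel of
di-, tri- and tetra-nucleotide markers genotyped on ~20 cultivated
accessions of a woody ornamental (*Viburnum farreri*), but every stage is
generic.

Because the original sequencing reads and genotype matrix of such studies
are rarely re-analysable at desk scale, the package pairs every stage with
a seeded synthetic-data generator that produces inputs with known truth.
All verification in the test suite runs against planted truth or against
independent brute-force oracles.

# SSR mining

`findSSRs()` scans each scaffold (forward strand) for maximal perfect runs
with period 2, 3 or 4. The thresholds are the conventional ones for
genomic SSR discovery and are the package defaults: at least **6** whole
unit copies for di- and tri-nucleotide motifs and at least **4** for
tetra-nucleotide motifs. Three rules make the scan well-defined:

* **Shortest-period reporting.** A run is reported once, under its
  primitive motif: twelve `AT` units are one di-nucleotide SSR, never a
  tetra-nucleotide `ATAT` repeat, and homopolymers are never motifs.
* **Masked bases break runs.** Lowercase (soft-masked) bases and `N` both
  count as masked; a perfect run may not contain any. This respects
  low-complexity masking applied upstream (e.g. DustMasker) — the package
  accepts masked input as given and does not mask itself.
* **Whole copies only.** A partial trailing unit does not extend the
  reported locus or its repeat count.

Class tabulation uses the canonical motif label: the lexicographic minimum
over cyclic rotations of the motif and of its reverse complement, so `TA`,
`AT` and their complements all count as the `AT` class, and class counts
are strand-symmetric even though scanning is strand-fixed.

Two SSRs separated by fewer than **15 bp** form a compound SSR
(`flagCompound()`, strict inequality, chains propagate). Compound SSRs are
kept in catalogs and class counts but are excluded from primer design,
matching usual marker-development practice.

```{r mine}
sim <- simulateGenome(nScaffolds = 2, scaffoldLen = 1000,
                      spec = ssrSpec(perScaffold = 2), seed = 7)
findSSRs(sim$scaffolds)
```

# Primer screening

`screenPrimers()` is a deliberately transparent surrogate for a
thermodynamic primer designer, not a Primer3 replacement. A candidate pair
must satisfy, with defaults chosen as a conservative screening window:

| parameter | default | unit |
|---|---|---|
| primer length | 18–27 | nt |
| GC fraction | 0.40–0.60 | — |
| Wallace Tm `2(A+T) + 4(G+C)` | 50–65 | °C |
| product size (spanning the full SSR) | 100–400 | bp |
| masked bases in a primer | none | — |

The product-size window is the one used in the reference marker panel.
Candidates are ranked deterministically: product size closest to the
window midpoint (250 bp), then the smallest forward/reverse Tm difference;
at most 20 candidates are returned per locus. The Wallace rule was chosen
over nearest-neighbour thermodynamics because it is fully specified and
dependency-free; the tests verify only properties that hold regardless of
the Tm model (constraint satisfaction, unique in-silico amplification at
the stated product size).

# Allele binning

Fragment sizes reported by capillary electrophoresis drift off the integer
grid by a locus-specific offset. `fitBinOffset()` models a locus's allele
sizes as `offset + k * m` (motif length `m`), fitting the offset by grid
search over `[0, m)` in **0.05 bp** steps, minimizing the summed squared
circular deviation of the sizes from the grid; ties break to the smallest
offset. The grid step is far below any real sizing precision, so the
discretization never limits recovery. `assignAlleles()` snaps sizes to the
fitted grid; a size farther than `m/2` from every class realized during
fitting is labeled but *flagged off-grid*, never silently accepted —
surfacing the inconsistent-amplification failures that lead loci to be
excluded in practice. Each locus is fitted independently; no cross-locus
information is shared, and no per-locus repeat "stretch" (non-integer
grid spacing) is modelled.

Under the simulator's sizing model (`size = offset + label + N(0, sd)`),
binning recovers ≥ 99% of planted labels at `sd = m/6`, and is exact when
`sd = 0`; both properties are asserted in the test suite.

# Diversity statistics

`cloneCorrect()` removes repeated multilocus genotypes (equality at every
locus, including missing-status), keeping the first occurrence in input
order for determinism. Per locus, `summarizeLoci()` reports:

* `N` — number of distinct alleles;
* missing % — `100 * missing / samples`;
* Shannon's diversity index `H' = -Σ p_i ln p_i` (natural log, nats) over
  allele frequencies;
* observed heterozygosity `Ho` — the heterozygous fraction of genotyped
  samples;
* Nei's **unbiased** expected heterozygosity
  `He = (2n / (2n - 1)) (1 - Σ p_i²)`, `n` the number of genotyped
  individuals at the locus.

Missing genotypes are excluded locus-wise (pairwise deletion), so `n`
varies by locus. The unbiased correction and the natural-log convention
were chosen because they reproduce the printed worked examples of the
reference marker table exactly (e.g. 17 homozygotes + 2 heterozygotes of
19 gives `H' = 0.21`, `He = 0.10`; 12 + 7 opposite homozygotes gives
`H' = 0.66`, `He = 0.48`); the biased form `1 - Σp²` cannot. The unbiased
estimator equals the probability that two allele copies drawn *without*
replacement differ, an identity the tests check against exhaustive
enumeration. Values are kept at full precision internally and rounded (2
decimals by default) only when written.

```{r worked}
g46 <- SsrGenotypes(a1 = matrix(rep(203L, 19), 1),
                    a2 = matrix(c(rep(203L, 17), 205L, 205L), 1))
sp <- alleleFrequencies(g46, 1)
round(c(Hprime = shannonIndex(sp), Ho = observedHet(g46, 1),
        He = expectedHet(sp)), 2)
```

# Linkage disequilibrium

Marker panels are only useful for diversity work if loci assort
independently, so the package tests multilocus association with the index
of association and its standardized form. The per-locus distance between
two diploid samples is half the number of unshared allele copies
(0, 0.5 or 1). Over all sample pairs observed at every locus of the
evaluated subset (complete-pair deletion, keeping the observed and
expected variances on the same support):

* `I_A = V_O / V_E - 1`, where `V_O` is the variance of the summed
  per-locus distances and `V_E = Σ_j var_j` its no-association
  expectation;
* `r̄d = Σ_{j<k} cov_jk / Σ_{j<k} sqrt(var_j var_k)`, which corrects
  `I_A`'s growth with the number of loci and lies in `[-1, 1]`.

Variances and covariances use the population sum-of-squares form over the
`n(n-1)/2` sample pairs; the common divisor cancels in both ratios. A
locus with zero distance variance makes the statistic undefined and is
signalled as a typed error (`ssrZeroVarianceError`), propagated as a
flagged `NA` cell by `pairwiseRbarD()` — never silently reported as 0.

`ldPermutationTest()` builds the null by independently shuffling each
locus's genotype column across samples, preserving per-locus allele and
missing composition while destroying inter-locus association. The p-value
is one-sided upper-tail with add-one correction,
`p = (1 + #{r̄d_perm ≥ r̄d_obs}) / (1 + n_perm)`, so `p` is never 0; LD
tests positive association, hence the one-sided form. The permutation
stream is fully determined by the `seed` argument.

```{r ld}
sim <- simulateGenotypes(40, list(A = c("100" = .5, "102" = .5),
                                  B = c("200" = .5, "204" = .5),
                                  C = c("300" = .5, "302" = .5)),
                         linkedPairs = list(list("A", "B", 0.9)), seed = 11)
round(pairwiseRbarD(sim$genotypes), 2)
```

# The synthetic-data generator

The generator defines the study conditions under which the package is
verified; its defaults are fixed, not tuning knobs.

* `simulateGenome()` — i.i.d. uniform background (GC = 0.5, which keeps
  accidental threshold-exceeding repeats vanishingly rare), planted
  primitive motifs at recorded coordinates, ≥ 20 bp apart unless planted
  as a compound pair (< 15 bp gap), with guard bases preventing a planted
  run from extending or phase-shifting into background; soft-masked
  stretches only in inter-SSR background.
* `simulateGenotypes()` — genotypes from stated allele frequencies with a
  heterozygote-deficit parameter `fis` (probability of duplicating a
  single draw), i.i.d. missingness, and optional linked pairs in which one
  locus copies another's draw with stated probability. Copying was chosen
  over gametic-phase simulation because it plants a target r̄d signal
  without needing a recombination model.
* `simulateFragmentSizes()` — `offset + label + N(0, sd)` per allele copy,
  independent draws for the two copies of a homozygote.

The pipeline demo (`runPipeline()`) emulates the reference study's shape:
15 loci with the published allele counts (67 alleles, 2–8 per locus),
geometrically decaying allele frequencies, 19 unique multilocus genotypes
plus one planted clone (removed again by clone correction), `fis = 0.6`
(the study panel's large He–Ho gap reflects cultivated, partly clonal
material), 3.9% missingness, sizing noise 0.25 bp, and one linked locus
pair with copy-probability 0.8. What the generator does **not** emulate:
real flanking-sequence composition, PCR stutter and allele dropout,
size-dependent sizing bias, and population structure — so green tests
demonstrate algorithmic correctness on the stated model, not robustness
to every artefact of real electrophoresis data.

# Numerical and design choices

* Coordinates are 1-based inclusive everywhere (`GRanges` convention,
  also the convention of every emitted file).
* Allele pairs are unordered; phase is never observed, so calls are stored
  sorted.
* The on-disk missing code is the literal string `NA` in genotype and
  size CSVs.
* Problem sizes in tests: planted-truth mining runs use 20–25 scaffolds of
  2–2.5 kb; oracle equivalence uses exhaustive enumeration on panels of
  ≤ 8 samples × ≤ 4 loci; null calibration uses 1000 two-locus panels of
  200 samples; binning recovery uses 1000 draws per motif length. These
  sizes give stable statistical checks while keeping the full suite fast.
* Known limitations: no imperfect/interrupted repeats, no mono- or
  penta-nucleotide motifs, no F-statistics or Hardy–Weinberg testing, no
  physical-linkage inference (an associated locus pair may or may not be
  physically close), and the primer screen is explicitly not
  Primer3-equivalent.
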
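---
title: "Characterizing a selfing-crop SNP panel: diversity, LD, structure and association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing a selfing-crop SNP panel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snppanel)
```

## Scope

`snppanel` characterizes diploid-coded biallelic SNP panels from small,
highly selfing crop diversity collections: a hundred-odd accessions, a few
thousand array markers, near-complete homozygosity, strong residual
population structure, and linkage disequilibrium that persists over
megabases. The workflow it supports runs: marker/sample QC, collection-level
nucleotide diversity, pairwise LD and its decay with physical distance,
confidence-interval haplotype blocks, admixture-model structure inference,
and mixed-linear-model association scans with multiple-testing thresholds
based on the effective number of independent tests. The numbered scripts
under `analysis/` drive the stages in that order on a fully synthetic panel;
every computation lives in the package and is unit-tested.

## Data model

A *genotype panel* is a plain pair: an integer matrix of samples x markers
with entries 0/1/2 counting alternate-allele copies (`NA` = missing, never
0), and a marker map (chromosome label, 1-based bp position, ref/alt
alleles) sorted by position. Heterozygous calls map to 1 regardless of
phasing. Chromosome labels are opaque strings, so any chromosome count
works. Re-polarizing dosages to count the minor allele is an explicit
operation (`polarize_to_minor()`), never an implicit side effect.

## Diversity statistics

Per marker we report allele frequency, MAF, observed heterozygosity,
gene diversity `2p(1-p)`, the biallelic Botstein polymorphic information
content `1 - p^2 - q^2 - 2p^2q^2` (bounded by 0.375; multi-allelic or
genotype-class PIC conventions used by some legacy software can exceed this
bound and are deliberately not reproduced), and the inbreeding coefficient
`f = 1 - Hobs/Hexp`, undefined at monomorphic sites.

Collection-level statistics treat each diploid as two sequences,
adjusted per site for missingness: per-site
`pi = n/(n-1) * 2p(1-p)`, Watterson's `theta = 1/a1` per segregating site
(per-SNP normalization, since array panels have no meaningful genomic
denominator), and Tajima's D with the 1989 constants evaluated at the
rounded mean per-site sequence count. Because diversity software differs in
whether `n` counts taxa or chromosomes, both conventions are exposed
(`n_convention`); chromosomes is the default. D is validated against an
independently coded direct-formula oracle and against a neutral-spectrum
simulation in which it centres on zero.

## LD estimation and decay

`r^2` between unphased markers uses EM-estimated haplotype frequencies
(the Haploview/TASSEL approach): double heterozygotes are split between
coupling and repulsion phases each iteration, to convergence `1e-8` or 100
iterations, with allele margins fixed. A composite dosage-correlation
estimator (`ld_r2_dosage()`) is provided only as a labelled cross-check.
Missingness is handled pairwise-complete; pairs monomorphic within the
complete subset are excluded as undefined. The windowed scan emits all
intra-chromosomal pairs within a 50-marker index window by default.

Decay is fitted by least squares of observed `r^2` against the drift-
recombination expectation

$$E[r^2] = \frac{10+C}{(2+C)(11+C)}\Big[1 + \frac{(3+C)(12+12C+C^2)}{n(2+C)(11+C)}\Big],\quad C = \rho d,$$

a 1-D optimization in `log10(rho)` from three starts (1e-9, 1e-7, 1e-5 per
bp), keeping the lowest RSS. Note the curve plateaus at the finite-sample
floor `~1/n`, not zero. The half-decay distance is defined relative to the
fitted curve's value at d = 0 (model-based, hence reproducible), solved by
bisection to 1 bp, as is the distance where the curve crosses `r^2 = 0.2`;
both are flagged when the target is not bracketed. `n` defaults to the
chromosome count (2 x samples) and is configurable. Background LD is the
90th percentile (linear interpolation) of `r^2` over a seeded sample of
interchromosomal pairs. The loess smooth is for plots only and never feeds
the decay distances. Binned summaries default to thirty log-spaced bins
from 0.10 kb to 100,000 kb (ratio about 1.61).

## Haplotype blocks

Blocks follow the Gabriel confidence-interval definition as implemented in
PLINK: per pair, the likelihood of the 3x3 unphased genotype table is
profiled over `|D'|` on a 0.001 grid with allele frequencies at their MLEs
and the sign of D fixed at the EM estimate; the normalized cumulative
likelihood gives a central 90% interval. Pairs are strong-LD when
`ci_low >= 0.70` and `ci_high >= 0.98`, recombination-evidence when
`ci_high < 0.90` (published PLINK defaults, all exposed). A candidate block
is a marker run within the span cap (2 Mb default) where at least 95% of
informative pairs are strong-LD; overlaps are resolved greedily by
descending span, ties to the leftmost start — Gabriel's paper leaves the
tie-break open, so we document PLINK's. The implementation is tested
against an exhaustive enumeration oracle on 12-SNP fixtures.

## Structure

Kinship uses the centered-IBS (VanRaden) scaling
`K = WW' / (2 sum p(1-p))` with mean-imputed missing dosages; fully inbred
panels sit near 2 on the diagonal. PCA is the SVD of the centered dosage
matrix with a deterministic sign convention. The admixture model maximizes
the binomial likelihood over ancestry proportions Q and ancestral
frequencies P by EM (best of 5 seeded restarts); the variational-Bayes
machinery of fastStructure is intentionally not reproduced — the likelihood
kernel is identical and the downstream use depends only on Q patterns and
the chosen K. K is selected by masking 5% of non-missing entries and
minimizing held-out binomial deviance (ties to the smaller K). Hard labels
for category tests are the argmax of Q; Fisher tests are exact for 2x2 or
small tables and seeded Monte Carlo (1e5 resamples) otherwise. IBS
distances (allele-sharing 1/0.5/0 per dosage difference 0/1/2) export as a
NEXUS DISTANCES block for SplitsTree-style network tools; network
construction itself is out of scope.

## Association

Trait preparation fits the random-genotype model
`value ~ environment (fixed) + (1 | genotype)` by REML (via `lme4`) and
uses the genotype BLUPs — shrunken, centered deviations — as the scan
phenotype. The mixed scan is EMMA with P3D: eigendecompose K once,
REML-optimize the variance ratio `delta = sigma2_e/sigma2_g` on the rotated
null likelihood, freeze the components, and test each marker by a
generalized-least-squares F-test; `marker_r2` is the marker's incremental
model R^2 on the whitened scale. With K = I the scan reduces exactly to
OLS (tested to 1e-6 in log10 p). Because P3D freezes the variance
components, single markers strongly aligned with leading kinship
eigenvectors can differ visibly from a full per-marker REML refit; the
typical marker agrees to a few thousandths of a log10 unit. "Compression"
(clustering individuals) is not implemented: at n ~ 110 it changes little
and adds untestable degrees of freedom. Per-observation weights are not
used.

Thresholds divide 1 (suggestive) and 0.05 (significant) by the effective
number of tests, computed by Li-Ji eigenvalue counting
`sum[I(lambda >= 1) + (lambda - floor(lambda))]` on per-chromosome marker
correlation matrices in windows of at most 500 markers; eigenvalues are
rounded to 8 decimals first because the counting rule is discontinuous at
integers. Candidate intervals around each significant marker run to the
nearest non-significant SNP on either side, and overlapping genes are
reported with signed distances in kb.

## The synthetic generator

`simulate_population()` emulates the structure of a bottlenecked, selfing,
admixed tetraploid-crop collection genotyped on a fixed array, with
defaults chosen once for realism at that scale: 110 samples, 2,000 markers
on 20 chromosomes of 100 Mb, five ancestral populations at Balding-Nichols
FST 0.25 around a shared Uniform(0.05, 0.5) spectrum, Dirichlet(0.2)
admixture, six selfing generations, 2% missing calls, and five unselfed
heterozygous outliers. LD comes from founder-mosaic copying, not a
coalescent: every founder haplotype descends from a pool of three shared
proto-haplotypes (the domestication bottleneck) with 10% per-site
divergence toward its population's frequencies, and gametes copy founder
segments with Poisson breakpoints at `recomb_per_bp` times 10 effective
historical generations. This puts the fitted half-decay on the Mb scale
with short-range `r^2` well above the interchromosomal background, and
halving `recomb_per_bp` approximately doubles the half-decay — the property
the tests rely on.

What the generator does *not* reproduce, and what passing tests therefore
do not show about real data: the realized mean MAF is ~0.20-0.25 (the
Balding-Nichols spread of a uniform spectrum), higher than the ~0.13 of a
real array panel whose content skews rare; Tajima's D on the synthetic
panel is strongly positive (structure inflates intermediate frequencies)
rather than near zero; short-range `r^2` tops out near 0.3 rather than
~0.9; and because the five subpopulations share most of their haplotypes by
construction, cross-validated K on the default panel tends to land below
the five truth components. Structure-inference accuracy is therefore
checked on unlinked Balding-Nichols panels (`simulate_bn_panel()`), where
truth is crisp, rather than on the bottleneck generator.
`simulate_traits()` adds planted QTL effects plus a polygenic term built
from small random marker effects, with the residual variance set to hit the
target per-plot heritability (default 0.7) over 3 environments.

## Numerical choices and degenerate inputs

Tolerances: EM haplotype frequencies converge at 1e-8; the admixture EM
stops at `|delta loglik| < 1e-4` (1e-3 in cross-validation); REML for the
variance ratio is optimized on `log delta` in [-10, 10] to 1e-8; decay
roots bisect to 1 bp. Ties: MAF filters are inclusive (`>=`); polarization
keeps the original polarity at p = 0.5; K selection prefers the smaller K.
Degenerate inputs error loudly rather than returning empty results: filters
that remove every marker, constant matrices in PCA, single-chromosome
background LD, strata below 10 samples. Monomorphic markers are dropped
from kinship with a warning and flagged (not zeroed) in `f` and D' CIs.

## Problem sizes

The test suite and the acceptance script size their simulations to run on
one CPU in a few minutes: the full pipeline fixture is 110 x 2,000; the
association calibration uses 2,000 unlinked markers; structure recovery
uses 90-150 samples x 300-400 markers with 2-3 restarts; cross-validated K
runs 5 replicates over K = 1..6. These sizes were chosen as the smallest at
which the distributional checks (type-I error bands, recovery rates) are
stable across seeds.

## Known limitations

Diploid dosage coding only — tetraploid subgenome ambiguity is assumed
resolved upstream, as on a curated array. No haplotype phasing, no
multi-locus association models, no permutation thresholds, no
Hardy-Weinberg tests. The Gabriel CI grid (step 0.001) matches PLINK's
resolution but makes single-pair CIs slightly grid-quantized. The deposited
collection's headline numbers depend on unstated software conventions
(taxa- vs chromosome-count n, window pooling); both conventions are
implemented, but reproducing those numbers requires the deposited genotypes
as input.
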
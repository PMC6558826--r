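Package: snppanel
Title: Diversity, Linkage Disequilibrium, Structure and Association Analysis of Crop SNP Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Population-genetic characterization of diploid-coded SNP genotype
    panels from highly selfing crop collections. Computes per-marker and
    per-sample descriptive statistics (minor allele frequency, polymorphic
    information content, observed and expected heterozygosity, inbreeding
    coefficients), collection-level nucleotide diversity (pi, Watterson's
    theta, Tajima's D), pairwise linkage disequilibrium from unphased
    genotypes via two-locus EM, nonlinear LD-decay fitting with the
    Hill-Weir expected-r2 curve, Gabriel confidence-interval haplotype
    blocks, centered-IBS kinship, an EM admixture model with cross-validated
    choice of the number of ancestral components, and mixed-linear-model
    genome-wide association scans with P3D variance components and
    effective-number-of-tests significance thresholds. Includes a seeded
    generator of structured, selfed, admixed synthetic panels so every
    analysis is exercisable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    vcfR,
    lme4,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
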
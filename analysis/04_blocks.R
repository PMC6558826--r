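#!/usr/bin/env Rscript
# Stage 4: Gabriel confidence-interval haplotype blocks at a 2 Mb span cap
# (PLINK-default thresholds), with the 50 Mb cap for comparison.

library(snppanel)

panel <- read_genotypes("results/data/panel.vcf", "vcf")
dir.create("results/blocks", showWarnings = FALSE, recursive = TRUE)

flt <- filter_markers(panel, min_known_alleles = 100, maf_min = 0.05)

for (cap in c(2000, 50000)) {
  blocks <- find_blocks(flt, max_span_kb = cap)
  s <- block_summary(blocks)
  write.table(blocks, sprintf("results/blocks/blocks_%dkb.tsv", cap),
              sep = "\t", row.names = FALSE, quote = FALSE)
  cat(sprintf(
    "cap %5.0f kb: %d blocks, mean span %.2f kb, %.1f SNPs/block, span range %.3f-%.0f kb\n",
    cap, s$n_blocks, s$mean_span_kb, s$mean_snps_per_block,
    if (s$n_blocks) min(blocks$span_bp) / 1000 else NA,
    if (s$n_blocks) max(blocks$span_bp) / 1000 else NA))
}
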
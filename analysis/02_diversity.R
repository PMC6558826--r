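#!/usr/bin/env Rscript
# Stage 2: marker- and sample-level descriptive statistics plus the
# collection-level diversity summary (pi, Watterson's theta, Tajima's D per
# assayed SNP), under both sequence-count conventions.

library(snppanel)

panel <- read_genotypes("results/data/panel.vcf", "vcf")
dir.create("results/diversity", showWarnings = FALSE, recursive = TRUE)

stats <- marker_summary(panel)
write.table(stats, "results/diversity/marker_stats.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
cat(sprintf("MAF: range %.3f-%.3f, mean %.3f\n", min(stats$maf),
            max(stats$maf), mean(stats$maf)))
cat(sprintf("PIC: range %.4f-%.3f, mean %.3f\n", min(stats$pic),
            max(stats$pic), mean(stats$pic)))
cat(sprintf("Markers with f = 1 (complete homozygosity): %.1f%%\n",
            100 * mean(stats$f > 0.999, na.rm = TRUE)))

het <- sample_heterozygosity(panel)
write.table(data.frame(sample = names(het), heterozygosity = het),
            "results/diversity/sample_heterozygosity.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
hi <- het[het > 0.10]
cat(length(hi), "accessions exceed 10% heterozygosity",
    sprintf("(max %.1f%%)\n", 100 * max(het)))

div <- rbind(cbind(convention = "chromosomes",
                   diversity_summary(panel, "chromosomes")),
             cbind(convention = "taxa", diversity_summary(panel, "taxa")))
write.table(div, "results/diversity/diversity_summary.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
cat(sprintf("pi = %.5f, theta = %.5f, Tajima's D = %.5f (chromosome count)\n",
            div$pi[1], div$theta_w[1], div$tajima_d[1]))
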
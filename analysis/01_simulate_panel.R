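#!/usr/bin/env Rscript
# Stage 1: generate the collection-like synthetic panel every later stage
# consumes: 110 accessions x 2,000 SNPs on 20 chromosomes, 5 admixed
# ancestral groups, 6 selfing generations, one planted moderate-effect QTL,
# 3-environment replicate traits. Writes genotypes (VCF), sample metadata,
# traits, a synthetic gene annotation around the QTL, and the truth record.

library(snppanel)

seed <- 20260924L
out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- sim_config(qtl = data.frame(marker_index = 1000L, effect = 0.8),
                  seed = seed)
sim <- simulate_population(cfg)
tt <- simulate_traits(sim$panel, cfg)

write_genotypes(sim$panel, file.path(out, "panel.vcf"), "vcf")
write.csv(sim$samples, file.path(out, "samples.csv"), row.names = FALSE)
write.csv(tt$traits, file.path(out, "traits.csv"), row.names = FALSE)

# synthetic annotation: genes tiled near the planted QTL plus decoys
qtl_row <- sim$panel$map[sim$panel$map$marker ==
                           sprintf("SNP%05d", 1000L), ]
genes <- data.frame(
  chrom = c(rep(qtl_row$chrom, 3), sim$panel$map$chrom[c(10, 500, 1500)]),
  type = "gene",
  start = c(qtl_row$pos + 356071L, qtl_row$pos - 120000L, qtl_row$pos - 500L,
            sim$panel$map$pos[c(10, 500, 1500)] + 50000L),
  id = c("synthetic.desaturase", "synthetic.thioesterase",
         "synthetic.monooxygenase", paste0("synthetic.decoy", 1:3)))
genes$end <- genes$start + 2500L
gff <- c("##gff-version 3",
         paste(genes$chrom, "synthetic", genes$type, genes$start, genes$end,
               ".", "+", ".", paste0("ID=", genes$id), sep = "\t"))
writeLines(gff, file.path(out, "genes_synthetic.gff3"))

jsonlite::write_json(
  list(seed = seed, qtl_marker = sprintf("SNP%05d", 1000L),
       qtl_effect = 0.8, K_true = cfg$K_true,
       outlier_samples = rownames(sim$panel$geno)[sim$truth$outliers],
       var_g = tt$truth$var_g, var_e = tt$truth$var_e),
  file.path(out, "truth.json"), auto_unbox = TRUE, digits = NA)

cat("Panel:", nrow(sim$panel$geno), "samples x", ncol(sim$panel$geno),
    "markers on", length(unique(sim$panel$map$chrom)), "chromosomes\n")
cat("Trait records:", nrow(tt$traits), "; planted QTL at marker SNP01000",
    "with effect 0.8\n")
cat("Wrote", out, "\n")
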
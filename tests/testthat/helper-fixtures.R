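# Shared fixture builders: tiny panels constructed in code, never on disk.

toy_panel <- function(geno, chrom = "c1", pos = NULL) {
  if (is.null(pos)) pos <- seq_len(ncol(geno)) * 1000L
  colnames(geno) <- paste0("m", seq_len(ncol(geno)))
  rownames(geno) <- paste0("s", seq_len(nrow(geno)))
  genotype_panel(geno, data.frame(marker = colnames(geno),
                                  chrom = rep_len(chrom, ncol(geno)),
                                  pos = pos))
}

# panel whose sites are drawn from the neutral frequency spectrum
# (P(count = i) proportional to 1/i over derived-allele counts), alleles
# paired randomly into diploids
neutral_sfs_panel <- function(n_samples, n_sites) {
  n_chr <- 2L * n_samples
  i <- 1:(n_chr - 1)
  counts <- sample(i, n_sites, replace = TRUE, prob = 1 / i)
  geno <- vapply(counts, function(k) {
    alleles <- sample(c(rep(1L, k), rep(0L, n_chr - k)))
    alleles[seq(1, n_chr, 2)] + alleles[seq(2, n_chr, 2)]
  }, integer(n_samples))
  toy_panel(geno)
}

# Hudson-style FST from two hard-assigned subpopulations
hudson_fst <- function(geno, labels) {
  stopifnot(length(unique(labels)) == 2)
  gs <- split.data.frame(geno, labels)
  p1 <- colMeans(gs[[1]], na.rm = TRUE) / 2
  p2 <- colMeans(gs[[2]], na.rm = TRUE) / 2
  n1 <- 2 * colSums(!is.na(gs[[1]]))
  n2 <- 2 * colSums(!is.na(gs[[2]]))
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  sum(num, na.rm = TRUE) / sum(den, na.rm = TRUE)
}

write_toy_gff3 <- function(path, rows) {
  lines <- c("##gff-version 3",
             vapply(seq_len(nrow(rows)), function(r)
               paste(rows$chrom[r], "synthetic", rows$type[r], rows$start[r],
                     rows$end[r], ".", "+", ".",
                     paste0("ID=", rows$id[r]), sep = "\t"), ""))
  writeLines(lines, path)
  path
}
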
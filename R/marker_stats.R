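# Per-marker / per-sample descriptive statistics and QC filters.

#' Per-marker summary statistics
#'
#' For every marker: alternate-allele frequency p over non-missing allele
#' copies (2 per genotyped sample), minor allele frequency, count of known
#' alleles, observed heterozygosity, expected heterozygosity (gene diversity
#' 2p(1-p)), polymorphic information content in the biallelic Botstein form
#' \eqn{PIC = 1 - p^2 - q^2 - 2 p^2 q^2}, and the within-population
#' inbreeding coefficient \eqn{f = 1 - Hobs/Hexp}.
#'
#' Monomorphic markers get PIC = 0 and \code{f = NA} (undefined when
#' Hexp = 0).
#'
#' @param panel genotype panel (or bare dosage matrix).
#' @return data.frame with one row per marker: \code{marker}, \code{p},
#'   \code{maf}, \code{n_known_alleles}, \code{hobs}, \code{hexp},
#'   \code{pic}, \code{f}.
#' @export
marker_summary <- function(panel) {
  geno <- if (is.list(panel)) panel$geno else panel
  n_geno <- colSums(!is.na(geno))
  if (any(n_geno == 0L)) stop("marker(s) with no non-missing calls")
  p <- colSums(geno, na.rm = TRUE) / (2 * n_geno)
  q <- 1 - p
  hobs <- colSums(geno == 1L, na.rm = TRUE) / n_geno
  hexp <- 2 * p * q
  pic <- 1 - p^2 - q^2 - 2 * p^2 * q^2
  f <- ifelse(hexp > 0, 1 - hobs / hexp, NA_real_)
  data.frame(marker = colnames(geno), p = p, maf = pmin(p, q),
             n_known_alleles = 2L * n_geno, hobs = hobs, hexp = hexp,
             pic = pic, f = f, row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-sample heterozygosity
#'
#' Fraction of heterozygous calls among non-missing markers for each sample.
#' Samples with no non-missing calls are returned as \code{NA} with a
#' warning.
#'
#' @param panel genotype panel (or bare dosage matrix).
#' @return named numeric vector in [0, 1], one entry per sample.
#' @export
sample_heterozygosity <- function(panel) {
  geno <- if (is.list(panel)) panel$geno else panel
  n <- rowSums(!is.na(geno))
  het <- rowSums(geno == 1L, na.rm = TRUE)
  out <- ifelse(n > 0L, het / n, NA_real_)
  if (anyNA(out)) warning("sample(s) with all calls missing: heterozygosity NA")
  names(out) <- rownames(geno)
  out
}

#' Filter markers on call completeness and minor allele frequency
#'
#' Retains markers with at least \code{min_known_alleles} non-missing allele
#' copies (two per genotyped diploid sample) and MAF >= \code{maf_min}; both
#' thresholds are inclusive. Marker order is preserved. A message reports
#' counts in/out.
#'
#' @param panel genotype panel.
#' @param min_known_alleles minimum non-missing allele copies (default 100,
#'   i.e. at least 50 genotyped samples).
#' @param maf_min minimum minor allele frequency (inclusive).
#' @return filtered genotype panel.
#' @export
filter_markers <- function(panel, min_known_alleles = 100, maf_min = 0.05) {
  stats <- marker_summary(panel)
  keep <- stats$n_known_alleles >= min_known_alleles & stats$maf >= maf_min
  if (!any(keep))
    stop("no markers pass filters (min_known_alleles = ", min_known_alleles,
         ", maf_min = ", maf_min, ")")
  message("filter_markers: ", sum(keep), " of ", length(keep),
          " markers retained (min_known_alleles >= ", min_known_alleles,
          ", MAF >= ", maf_min, ")")
  list(geno = panel$geno[, keep, drop = FALSE],
       map = {m <- panel$map[keep, , drop = FALSE]; rownames(m) <- NULL; m})
}

#' Re-polarize dosages to count the minor allele
#'
#' Per marker, if the alternate-allele frequency exceeds 0.5 the coding is
#' swapped (0 <-> 2, ref/alt exchanged in the map) so dosages count the minor
#' allele. Ties (p = 0.5) keep the original polarity; the operation is
#' idempotent.
#'
#' @param panel genotype panel.
#' @return genotype panel with MAF-polarized dosages.
#' @export
polarize_to_minor <- function(panel) {
  stats <- marker_summary(panel)
  flip <- stats$p > 0.5
  geno <- panel$geno
  geno[, flip] <- 2L - geno[, flip, drop = FALSE]
  map <- panel$map
  tmp <- map$ref[flip]; map$ref[flip] <- map$alt[flip]; map$alt[flip] <- tmp
  list(geno = geno, map = map)
}
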
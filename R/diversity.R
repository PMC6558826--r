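# Collection-level nucleotide diversity per assayed SNP: pi, Watterson's
# theta and Tajima's D, with diploid samples contributing two sequences each
# (heterozygotes one copy of each allele), adjusted per site for missingness.

#' Tajima (1989) normalizing constants
#'
#' @param n number of sequences (>= 2).
#' @return named list a1, a2, b1, b2, c1, c2, e1, e2.
#' @export
tajima_constants <- function(n) {
  if (n < 2) stop("need n >= 2 sequences")
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

site_counts <- function(geno, n_convention) {
  n_geno <- colSums(!is.na(geno))
  alt <- colSums(geno, na.rm = TRUE)
  p <- alt / (2 * n_geno)
  n_seq <- switch(n_convention, chromosomes = 2L * n_geno, taxa = n_geno)
  list(p = p, n_seq = n_seq)
}

#' Per-site nucleotide diversity (pi)
#'
#' Unbiased per-site heterozygosity \eqn{\hat\pi = n/(n-1) \cdot 2\hat p(1-\hat p)}
#' with n the number of non-missing sequences at the site, and its mean over
#' usable sites. Invariant under allele-polarity swaps. Sites with fewer than
#' two sequences are excluded with a warning.
#'
#' @param panel genotype panel (or bare dosage matrix).
#' @param n_convention count sequences as chromosomes (2 per sample, default)
#'   or as taxa (1 per sample); exposed because diversity software differs.
#' @return list with \code{per_site} (named vector) and \code{mean}.
#' @export
nucleotide_diversity_pi <- function(panel, n_convention = c("chromosomes", "taxa")) {
  n_convention <- match.arg(n_convention)
  geno <- if (is.list(panel)) panel$geno else panel
  sc <- site_counts(geno, n_convention)
  usable <- sc$n_seq >= 2
  if (!all(usable)) warning(sum(!usable), " site(s) with n < 2 excluded")
  n <- sc$n_seq[usable]; p <- sc$p[usable]
  pi <- (n / (n - 1)) * 2 * p * (1 - p)
  names(pi) <- colnames(geno)[usable]
  list(per_site = pi, mean = mean(pi))
}

#' Watterson's theta per segregating site
#'
#' With per-SNP normalization (L = S), \eqn{\theta = S/(a_1 L) = 1/a_1}
#' evaluated per site from the site's own sequence count, averaged over
#' segregating sites.
#'
#' @inheritParams nucleotide_diversity_pi
#' @return list with \code{per_site} (segregating sites only), \code{mean},
#'   and \code{S}.
#' @export
watterson_theta <- function(panel, n_convention = c("chromosomes", "taxa")) {
  n_convention <- match.arg(n_convention)
  geno <- if (is.list(panel)) panel$geno else panel
  sc <- site_counts(geno, n_convention)
  seg <- sc$p > 0 & sc$p < 1 & sc$n_seq >= 2
  if (!any(seg)) stop("no segregating sites: theta undefined")
  theta <- vapply(sc$n_seq[seg], function(n) 1 / tajima_constants(n)$a1, 0)
  names(theta) <- colnames(geno)[seg]
  list(per_site = theta, mean = mean(theta), S = sum(seg))
}

#' Tajima's D over the assayed sites
#'
#' \eqn{D = (\sum\pi - S/a_1) / \sqrt{e_1 S + e_2 S(S-1)}} with the Tajima
#' (1989) constants evaluated at the (rounded) mean per-site sequence count.
#' Negative values indicate an excess of rare alleles.
#'
#' @inheritParams nucleotide_diversity_pi
#' @return scalar D (NA with a warning if the variance term is zero).
#' @export
tajimas_d <- function(panel, n_convention = c("chromosomes", "taxa")) {
  n_convention <- match.arg(n_convention)
  geno <- if (is.list(panel)) panel$geno else panel
  sc <- site_counts(geno, n_convention)
  usable <- sc$n_seq >= 2
  n <- sc$n_seq[usable]; p <- sc$p[usable]
  S <- sum(p > 0 & p < 1)
  if (S < 1) stop("no segregating sites: D undefined")
  sum_pi <- sum((n / (n - 1)) * 2 * p * (1 - p))
  k <- tajima_constants(round(mean(n)))
  vr <- k$e1 * S + k$e2 * S * (S - 1)
  if (vr <= 0) { warning("zero variance term: D undefined"); return(NA_real_) }
  (sum_pi - S / k$a1) / sqrt(vr)
}

#' One-row diversity summary
#'
#' @inheritParams nucleotide_diversity_pi
#' @return data.frame with \code{n_seq} (mean per-site sequence count),
#'   \code{S}, \code{pi}, \code{theta_w}, \code{tajima_d}.
#' @export
diversity_summary <- function(panel, n_convention = c("chromosomes", "taxa")) {
  n_convention <- match.arg(n_convention)
  geno <- if (is.list(panel)) panel$geno else panel
  pi <- nucleotide_diversity_pi(geno, n_convention)
  th <- watterson_theta(geno, n_convention)
  d <- tajimas_d(geno, n_convention)
  sc <- site_counts(geno, n_convention)
  data.frame(n_seq = mean(sc$n_seq), S = th$S, pi = pi$mean,
             theta_w = th$mean, tajima_d = d)
}
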
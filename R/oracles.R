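# Brute-force oracles: deliberately naive straight-line implementations used
# by the test suite to cross-check the optimized estimators. Intended for
# tiny instances only (<= ~20 samples / markers).

#' r2 from phased haplotype counts (oracle)
#'
#' Direct counting on known haplotypes: no EM, no missing-data handling.
#'
#' @param hap_i,hap_j 0/1 allele vectors over the same chromosomes.
#' @return list: \code{r2}, \code{d_coef}, \code{dprime}.
#' @export
oracle_r2 <- function(hap_i, hap_j) {
  pA <- mean(hap_i); pB <- mean(hap_j)
  pAB <- mean(hap_i == 1 & hap_j == 1)
  D <- pAB - pA * pB
  dmax <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB)
          else min(pA * pB, (1 - pA) * (1 - pB))
  list(r2 = D^2 / (pA * (1 - pA) * pB * (1 - pB)),
       d_coef = D, dprime = abs(D) / dmax)
}

#' Two-locus likelihood maximized by grid search (oracle for the EM)
#'
#' Maximizes the unphased two-locus genotype likelihood over p_AB on a
#' 1e-4-step grid with allele frequencies fixed at their MLEs, and returns
#' the implied r2.
#'
#' @param g_i,g_j dosage vectors over the same samples.
#' @param step grid step on p_AB.
#' @return list: \code{p_ab}, \code{r2}.
#' @export
oracle_ld_grid <- function(g_i, g_j, step = 1e-4) {
  ok <- !is.na(g_i) & !is.na(g_j)
  gi <- g_i[ok]; gj <- g_j[ok]
  n <- length(gi)
  pA <- sum(gi) / (2 * n); pB <- sum(gj) / (2 * n)
  lo <- max(0, pA + pB - 1); hi <- min(pA, pB)
  grid <- seq(lo, hi, by = step)
  eps <- 1e-12
  ll <- vapply(grid, function(pAB) {
    h <- c(AB = pAB, Ab = pA - pAB, aB = pB - pAB, ab = 1 - pA - pB + pAB)
    h <- pmax(h, 0)
    pr <- matrix(0, 3, 3)  # [gi+1, gj+1]
    pr[1, 1] <- h["ab"]^2
    pr[1, 2] <- 2 * h["ab"] * h["aB"]
    pr[1, 3] <- h["aB"]^2
    pr[2, 1] <- 2 * h["ab"] * h["Ab"]
    pr[2, 2] <- 2 * (h["AB"] * h["ab"] + h["Ab"] * h["aB"])
    pr[2, 3] <- 2 * h["aB"] * h["AB"]
    pr[3, 1] <- h["Ab"]^2
    pr[3, 2] <- 2 * h["Ab"] * h["AB"]
    pr[3, 3] <- h["AB"]^2
    sum(log(pr[cbind(gi + 1, gj + 1)] + eps))
  }, 0)
  pAB <- grid[which.max(ll)]
  D <- pAB - pA * pB
  list(p_ab = pAB, r2 = D^2 / (pA * (1 - pA) * pB * (1 - pB)))
}

#' Nucleotide diversity by pairwise-difference enumeration (oracle)
#'
#' Expands each diploid sample into two allele copies and averages the
#' per-site mismatch fraction over every pair of copies.
#'
#' @param geno dosage matrix (0/1/2/NA).
#' @return list: \code{per_site}, \code{mean}.
#' @export
oracle_pi <- function(geno) {
  per_site <- apply(geno, 2L, function(g) {
    g <- g[!is.na(g)]
    alleles <- unlist(lapply(g, function(d) c(rep(1, d), rep(0, 2 - d))))
    n <- length(alleles)
    if (n < 2) return(NA_real_)
    diff <- 0
    for (a in 1:(n - 1)) for (b in (a + 1):n)
      diff <- diff + (alleles[a] != alleles[b])
    diff / choose(n, 2)
  })
  list(per_site = per_site, mean = mean(per_site, na.rm = TRUE))
}

#' Tajima's D by direct formula evaluation (oracle)
#'
#' Recomputes every constant and term from scratch, with n fixed at the
#' modal per-site allele-copy count, independent of the package's
#' vectorized path.
#'
#' @param geno dosage matrix (0/1/2/NA).
#' @return scalar D.
#' @export
oracle_tajima_d <- function(geno) {
  pi_site <- numeric(0); n_site <- integer(0); seg <- 0
  for (l in seq_len(ncol(geno))) {
    g <- geno[, l]; g <- g[!is.na(g)]
    alleles <- unlist(lapply(g, function(d) c(rep(1, d), rep(0, 2 - d))))
    n <- length(alleles)
    if (n < 2) next
    k <- sum(alleles)
    if (k > 0 && k < n) seg <- seg + 1
    pi_site <- c(pi_site, k * (n - k) / choose(n, 2))
    n_site <- c(n_site, n)
  }
  n <- round(mean(n_site))
  a1 <- sum(1 / seq_len(n - 1)); a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  S <- seg
  (sum(pi_site) - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

#' Gabriel blocks by exhaustive enumeration (oracle)
#'
#' Classifies every pair via \code{\link{dprime_ci}}, enumerates all
#' candidate intervals directly, and resolves overlaps by the same greedy
#' rule (descending span, ties leftmost) in plainly-written loops.
#'
#' @param panel small genotype panel (single chromosome recommended).
#' @inheritParams find_blocks
#' @return data.frame of blocks: \code{first}, \code{last}, \code{n_snps}.
#' @export
oracle_blocks <- function(panel, max_span_kb = 2000, strong_low = 0.70,
                          strong_high = 0.98, recomb_high = 0.90,
                          inform_frac = 0.95) {
  geno <- panel$geno; map <- panel$map
  stopifnot(length(unique(map$chrom)) == 1L)
  m <- nrow(map); pos <- map$pos
  strong <- matrix(FALSE, m, m); informative <- matrix(FALSE, m, m)
  for (a in 1:(m - 1)) for (b in (a + 1):m) {
    ci <- dprime_ci(geno[, a], geno[, b])
    if (anyNA(ci)) next
    if (ci[["ci_low"]] >= strong_low && ci[["ci_high"]] >= strong_high) {
      strong[a, b] <- TRUE; informative[a, b] <- TRUE
    } else if (ci[["ci_high"]] < recomb_high) {
      informative[a, b] <- TRUE
    }
  }
  cands <- data.frame(a = integer(), b = integer(), span = integer())
  for (a in 1:(m - 1)) for (b in (a + 1):m) {
    if (pos[b] - pos[a] > max_span_kb * 1000) next
    n_s <- 0; n_i <- 0
    for (x in a:(b - 1)) for (y in (x + 1):b) {
      n_s <- n_s + strong[x, y]; n_i <- n_i + informative[x, y]
    }
    if (n_i > 0 && n_s / n_i >= inform_frac)
      cands <- rbind(cands, data.frame(a = a, b = b, span = pos[b] - pos[a]))
  }
  cands <- cands[order(-cands$span, cands$a), , drop = FALSE]
  used <- rep(FALSE, m)
  out <- data.frame(first = integer(), last = integer(), n_snps = integer())
  for (r in seq_len(nrow(cands))) {
    a <- cands$a[r]; b <- cands$b[r]
    if (any(used[a:b])) next
    used[a:b] <- TRUE
    out <- rbind(out, data.frame(first = a, last = b, n_snps = b - a + 1L))
  }
  out[order(out$first), , drop = FALSE]
}
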
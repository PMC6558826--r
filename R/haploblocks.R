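# Gabriel-style haplotype blocks from D' confidence intervals, following the
# PLINK --blocks implementation: per pair, the likelihood of the unphased
# two-locus genotype counts is profiled over D' on a fine grid with allele
# frequencies fixed at their MLEs, and the normalized cumulative likelihood
# gives a central confidence interval for |D'|.

#' Likelihood-based confidence interval for |D'|
#'
#' Evaluates the multinomial likelihood of the observed 3x3 unphased
#' genotype counts on a grid of D' in [0, 1] (step 0.001), with allele
#' frequencies fixed at their MLEs and the sign of D fixed at the EM
#' estimate. The normalized cumulative likelihood yields the central
#' interval (default 90%: 5th and 95th percentiles).
#'
#' @param g_i,g_j dosage vectors over the same samples.
#' @param conf central coverage (default 0.90).
#' @param step D' grid step.
#' @return named vector \code{ci_low}, \code{ci_high}; NAs when the pair is
#'   non-informative (either marker monomorphic in the pairwise-complete
#'   subset).
#' @export
dprime_ci <- function(g_i, g_j, conf = 0.90, step = 0.001) {
  cnt <- pair_genotype_counts(cbind(g_i, g_j), 1L, 2L)[1L, ]
  em <- em_ld_from_counts(rbind(cnt))
  if (is.na(em$r2)) return(c(ci_low = NA_real_, ci_high = NA_real_))
  pA <- em$p_a; pB <- em$p_b
  sgn <- if (em$d_coef >= 0) 1 else -1
  dmax <- if (sgn > 0) min(pA * (1 - pB), (1 - pA) * pB)
          else min(pA * pB, (1 - pA) * (1 - pB))
  grid <- seq(0, 1, by = step)
  eps <- 1e-12
  D <- sgn * grid * dmax
  hAB <- pmax(pA * pB + D, 0)
  hAb <- pmax(pA * (1 - pB) - D, 0)
  haB <- pmax((1 - pA) * pB - D, 0)
  hab <- pmax((1 - pA) * (1 - pB) + D, 0)
  # genotype-cell probabilities under random union of gametes; column order
  # matches pair_genotype_counts (n00, n01, ..., n22)
  pr <- cbind(hab^2,  2 * hab * haB,                 haB^2,
              2 * hab * hAb, 2 * (hAB * hab + hAb * haB), 2 * haB * hAB,
              hAb^2,  2 * hAb * hAB,                 hAB^2)
  loglik <- as.numeric(log(pr + eps) %*% cnt)
  lik <- exp(loglik - max(loglik))
  cum <- cumsum(lik) / sum(lik)
  lo_p <- (1 - conf) / 2
  ci_low <- grid[which(cum >= lo_p)[1]]
  ci_high <- grid[which(cum >= 1 - lo_p)[1]]
  c(ci_low = ci_low, ci_high = ci_high)
}

# Classify each pair no farther apart than max_span: +1 strong LD, -1 strong
# recombination evidence, 0 non-informative. Pairs beyond max_span never
# enter a candidate block, so their CIs are not computed.
classify_pairs <- function(geno, idx, pos, max_span, strong_low, strong_high,
                           recomb_high, conf = 0.90) {
  m <- length(idx)
  cls <- matrix(0L, m, m)
  for (a in seq_len(m - 1L)) for (b in (a + 1L):m) {
    if (pos[b] - pos[a] > max_span) break
    ci <- dprime_ci(geno[, idx[a]], geno[, idx[b]], conf = conf)
    if (anyNA(ci)) next
    if (ci[["ci_low"]] >= strong_low && ci[["ci_high"]] >= strong_high)
      cls[a, b] <- cls[b, a] <- 1L
    else if (ci[["ci_high"]] < recomb_high)
      cls[a, b] <- cls[b, a] <- -1L
  }
  cls
}

#' Gabriel confidence-interval haplotype blocks
#'
#' A pair is in strong LD when its D' CI satisfies ci_low >= strong_low and
#' ci_high >= strong_high, and shows strong recombination evidence when
#' ci_high < recomb_high (default thresholds are the published PLINK
#' defaults). A candidate block is a contiguous marker run, spanning at most
#' \code{max_span_kb}, in which at least \code{inform_frac} of the
#' informative pairs are strong-LD (and at least one informative pair
#' exists). Non-overlapping blocks are chosen greedily by descending span,
#' ties broken by leftmost start.
#'
#' @param panel genotype panel (map sorted by position).
#' @param max_span_kb maximum block span in kb (default 2000 = 2 Mb).
#' @param strong_low,strong_high strong-LD CI thresholds.
#' @param recomb_high recombination-evidence CI threshold.
#' @param inform_frac minimum fraction of informative pairs in strong LD.
#' @return data.frame: \code{chrom}, \code{first}, \code{last} (marker map
#'   row indices), \code{start_bp}, \code{end_bp}, \code{span_bp},
#'   \code{n_snps}, \code{strong_frac}, \code{snps} (comma-separated IDs).
#' @export
find_blocks <- function(panel, max_span_kb = 2000, strong_low = 0.70,
                        strong_high = 0.98, recomb_high = 0.90,
                        inform_frac = 0.95) {
  geno <- panel$geno; map <- panel$map
  max_span <- max_span_kb * 1000
  blocks <- list()
  for (chr in unique(map$chrom)) {
    idx <- which(map$chrom == chr)
    m <- length(idx)
    if (m < 2L) next
    pos <- map$pos[idx]
    cls <- classify_pairs(geno, idx, pos, max_span, strong_low, strong_high,
                          recomb_high)
    cand <- list()
    for (a in seq_len(m - 1L)) for (b in (a + 1L):m) {
      if (pos[b] - pos[a] > max_span) break
      sub <- cls[a:b, a:b]
      up <- sub[upper.tri(sub)]
      n_strong <- sum(up == 1L); n_inf <- sum(up != 0L)
      if (n_inf > 0 && n_strong / n_inf >= inform_frac)
        cand[[length(cand) + 1L]] <- c(a = a, b = b,
                                       span = pos[b] - pos[a],
                                       frac = n_strong / n_inf)
    }
    if (!length(cand)) next
    cand <- do.call(rbind, cand)
    cand <- cand[order(-cand[, "span"], cand[, "a"]), , drop = FALSE]
    taken <- rep(FALSE, m)
    for (r in seq_len(nrow(cand))) {
      a <- cand[r, "a"]; b <- cand[r, "b"]
      if (any(taken[a:b])) next
      taken[a:b] <- TRUE
      blocks[[length(blocks) + 1L]] <- data.frame(
        chrom = chr, first = idx[a], last = idx[b],
        start_bp = pos[a], end_bp = pos[b],
        span_bp = pos[b] - pos[a], n_snps = b - a + 1L,
        strong_frac = cand[r, "frac"],
        snps = paste(map$marker[idx[a:b]], collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(blocks))
    return(data.frame(chrom = character(), first = integer(),
                      last = integer(), start_bp = integer(),
                      end_bp = integer(), span_bp = integer(),
                      n_snps = integer(), strong_frac = numeric(),
                      snps = character(), stringsAsFactors = FALSE))
  out <- do.call(rbind, blocks)
  out <- out[order(out$chrom, out$start_bp), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summary statistics over a block set
#'
#' @param blocks output of \code{\link{find_blocks}}.
#' @return data.frame: \code{n_blocks}, \code{mean_span_kb},
#'   \code{mean_snps_per_block}.
#' @export
block_summary <- function(blocks) {
  data.frame(n_blocks = nrow(blocks),
             mean_span_kb = if (nrow(blocks)) mean(blocks$span_bp) / 1000 else NA_real_,
             mean_snps_per_block = if (nrow(blocks)) mean(blocks$n_snps) else NA_real_)
}
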
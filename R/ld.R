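# Pairwise LD from unphased diploid genotypes. Haplotype frequencies are
# estimated by a two-locus EM (double heterozygotes split between coupling
# and repulsion each iteration), the Haploview/TASSEL approach, so r2 here is
# the haplotype-frequency r2, not the composite dosage correlation (that
# estimator is provided separately as ld_r2_dosage for cross-checks).

# 3x3 genotype counts for P marker pairs, pairwise-complete.
# Returns a list of nine P-vectors n00..n22 (first index = dosage at i).
pair_genotype_counts <- function(geno, ii, jj, chunk = 20000L) {
  P <- length(ii)
  out <- matrix(0, nrow = P, ncol = 9L)
  colnames(out) <- paste0("n", rep(0:2, each = 3), rep(0:2, 3))
  ind <- lapply(0:2, function(d) {
    m <- geno == d; m[is.na(m)] <- FALSE; storage.mode(m) <- "double"; m
  })
  for (start in seq(1L, P, by = chunk)) {
    idx <- start:min(start + chunk - 1L, P)
    gi <- lapply(ind, function(m) m[, ii[idx], drop = FALSE])
    gj <- lapply(ind, function(m) m[, jj[idx], drop = FALSE])
    k <- 1L
    for (a in 1:3) for (b in 1:3) {
      out[idx, k] <- colSums(gi[[a]] * gj[[b]])
      k <- k + 1L
    }
  }
  out
}

# Vectorized two-locus EM over rows of a 9-column count matrix.
# Returns data.frame(p_ab, p_a, p_b, d, r2, dprime, n_pair); rows where either
# marker is monomorphic in the pairwise-complete subset come back NA.
em_ld_from_counts <- function(cnt, tol = 1e-8, max_iter = 100L) {
  n <- rowSums(cnt)
  # haplotype counts resolvable without the double-het cell
  nAB <- 2 * cnt[, "n22"] + cnt[, "n21"] + cnt[, "n12"]
  nAb <- 2 * cnt[, "n20"] + cnt[, "n21"] + cnt[, "n10"]
  naB <- 2 * cnt[, "n02"] + cnt[, "n01"] + cnt[, "n12"]
  nab <- 2 * cnt[, "n00"] + cnt[, "n01"] + cnt[, "n10"]
  ndh <- cnt[, "n11"]
  tot <- 2 * n
  pA <- (nAB + nAb + ndh) / tot
  pB <- (nAB + naB + ndh) / tot
  poly <- pA > 0 & pA < 1 & pB > 0 & pB < 1 & n > 0
  pAB <- pA * pB
  active <- poly
  for (iter in seq_len(max_iter)) {
    if (!any(active)) break
    pAb <- pA - pAB; paB <- pB - pAB; pab <- 1 - pA - pB + pAB
    coup <- pAB * pab
    rep_ <- pAb * paB
    w <- ifelse(coup + rep_ > 0, coup / (coup + rep_), 0.5)
    new <- (nAB + w * ndh) / tot
    moved <- abs(new - pAB) >= tol & active
    pAB[active] <- new[active]
    active <- moved
  }
  D <- pAB - pA * pB
  denom <- pA * (1 - pA) * pB * (1 - pB)
  r2 <- ifelse(poly, D^2 / denom, NA_real_)
  dmax <- ifelse(D >= 0,
                 pmin(pA * (1 - pB), (1 - pA) * pB),
                 pmin(pA * pB, (1 - pA) * (1 - pB)))
  dprime <- ifelse(poly & dmax > 0, abs(D) / dmax, NA_real_)
  data.frame(p_ab = ifelse(poly, pAB, NA_real_), p_a = pA, p_b = pB,
             d_coef = ifelse(poly, D, NA_real_), r2 = r2, dprime = dprime,
             n_pair = n)
}

#' LD between two markers from unphased genotypes
#'
#' Estimates two-locus haplotype frequencies by EM over the 3x3 unphased
#' genotype table (pairwise-complete samples), then reports
#' \eqn{D = p_{AB} - p_A p_B}, \eqn{r^2 = D^2/(p_A q_A p_B q_B)} and
#' \eqn{D' = |D|/D_{max}}.
#'
#' @param g_i,g_j dosage vectors (0/1/2/NA) over the same samples.
#' @return one-row data.frame with \code{p_ab}, \code{d_coef}, \code{r2},
#'   \code{dprime}, \code{n_pair}; NA estimates if either marker is
#'   monomorphic within the pairwise-complete subset.
#' @export
ld_pair <- function(g_i, g_j) {
  stopifnot(length(g_i) == length(g_j))
  cnt <- pair_genotype_counts(cbind(g_i, g_j), 1L, 2L)
  em_ld_from_counts(cnt)
}

#' Composite dosage-correlation r2 (cross-check estimator)
#'
#' Plain squared Pearson correlation of the two dosage vectors over
#' pairwise-complete samples; labelled alternative to the EM estimator.
#'
#' @inheritParams ld_pair
#' @return scalar r2.
#' @export
ld_r2_dosage <- function(g_i, g_j) {
  ok <- !is.na(g_i) & !is.na(g_j)
  suppressWarnings(stats::cor(g_i[ok], g_j[ok])^2)
}

#' Sliding-window pairwise LD along each chromosome
#'
#' Emits every intra-chromosomal marker pair whose index separation is at
#' most \code{window} (markers sorted by position), with physical distance in
#' bp and EM-based LD statistics. Pairs undefined because one marker is
#' monomorphic in the pairwise-complete subset are dropped.
#'
#' @param panel genotype panel.
#' @param window maximum index separation (default 50 markers).
#' @return data.frame: \code{chrom}, \code{marker_i}, \code{marker_j},
#'   \code{pos_i}, \code{pos_j}, \code{dist_bp}, \code{r2}, \code{dprime},
#'   \code{n_pair}.
#' @export
sliding_window_ld <- function(panel, window = 50) {
  geno <- panel$geno; map <- panel$map
  out <- list()
  for (chr in unique(map$chrom)) {
    idx <- which(map$chrom == chr)
    m <- length(idx)
    if (m < 2L) { warning("chromosome ", chr, " has < 2 markers"); next }
    off <- unlist(lapply(seq_len(min(window, m - 1L)),
                         function(k) seq_len(m - k)))
    sep <- unlist(lapply(seq_len(min(window, m - 1L)),
                         function(k) rep(k, m - k)))
    i_loc <- off; j_loc <- off + sep
    ii <- idx[i_loc]; jj <- idx[j_loc]
    cnt <- pair_genotype_counts(geno, ii, jj)
    em <- em_ld_from_counts(cnt)
    tab <- data.frame(chrom = chr,
                      marker_i = map$marker[ii], marker_j = map$marker[jj],
                      pos_i = map$pos[ii], pos_j = map$pos[jj],
                      dist_bp = abs(map$pos[jj] - map$pos[ii]),
                      r2 = em$r2, dprime = em$dprime, n_pair = em$n_pair,
                      stringsAsFactors = FALSE)
    out[[chr]] <- tab[!is.na(tab$r2), , drop = FALSE]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Background LD from interchromosomal marker pairs
#'
#' The 90th percentile (linear-interpolation rule) of r2 over a seeded random
#' sample of marker pairs on different chromosomes.
#'
#' @param panel genotype panel with markers on >= 2 chromosomes.
#' @param n_pairs number of random interchromosomal pairs (all pairs if the
#'   total is smaller).
#' @param seed RNG seed.
#' @param probs percentile(s) to report (default 0.9).
#' @return named numeric percentile(s) of interchromosomal r2.
#' @export
background_ld <- function(panel, n_pairs = 10000, seed = 1, probs = 0.9) {
  map <- panel$map
  if (length(unique(map$chrom)) < 2L) stop("need >= 2 chromosomes")
  M <- nrow(map)
  set.seed(seed)
  total_inter <- choose(M, 2)  # upper bound; rejection-sample below
  ii <- integer(0); jj <- integer(0)
  while (length(ii) < n_pairs) {
    a <- sample.int(M, 2 * n_pairs, replace = TRUE)
    b <- sample.int(M, 2 * n_pairs, replace = TRUE)
    ok <- map$chrom[a] != map$chrom[b]
    ii <- c(ii, a[ok]); jj <- c(jj, b[ok])
  }
  ii <- ii[seq_len(n_pairs)]; jj <- jj[seq_len(n_pairs)]
  cnt <- pair_genotype_counts(panel$geno, ii, jj)
  em <- em_ld_from_counts(cnt)
  stats::quantile(em$r2, probs = probs, na.rm = TRUE, type = 7)
}

#' Distance-bin edges used for the genome-wide mean-LD table
#'
#' Thirty log-spaced (ratio about 1.61) upper edges in kb from 0.10 to
#' 100,000; the first bin is 0-0.10 kb.
#' @return numeric vector of 30 upper bin edges in kb.
#' @export
default_ld_bins <- function() {
  c(0.10, 0.16, 0.26, 0.42, 0.67, 1.08, 1.74, 2.81, 4.52, 7.28,
    11.7, 18.9, 30.4, 48.9, 78.8, 127, 204, 329, 530, 853,
    1370, 2210, 3560, 5740, 9240, 14900, 24000, 38600, 62100, 100000)
}

#' Binned mean LD over physical distance
#'
#' Buckets an LD table into distance bins and reports pair count, mean r2 and
#' SD r2 per bin; pairs beyond the last edge are counted in an
#' \code{overflow} attribute.
#'
#' @param ld_table output of \code{\link{sliding_window_ld}}.
#' @param bin_edges_kb ordered upper bin edges in kb (lower edge of the first
#'   bin is 0).
#' @return data.frame \code{bin_low_kb}, \code{bin_high_kb}, \code{n},
#'   \code{mean_r2}, \code{sd_r2}; attribute \code{overflow} = pairs beyond
#'   the last edge.
#' @export
binned_mean_ld <- function(ld_table, bin_edges_kb = default_ld_bins()) {
  if (is.unsorted(bin_edges_kb, strictly = TRUE) || any(bin_edges_kb <= 0))
    stop("bin edges must be positive and increasing")
  d_kb <- ld_table$dist_bp / 1000
  edges <- c(0, bin_edges_kb)
  idx <- findInterval(d_kb, edges, left.open = TRUE, rightmost.closed = FALSE)
  idx[d_kb == 0] <- 1L
  inside <- idx >= 1L & idx <= length(bin_edges_kb)
  overflow <- sum(!inside)
  idx_f <- factor(idx[inside], levels = seq_along(bin_edges_kb))
  r2 <- ld_table$r2[inside]
  out <- data.frame(
    bin_low_kb = edges[-length(edges)],
    bin_high_kb = bin_edges_kb,
    n = as.integer(tabulate(idx_f, nbins = length(bin_edges_kb))),
    mean_r2 = as.numeric(tapply(r2, idx_f, mean)),
    sd_r2 = as.numeric(tapply(r2, idx_f, stats::sd)))
  attr(out, "overflow") <- overflow
  out
}

#' Hill-Weir expected r2 under drift-recombination equilibrium
#'
#' \deqn{E[r^2] = \frac{10+C}{(2+C)(11+C)}\left[1 +
#'   \frac{(3+C)(12+12C+C^2)}{n(2+C)(11+C)}\right]}
#' with C the population recombination parameter and n the sample size
#' (number of sequences) entering the small-sample correction.
#'
#' @param C non-negative recombination parameter (rho * distance).
#' @param n sample size in the correction term.
#' @return expected r2.
#' @export
hill_weir_expectation <- function(C, n) {
  ((10 + C) / ((2 + C) * (11 + C))) *
    (1 + ((3 + C) * (12 + 12 * C + C^2)) / (n * (2 + C) * (11 + C)))
}

#' Fit the LD decay curve
#'
#' Nonlinear least squares of observed r2 against the Hill-Weir expectation
#' with \eqn{C = \rho d}, over \eqn{\rho > 0}. The 1-D optimization runs in
#' log10(rho) from each of several starts and keeps the lowest residual sum
#' of squares.
#'
#' @param ld_table LD table with \code{dist_bp} and \code{r2} (>= 20 pairs).
#' @param n_fit sample size for the Hill-Weir correction (>= 4); typically
#'   2 x samples (chromosome count).
#' @param starts starting values for rho (per bp).
#' @return object of class \code{decay_fit}: list(rho_hat, n_fit, rss,
#'   n_pairs).
#' @export
fit_decay <- function(ld_table, n_fit, starts = c(1e-9, 1e-7, 1e-5)) {
  ok <- is.finite(ld_table$r2) & is.finite(ld_table$dist_bp)
  d <- as.numeric(ld_table$dist_bp[ok]); r2 <- ld_table$r2[ok]
  if (length(d) < 20L) stop("need >= 20 pairs with defined r2")
  if (n_fit < 4) stop("n_fit must be >= 4")
  rss_fun <- function(log10_rho) {
    C <- 10^log10_rho * d
    sum((r2 - hill_weir_expectation(C, n_fit))^2)
  }
  best <- NULL
  for (s in starts) {
    opt <- tryCatch(
      stats::nlminb(log10(s), rss_fun, lower = -15, upper = 0),
      error = function(e) NULL)
    if (!is.null(opt) && (is.null(best) || opt$objective < best$objective))
      best <- opt
  }
  if (is.null(best))
    stop("decay fit failed from all starts (", paste(starts, collapse = ", "), ")")
  structure(list(rho_hat = 10^best$par, n_fit = n_fit,
                 rss = best$objective, n_pairs = length(d)),
            class = "decay_fit")
}

#' Evaluate a fitted decay curve
#'
#' @param fit \code{decay_fit} object.
#' @param d distances in bp.
#' @return expected r2 at each distance.
#' @export
decay_curve <- function(fit, d) {
  hill_weir_expectation(fit$rho_hat * d, fit$n_fit)
}

#' @export
print.decay_fit <- function(x, ...) {
  dd <- tryCatch(decay_distances(x), error = function(e) NULL)
  cat("LD decay fit (Hill-Weir, n =", x$n_fit, ")\n")
  cat("  rho_hat:", format(x$rho_hat, digits = 4), "per bp;  RSS:",
      format(x$rss, digits = 4), "over", x$n_pairs, "pairs\n")
  if (!is.null(dd))
    cat("  half-decay:", format(dd[["half_decay_bp"]] / 1e6, digits = 4),
        "Mb;  r2 = 0.2 at:",
        if (is.na(dd[["r2_02_bp"]])) "n/a" else
          paste(format(dd[["r2_02_bp"]] / 1e6, digits = 4), "Mb"), "\n")
  invisible(x)
}

#' Characteristic decay distances of a fitted curve
#'
#' \code{half_decay_bp} solves curve(d) = 0.5 * curve(0); \code{r2_02_bp}
#' solves curve(d) = 0.2 (NA if the curve never exceeds 0.2). Both roots are
#' found by bisection to 1 bp; the curve is strictly decreasing so each root
#' is unique.
#'
#' @param fit \code{decay_fit} object.
#' @param max_distance_bp bracketing limit (default 1e10).
#' @return named vector \code{half_decay_bp}, \code{r2_02_bp} (NA when not
#'   bracketed within \code{max_distance_bp}).
#' @export
decay_distances <- function(fit, max_distance_bp = 1e10) {
  r2_0 <- decay_curve(fit, 0)
  solve_for <- function(target) {
    if (decay_curve(fit, max_distance_bp) > target) return(NA_real_)
    lo <- 0; hi <- max_distance_bp
    while (hi - lo > 1) {
      mid <- (lo + hi) / 2
      if (decay_curve(fit, mid) > target) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }
  half <- solve_for(r2_0 / 2)
  r02 <- if (r2_0 <= 0.2) NA_real_ else solve_for(0.2)
  c(half_decay_bp = half, r2_02_bp = r02)
}

#' Loess smooth of r2 against distance (plotting aid)
#'
#' Local-regression smooth of r2 on distance, evaluated on a log-spaced grid
#' spanning the observed distances. For visual comparison with the nonlinear
#' fit only; decay distances always come from \code{\link{decay_distances}}.
#'
#' @param ld_table LD table (>= 10 pairs).
#' @param span loess span.
#' @param n_grid grid size.
#' @return data.frame \code{dist_bp}, \code{r2_smooth}.
#' @export
loess_smooth <- function(ld_table, span = 0.5, n_grid = 100) {
  ok <- is.finite(ld_table$r2) & ld_table$dist_bp > 0
  d <- as.numeric(ld_table$dist_bp[ok]); r2 <- ld_table$r2[ok]
  if (length(d) < 10L) stop("need >= 10 pairs")
  if (length(unique(d)) < 2L) stop("degenerate distances")
  fit <- stats::loess(r2 ~ d, span = span, degree = 2,
                      control = stats::loess.control(surface = "direct"))
  grid <- exp(seq(log(min(d)), log(max(d)), length.out = n_grid))
  data.frame(dist_bp = grid, r2_smooth = stats::predict(fit, newdata = data.frame(d = grid)))
}

#' Per-stratum LD chain
#'
#' Subsets samples by a metadata category (e.g. subspecies), re-filters
#' markers within each stratum (MAF is stratum-specific), and runs the full
#' windowed-LD / binning / decay-fit chain per stratum.
#'
#' @param panel genotype panel.
#' @param sample_table data.frame with columns \code{sample} and the stratum
#'   column.
#' @param stratum_col metadata column defining strata (default
#'   \code{"subspecies"}).
#' @param levels stratum values to analyze (default: all with >= min_samples,
#'   excluding \code{"unknown"}).
#' @param min_samples minimum stratum size (default 10).
#' @param window,maf_min,min_known_alleles,bin_edges_kb passed through to the
#'   LD chain; \code{min_known_alleles} defaults to the stratum's sample
#'   count (all calls present) scaled by 0.9.
#' @return named list per stratum: list(ld, binned, fit, decay).
#' @export
stratified_ld <- function(panel, sample_table, stratum_col = "subspecies",
                          levels = NULL, min_samples = 10, window = 50,
                          maf_min = 0.05, min_known_alleles = NULL,
                          bin_edges_kb = default_ld_bins()) {
  stopifnot(stratum_col %in% names(sample_table))
  lab <- sample_table[[stratum_col]][match(rownames(panel$geno),
                                           sample_table$sample)]
  if (is.null(levels))
    levels <- setdiff(names(which(table(lab) >= min_samples)), "unknown")
  out <- list()
  for (lv in levels) {
    keep <- which(!is.na(lab) & lab == lv)
    if (length(keep) < min_samples)
      stop("stratum ", lv, " has fewer than ", min_samples, " samples")
    sub <- list(geno = panel$geno[keep, , drop = FALSE], map = panel$map)
    mka <- if (is.null(min_known_alleles)) ceiling(0.9 * 2 * length(keep))
           else min_known_alleles
    sub <- filter_markers(sub, min_known_alleles = mka, maf_min = maf_min)
    ld <- sliding_window_ld(sub, window = window)
    fit <- fit_decay(ld, n_fit = 2 * length(keep))
    out[[lv]] <- list(ld = ld, binned = binned_mean_ld(ld, bin_edges_kb),
                      fit = fit, decay = decay_distances(fit))
  }
  out
}
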
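# Seeded generator of structured, admixed, highly selfed SNP panels with
# distance-decaying LD, emulating a small tetraploid-crop diversity
# collection genotyped on a fixed array: ~110 samples, thousands of
# biallelic SNPs on 20 chromosomes, low average MAF, near-complete
# homozygosity with a few heterozygous outliers, 4-5 admixed
# subpopulations, Mb-scale LD, and replicate-level quantitative traits with
# a handful of moderate-effect QTLs.

#' Simulation configuration
#'
#' Collects every knob of the generator with collection-like defaults:
#' 110 samples, 2,000 markers on 20 chromosomes (~100 Mb each), 5 ancestral
#' populations at Balding-Nichols FST 0.25, Dirichlet(0.2) admixture,
#' 6 selfing generations, crossover intensity 1e-8 per bp per meiosis,
#' 2% missing calls, and 3-replicate traits at h2 = 0.7.
#'
#' @param n_samples,n_markers,n_chromosomes panel dimensions.
#' @param chrom_length_bp chromosome length in bp.
#' @param K_true number of ancestral populations.
#' @param fst Balding-Nichols differentiation among them.
#' @param alpha Dirichlet admixture concentration (small = near-hard
#'   assignment).
#' @param n_founders founder haplotypes per ancestral population (small
#'   pools create long-range LD).
#' @param n_proto size of the shared proto-haplotype pool all population
#'   founders descend from; small values emulate the extreme bottleneck of
#'   a recently domesticated selfer (high zero-distance r2).
#' @param proto_divergence per-site probability that a founder re-draws its
#'   allele from its population's Balding-Nichols frequency instead of
#'   copying the proto-haplotype.
#' @param selfing_generations generations of self-fertilization (each halves
#'   expected heterozygosity).
#' @param recomb_per_bp crossover intensity per bp per meiosis (controls the
#'   LD decay scale).
#' @param history_generations effective generations of historical
#'   recombination baked into the founder-mosaic copying (the mosaic
#'   breakpoint rate is \code{recomb_per_bp * history_generations}).
#' @param missing_rate fraction of calls masked missing.
#' @param maf_floor lower bound of the shared ancestral allele-frequency
#'   spectrum.
#' @param n_het_outliers samples left unselfed (heterozygous outliers).
#' @param qtl data.frame(marker_index, effect) of planted QTLs.
#' @param h2 narrow-sense heritability of simulated traits.
#' @param n_envs,n_reps trait design (environments x replicates per env).
#' @param seed mandatory RNG seed.
#' @return list of class \code{sim_config}.
#' @export
sim_config <- function(n_samples = 110, n_markers = 2000,
                       n_chromosomes = 20, chrom_length_bp = 1e8,
                       K_true = 5, fst = 0.25, alpha = 0.2,
                       n_founders = 8, n_proto = 3, proto_divergence = 0.1,
                       selfing_generations = 6,
                       recomb_per_bp = 1e-8, history_generations = 10,
                       missing_rate = 0.02,
                       maf_floor = 0.05, n_het_outliers = 5,
                       qtl = NULL, h2 = 0.7, n_envs = 3, n_reps = 1,
                       seed) {
  if (missing(seed)) stop("seed is mandatory")
  cfg <- list(n_samples = n_samples, n_markers = n_markers,
              n_chromosomes = n_chromosomes,
              chrom_length_bp = chrom_length_bp, K_true = K_true,
              fst = fst, alpha = alpha, n_founders = n_founders,
              n_proto = n_proto, proto_divergence = proto_divergence,
              selfing_generations = selfing_generations,
              recomb_per_bp = recomb_per_bp,
              history_generations = history_generations,
              missing_rate = missing_rate,
              maf_floor = maf_floor, n_het_outliers = n_het_outliers,
              qtl = qtl, h2 = h2, n_envs = n_envs, n_reps = n_reps,
              seed = seed)
  rates <- c(fst = fst, missing_rate = missing_rate, maf_floor = maf_floor,
             h2 = h2)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  if (!is.null(qtl) && any(qtl$marker_index > n_markers))
    stop("QTL marker index out of range")
  class(cfg) <- "sim_config"
  cfg
}

# one recombinant gamete from a pair of haplotypes at given bp positions
recombine <- function(hap1, hap2, pos, chrom_length, rate) {
  n_break <- stats::rpois(1, rate * chrom_length)
  start <- sample(c(TRUE, FALSE), 1)
  if (n_break == 0) return(if (start) hap1 else hap2)
  breaks <- sort(stats::runif(n_break, 0, chrom_length))
  seg <- findInterval(pos, breaks)          # 0..n_break
  use1 <- (seg %% 2 == 0) == start
  ifelse(use1, hap1, hap2)
}

#' Simulate a structured, selfed, admixed SNP panel
#'
#' Ancestral alternate-allele frequencies follow a Balding-Nichols model
#' around a shared spectrum \eqn{\pi_l \sim U(maf_{floor}, 0.5)}; each
#' ancestral population carries a small pool of founder haplotypes; sample
#' gametes are founder mosaics with Poisson crossover breakpoints (Haldane),
#' segments drawn from populations according to the sample's Dirichlet
#' admixture vector; diploids are then selfed (with recombination each
#' generation) except for a few heterozygous outliers, and calls are masked
#' missing at the configured rate. Fully reproducible from config + seed.
#'
#' @param cfg \code{\link{sim_config}} object.
#' @return list: \code{panel} (genotype panel), \code{samples} (sample
#'   metadata with subspecies/market-type labels derived from the dominant
#'   ancestry), \code{truth} (q, p, founder haplotypes, config).
#' @export
simulate_population <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_samples; M <- cfg$n_markers; K <- cfg$K_true
  n_chr <- cfg$n_chromosomes
  chrom_labels <- paste0(rep(c("A", "B"), each = 10), sprintf("%02d", 1:10))
  chrom_labels <- rep(chrom_labels, length.out = n_chr)[seq_len(n_chr)]
  per_chr <- diff(floor(seq(0, M, length.out = n_chr + 1)))
  chrom <- rep(chrom_labels, per_chr)
  pos <- unlist(lapply(per_chr, function(m)
    sort(sample.int(cfg$chrom_length_bp, m))))
  pi_l <- stats::runif(M, cfg$maf_floor, 0.5)
  shape <- (1 - cfg$fst) / cfg$fst
  P <- matrix(0, K, M)
  for (k in seq_len(K))
    P[k, ] <- stats::rbeta(M, pi_l * shape, (1 - pi_l) * shape)
  # founder haplotype pools: every founder descends from a small shared
  # proto-haplotype pool (domestication bottleneck), diverging per
  # population at rate proto_divergence toward its Balding-Nichols
  # frequencies
  proto <- matrix(stats::rbinom(cfg$n_proto * M, 1,
                                rep(pi_l, each = cfg$n_proto)),
                  nrow = cfg$n_proto)
  founders <- lapply(seq_len(K), function(k) {
    f <- proto[sample.int(cfg$n_proto, cfg$n_founders, replace = TRUE), ,
               drop = FALSE]
    mut <- matrix(stats::runif(cfg$n_founders * M) < cfg$proto_divergence,
                  nrow = cfg$n_founders)
    redraw <- matrix(stats::rbinom(cfg$n_founders * M, 1,
                                   rep(P[k, ], each = cfg$n_founders)),
                     nrow = cfg$n_founders)
    f[mut] <- redraw[mut]
    f
  })
  Qtrue <- matrix(stats::rgamma(n * K, cfg$alpha), n, K)
  Qtrue <- Qtrue / rowSums(Qtrue)
  chr_index <- split(seq_len(M), factor(chrom, levels = chrom_labels))
  draw_gamete <- function(i) {
    hap <- integer(M)
    for (ci in chr_index) {
      m <- length(ci)
      cpos <- pos[ci]
      n_break <- stats::rpois(1, cfg$recomb_per_bp * cfg$history_generations *
                                   cfg$chrom_length_bp)
      breaks <- sort(stats::runif(n_break, 0, cfg$chrom_length_bp))
      seg <- findInterval(cpos, breaks)
      for (s in unique(seg)) {
        k <- sample.int(K, 1, prob = Qtrue[i, ])
        f <- sample.int(cfg$n_founders, 1)
        sel <- ci[seg == s]
        hap[sel] <- founders[[k]][f, sel]
      }
    }
    hap
  }
  hap1 <- matrix(0L, n, M); hap2 <- matrix(0L, n, M)
  for (i in seq_len(n)) {
    hap1[i, ] <- draw_gamete(i)
    hap2[i, ] <- draw_gamete(i)
  }
  # selfing with per-generation recombination; a few outliers stay unselfed
  outliers <- if (cfg$n_het_outliers > 0)
    sample.int(n, min(cfg$n_het_outliers, n)) else integer(0)
  for (i in setdiff(seq_len(n), outliers)) {
    for (g in seq_len(cfg$selfing_generations)) {
      new1 <- integer(M); new2 <- integer(M)
      for (ci in chr_index) {
        cpos <- pos[ci]
        new1[ci] <- recombine(hap1[i, ci], hap2[i, ci], cpos,
                              cfg$chrom_length_bp, cfg$recomb_per_bp)
        new2[ci] <- recombine(hap1[i, ci], hap2[i, ci], cpos,
                              cfg$chrom_length_bp, cfg$recomb_per_bp)
      }
      hap1[i, ] <- new1; hap2[i, ] <- new2
    }
  }
  geno <- hap1 + hap2
  if (cfg$missing_rate > 0)
    geno[stats::runif(length(geno)) < cfg$missing_rate] <- NA_integer_
  samples <- sprintf("ACC%03d", seq_len(n))
  markers <- sprintf("SNP%05d", seq_len(M))
  dimnames(geno) <- list(samples, markers)
  map <- data.frame(marker = markers, chrom = chrom, pos = pos,
                    ref = "A", alt = "T", stringsAsFactors = FALSE)
  panel <- genotype_panel(geno, map)
  dom <- apply(Qtrue, 1L, which.max)
  subsp <- c("fastigiata", "hypogaea")[1 + (dom > ceiling(K / 2))]
  market <- c("Runner", "Virginia", "Spanish", "Valencia", "mixed")[
    ((dom - 1) %% 5) + 1]
  sample_table <- data.frame(sample = samples, subspecies = subsp,
                             market_type = market,
                             botanical_variety = paste0("var", dom),
                             stringsAsFactors = FALSE)
  list(panel = panel, samples = sample_table,
       truth = list(Q = Qtrue, P = P, founders = founders,
                    hap1 = hap1, hap2 = hap2, outliers = outliers,
                    config = cfg))
}

#' Simulate an unlinked Balding-Nichols panel
#'
#' Sites are independent (no LD): ancestral frequencies
#' \eqn{p_{kl} \sim BN(\pi_l, F_{ST})}, admixture rows from a Dirichlet
#' (hard population assignment when \code{alpha = 0}), and genotypes
#' \eqn{g_{il} \sim Binom(2, \sum_k q_{ik} p_{kl})}. The calibration
#' substrate for structure-inference checks, where mosaic LD would only
#' confound the comparison.
#'
#' @param n_samples,n_markers panel dimensions.
#' @param K number of populations.
#' @param fst Balding-Nichols differentiation.
#' @param alpha Dirichlet concentration; 0 = hard assignment (balanced).
#' @param maf_floor lower bound of the shared spectrum.
#' @param seed RNG seed.
#' @return list: \code{panel}, \code{truth} (Q, P, labels).
#' @export
simulate_bn_panel <- function(n_samples, n_markers, K, fst, alpha = 0,
                              maf_floor = 0.05, seed) {
  if (missing(seed)) stop("seed is mandatory")
  set.seed(seed)
  pi_l <- stats::runif(n_markers, maf_floor, 0.5)
  shape <- (1 - fst) / fst
  P <- matrix(0, K, n_markers)
  for (k in seq_len(K))
    P[k, ] <- stats::rbeta(n_markers, pi_l * shape, (1 - pi_l) * shape)
  if (alpha > 0) {
    Q <- matrix(stats::rgamma(n_samples * K, alpha), n_samples, K)
    Q <- Q / rowSums(Q)
  } else {
    lab <- rep_len(seq_len(K), n_samples)
    Q <- matrix(0, n_samples, K)
    Q[cbind(seq_len(n_samples), lab)] <- 1
  }
  Fq <- Q %*% P
  geno <- matrix(stats::rbinom(length(Fq), 2, Fq), n_samples, n_markers)
  samples <- sprintf("BN%03d", seq_len(n_samples))
  markers <- sprintf("M%05d", seq_len(n_markers))
  dimnames(geno) <- list(samples, markers)
  map <- data.frame(marker = markers, chrom = "C01",
                    pos = seq_len(n_markers) * 1000L,
                    ref = "A", alt = "T", stringsAsFactors = FALSE)
  list(panel = genotype_panel(geno, map),
       truth = list(Q = Q, P = P, labels = apply(Q, 1L, which.max)))
}

#' Simulate replicate-level quantitative traits
#'
#' Genetic value = sum of planted QTL effects x dosage plus a polygenic
#' term built from many small random marker effects; replicate value =
#' grand mean + environment effect + genetic value + residual, with the
#' residual variance set so that the per-plot narrow-sense heritability
#' matches \code{cfg$h2}.
#'
#' @param panel genotype panel.
#' @param cfg \code{\link{sim_config}} (uses qtl, h2, n_envs, n_reps, seed).
#' @param trait trait name for the output table.
#' @param polygenic_var variance of the polygenic genetic component relative
#'   to the QTL variance (default 0.2).
#' @return list: \code{traits} (long-format table), \code{truth}
#'   (genetic values, qtl effects, variances).
#' @export
simulate_traits <- function(panel, cfg, trait = "trait1",
                            polygenic_var = 0.2) {
  if (cfg$h2 <= 0 || cfg$h2 >= 1) stop("h2 must be in (0, 1)")
  set.seed(cfg$seed + 101L)
  geno <- panel$geno
  G <- geno
  G[is.na(G)] <- matrix(colMeans(geno, na.rm = TRUE),
                        nrow(G), ncol(G), byrow = TRUE)[is.na(G)]
  g <- rep(0, nrow(G))
  if (!is.null(cfg$qtl))
    g <- g + as.numeric(G[, cfg$qtl$marker_index, drop = FALSE] %*%
                          cfg$qtl$effect)
  # polygenic background from small random effects over all markers
  # (monomorphic columns scale to NaN and are zeroed out)
  u <- stats::rnorm(ncol(G), 0, 1)
  Gs <- scale(G)
  Gs[!is.finite(Gs)] <- 0
  poly <- as.numeric(Gs %*% u)
  if (stats::sd(poly) > 0) {
    target_sd <- if (stats::sd(g) > 0)
      stats::sd(g) * sqrt(polygenic_var) else 1
    poly <- poly / stats::sd(poly) * target_sd
  }
  g <- g + poly
  var_g <- stats::var(g)
  var_e <- var_g * (1 - cfg$h2) / cfg$h2
  env_eff <- stats::rnorm(cfg$n_envs, 0, sqrt(var_g) / 2)
  rows <- list()
  for (e in seq_len(cfg$n_envs)) for (r in seq_len(cfg$n_reps)) {
    rows[[length(rows) + 1L]] <- data.frame(
      sample = rownames(G), trait = trait,
      env = paste0("E", e, if (cfg$n_reps > 1) paste0("R", r) else ""),
      value = 10 + env_eff[e] + g + stats::rnorm(nrow(G), 0, sqrt(var_e)),
      stringsAsFactors = FALSE)
  }
  list(traits = do.call(rbind, rows),
       truth = list(g = stats::setNames(g, rownames(G)),
                    qtl = cfg$qtl, var_g = var_g, var_e = var_e,
                    env_eff = env_eff))
}
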
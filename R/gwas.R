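# Association machinery: BLUP phenotype preparation, GLM and EMMA/P3D
# mixed-model scans, effective-number-of-tests thresholds, QQ/lambda
# diagnostics and candidate-gene interval reporting.

#' BLUPs across environments for one trait
#'
#' Fits the random-genotype model value ~ env (fixed) + (1 | sample) by REML
#' and returns the genotype BLUPs (shrunken, centered deviations from the
#' grand mean) with the variance components of the prep model.
#'
#' @param traits long-format trait table (\code{sample}, \code{trait},
#'   \code{env}, \code{value}).
#' @param trait trait name to extract.
#' @return list: \code{blup} (named vector, centered at 0),
#'   \code{intercept} (grand mean on the reference environment),
#'   \code{sigma2_g}, \code{sigma2_e}.
#' @export
fit_blups <- function(traits, trait) {
  dat <- traits[traits$trait == trait, , drop = FALSE]
  if (!nrow(dat)) stop("no records for trait ", trait)
  dat$sample <- factor(dat$sample)
  dat$env <- factor(dat$env)
  form <- if (nlevels(dat$env) > 1) value ~ env + (1 | sample)
          else value ~ (1 | sample)
  fit <- lme4::lmer(form, data = dat, REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(fit))
  s2g <- vc$vcov[vc$grp == "sample"]
  s2e <- vc$vcov[vc$grp == "Residual"]
  if (s2g < 1e-12) warning("zero genotypic variance: BLUPs are all ~0")
  re <- lme4::ranef(fit)$sample
  blup <- stats::setNames(re[, 1], rownames(re))
  list(blup = blup, intercept = lme4::fixef(fit)[["(Intercept)"]],
       sigma2_g = s2g, sigma2_e = s2e)
}

# REML profile log-likelihood for the rotated null model:
# y* ~ N(X* b, sg^2 (D + delta I)); maximized over log(delta) by
# golden-section (stats::optimize) on [-10, 10] natural-log scale.
emma_reml_delta <- function(ystar, Xstar, lambda) {
  n <- length(ystar); p <- ncol(Xstar)
  neg_restricted_ll <- function(log_delta) {
    delta <- exp(log_delta)
    w <- 1 / (lambda + delta)
    sw <- sqrt(w)
    Xw <- Xstar * sw; yw <- ystar * sw
    qr_x <- qr(Xw)
    res <- qr.resid(qr_x, yw)
    rss <- sum(res^2)
    s2 <- rss / (n - p)
    # REML criterion (constant terms dropped)
    0.5 * ((n - p) * log(s2) - sum(log(w)) +
             2 * sum(log(abs(diag(qr.R(qr_x))))))
  }
  opt <- stats::optimize(neg_restricted_ll, c(-10, 10), tol = 1e-8)
  delta <- exp(opt$minimum)
  w <- 1 / (lambda + delta)
  sw <- sqrt(w)
  res <- qr.resid(qr(Xstar * sw), ystar * sw)
  s2g <- sum(res^2) / (n - ncol(Xstar))
  list(delta = delta, sigma2_g = s2g, sigma2_e = s2g * delta)
}

scan_markers <- function(yw, X0w, Gw, map, marker_means) {
  # yw, X0w, Gw already whitened; test each marker column by its increment
  # over the null fit
  n <- length(yw); p0 <- ncol(X0w)
  qr0 <- qr(X0w)
  ry <- qr.resid(qr0, yw)
  RM <- qr.resid(qr0, Gw)
  rss0 <- sum(ry^2)
  tss <- sum((yw - X0w %*% qr.coef(qr0, yw))^2) + 0  # = rss0 under null
  mm <- colSums(RM^2)
  num <- as.numeric(crossprod(RM, ry))
  ok <- mm > 1e-10
  beta <- ifelse(ok, num / mm, NA_real_)
  rss1 <- rss0 - ifelse(ok, num^2 / mm, 0)
  df2 <- n - p0 - 1L
  Fst <- (rss0 - rss1) / (rss1 / df2)
  p <- ifelse(ok, stats::pf(Fst, 1, df2, lower.tail = FALSE), NA_real_)
  # total (weighted) SS around the fitted-intercept projection for marker r2
  tss_w <- sum(qr.resid(qr(matrix(X0w[, 1], n)), yw)^2)
  data.frame(marker = map$marker, chrom = map$chrom, pos = map$pos,
             p_value = p, effect = beta,
             marker_r2 = ifelse(ok, (rss0 - rss1) / tss_w, NA_real_),
             stringsAsFactors = FALSE)
}

#' Mixed-linear-model association scan (EMMA with P3D)
#'
#' Null model \eqn{y = X\beta + u + e} with \eqn{u \sim N(0, \sigma^2_g K)}:
#' K is eigendecomposed once, the variance ratio
#' \eqn{\delta = \sigma^2_e/\sigma^2_g} is REML-optimized on the rotated 1-D
#' likelihood, then (P3D) the variance components are frozen and every
#' marker is tested by a generalized-least-squares F-test adding the marker
#' to the fixed effects. \code{marker_r2} is the marker's incremental model
#' R-squared on the rotated (whitened) scale.
#'
#' @param y named phenotype vector aligned with panel samples (e.g. BLUPs).
#' @param panel genotype panel.
#' @param K kinship matrix (samples x samples), e.g.
#'   \code{\link{kinship_centered_ibs}}.
#' @param n_pcs number of genotype principal components as covariates (0-10).
#' @return list: \code{records} data.frame (marker, chrom, pos, p_value,
#'   effect, marker_r2), \code{delta}, \code{sigma2_g}, \code{sigma2_e}.
#' @export
mlm_scan <- function(y, panel, K, n_pcs = 0) {
  geno <- panel$geno
  ids <- intersect(rownames(geno), names(y))
  if (!length(ids)) stop("no samples shared between y and panel")
  y <- y[ids]
  geno <- geno[ids, , drop = FALSE]
  K <- K[ids, ids]
  X0 <- matrix(1, length(ids), 1)
  if (n_pcs > 0) {
    pcs <- genotype_pca(list(geno = geno, map = panel$map), n_pcs)$scores
    X0 <- cbind(X0, pcs)
  }
  eig <- eigen(K, symmetric = TRUE)
  lambda <- pmax(eig$values, 0)
  U <- eig$vectors
  ystar <- as.numeric(crossprod(U, y))
  X0star <- crossprod(U, X0)
  vc <- emma_reml_delta(ystar, X0star, lambda)
  w <- 1 / (lambda + vc$delta)
  sw <- sqrt(w)
  G <- geno
  G[is.na(G)] <- matrix(colMeans(geno, na.rm = TRUE),
                        nrow(geno), ncol(geno), byrow = TRUE)[is.na(G)]
  Gstar <- crossprod(U, G)
  rec <- scan_markers(ystar * sw, X0star * sw, Gstar * sw, panel$map,
                      colMeans(geno, na.rm = TRUE))
  list(records = rec, delta = vc$delta, sigma2_g = vc$sigma2_g,
       sigma2_e = vc$sigma2_e)
}

#' Fixed-effects (GLM) association scan
#'
#' Ordinary least-squares regression of the phenotype on each marker with
#' optional principal-component covariates; per-marker F-test. Equals
#' \code{\link{mlm_scan}} when the kinship contribution vanishes
#' (\eqn{\delta \to \infty} or K = I).
#'
#' @inheritParams mlm_scan
#' @return list with \code{records} as in \code{\link{mlm_scan}}.
#' @export
glm_scan <- function(y, panel, n_pcs = 0) {
  geno <- panel$geno
  ids <- intersect(rownames(geno), names(y))
  y <- y[ids]
  geno <- geno[ids, , drop = FALSE]
  X0 <- matrix(1, length(ids), 1)
  if (n_pcs > 0)
    X0 <- cbind(X0, genotype_pca(list(geno = geno, map = panel$map),
                                 n_pcs)$scores)
  G <- geno
  G[is.na(G)] <- matrix(colMeans(geno, na.rm = TRUE),
                        nrow(geno), ncol(geno), byrow = TRUE)[is.na(G)]
  rec <- scan_markers(y, X0, G, panel$map, colMeans(geno, na.rm = TRUE))
  list(records = rec)
}

#' Effective number of independent tests (eigenvalue counting)
#'
#' Per chromosome, the marker-marker correlation matrix is eigendecomposed
#' in non-overlapping windows of at most \code{block_size} markers and each
#' block contributes \eqn{M_e = \sum_i [I(\lambda_i \ge 1) + (\lambda_i -
#' \lfloor\lambda_i\rfloor)]}; the genome-wide effective number is the sum
#' over blocks.
#'
#' @param panel genotype panel.
#' @param block_size maximum window size per eigendecomposition.
#' @return scalar Me.
#' @export
effective_tests <- function(panel, block_size = 500) {
  geno <- panel$geno; map <- panel$map
  if (ncol(geno) < 2L) return(as.numeric(ncol(geno)))
  me <- 0
  for (chr in unique(map$chrom)) {
    idx <- which(map$chrom == chr)
    for (start in seq(1L, length(idx), by = block_size)) {
      blk <- idx[start:min(start + block_size - 1L, length(idx))]
      if (length(blk) == 1L) { me <- me + 1; next }
      G <- geno[, blk, drop = FALSE]
      G[is.na(G)] <- matrix(colMeans(geno[, blk, drop = FALSE], na.rm = TRUE),
                            nrow(G), ncol(G), byrow = TRUE)[is.na(G)]
      cc <- suppressWarnings(stats::cor(G))
      cc[!is.finite(cc)] <- 0; diag(cc) <- 1
      ev <- eigen(cc, symmetric = TRUE, only.values = TRUE)$values
      # round before the floor: exact duplicates must land on the integer,
      # not a hair below it (the counting rule is discontinuous there)
      ev <- round(pmax(ev, 0), 8)
      me <- me + sum((ev >= 1) + (ev - floor(ev)))
    }
  }
  me
}

#' Significance thresholds from the effective number of tests
#'
#' Modified Bonferroni correction: suggestive = 1/Me and significant =
#' 0.05/Me, so significant is exactly 0.05 x suggestive.
#'
#' @param me effective number of independent tests.
#' @return list: \code{me}, \code{suggestive}, \code{significant}.
#' @export
thresholds <- function(me) {
  if (me < 1) stop("Me must be >= 1")
  list(me = me, suggestive = 1 / me, significant = 0.05 / me)
}

#' QQ coordinates and genomic inflation factor
#'
#' Expected -log10 p from uniform order statistics (i/(M+1)) against the
#' observed sorted values, plus \eqn{\lambda_{GC} =
#' \mathrm{median}(\chi^2_1(p)) / \mathrm{median}(\chi^2_1)}.
#'
#' @param p_values vector of p-values (>= 10); zeros are clipped to the
#'   smallest positive double with a warning.
#' @return list: \code{qq} data.frame(expected, observed) in -log10 units,
#'   \code{lambda_gc}.
#' @export
qq_lambda <- function(p_values) {
  p <- p_values[is.finite(p_values)]
  if (length(p) < 10L) stop("need >= 10 p-values")
  if (any(p <= 0)) {
    warning("p-value(s) <= 0 clipped to machine minimum")
    p[p <= 0] <- .Machine$double.xmin
  }
  M <- length(p)
  qq <- data.frame(expected = -log10(seq_len(M) / (M + 1)),
                   observed = -log10(sort(p)))
  chi <- stats::qchisq(p, df = 1, lower.tail = FALSE)
  list(qq = qq,
       lambda_gc = stats::median(chi) / stats::qchisq(0.5, df = 1))
}

#' Candidate-gene intervals around significant markers
#'
#' For each marker with p below the significant threshold, the candidate
#' interval runs from the nearest non-significant SNP to its left to the
#' nearest to its right (falling back to the chromosome's first/last mapped
#' position when none exists). Genes overlapping the interval are listed
#' with their signed distance from the index SNP (0 when the SNP lies inside
#' the gene; otherwise distance to the nearer gene edge, positive when the
#' gene is downstream of the SNP in coordinate direction), reported in kb to
#' 2 decimals.
#'
#' @param records GWAS records (sorted output of a scan).
#' @param thr threshold set from \code{\link{thresholds}}.
#' @param genes gene table from \code{\link{read_annotation}}.
#' @return data.frame: index SNP, interval bounds, overlapping gene, signed
#'   \code{distance_kb}, annotation.
#' @export
candidate_regions <- function(records, thr, genes) {
  sig <- which(records$p_value < thr$significant)
  out <- list()
  for (s in sig) {
    chr <- records$chrom[s]; pos <- records$pos[s]
    same <- records[records$chrom == chr, , drop = FALSE]
    nonsig <- same[same$p_value >= thr$significant, , drop = FALSE]
    left <- nonsig$pos[nonsig$pos < pos]
    right <- nonsig$pos[nonsig$pos > pos]
    lo <- if (length(left)) max(left) else min(same$pos)
    hi <- if (length(right)) min(right) else max(same$pos)
    hit <- genes[genes$chrom == chr & genes$end >= lo & genes$start <= hi, ,
                 drop = FALSE]
    if (!nrow(hit)) next
    dist_bp <- ifelse(hit$start <= pos & pos <= hit$end, 0,
                      ifelse(hit$start > pos, hit$start - pos,
                             hit$end - pos))
    out[[length(out) + 1L]] <- data.frame(
      marker = records$marker[s], chrom = chr, pos = pos,
      p_value = records$p_value[s],
      interval_lo = lo, interval_hi = hi,
      gene = hit$gene, gene_start = hit$start, gene_end = hit$end,
      distance_kb = round(dist_bp / 1000, 2),
      annotation = hit$annotation, stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(marker = character(), chrom = character(),
                      pos = integer(), p_value = numeric(),
                      interval_lo = integer(), interval_hi = integer(),
                      gene = character(), gene_start = integer(),
                      gene_end = integer(), distance_kb = numeric(),
                      annotation = character(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
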
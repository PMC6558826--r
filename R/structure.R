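# Kinship, PCA, an EM admixture model with cross-validated choice of K,
# cluster-vs-category tests, and IBS distance export for network tools.

#' Centered-IBS genomic relationship matrix
#'
#' VanRaden-style scaling: dosages are column-centered by 2*p-hat (missing
#' dosages imputed to the column mean first) and \eqn{K = WW' / (2\sum
#' \hat p(1-\hat p))}. Monomorphic columns are dropped with a warning. A
#' diagonal ridge of 1e-8 keeps the matrix numerically positive
#' semi-definite.
#'
#' @param panel genotype panel (or bare dosage matrix).
#' @return samples x samples symmetric relationship matrix.
#' @export
kinship_centered_ibs <- function(panel) {
  geno <- if (is.list(panel)) panel$geno else panel
  if (nrow(geno) < 2L) stop("need >= 2 samples")
  p <- colMeans(geno, na.rm = TRUE) / 2
  poly <- p > 0 & p < 1
  if (!all(poly)) {
    warning(sum(!poly), " monomorphic marker(s) dropped from kinship")
    geno <- geno[, poly, drop = FALSE]; p <- p[poly]
  }
  W <- sweep(geno, 2L, 2 * p)
  W[is.na(W)] <- 0  # mean imputation: centered missing dosage is 0
  K <- tcrossprod(W) / (2 * sum(p * (1 - p)))
  K + diag(1e-8, nrow(K))
}

#' Principal components of the genotype matrix
#'
#' SVD of the column-centered (mean-imputed) dosage matrix. Score signs are
#' fixed by making the largest-magnitude loading of each component positive,
#' so results are deterministic.
#'
#' @param panel genotype panel (or bare dosage matrix).
#' @param n_components number of PCs (< min(samples, markers)).
#' @return list: \code{scores} (samples x n_components),
#'   \code{explained_var} (proportions, non-increasing), \code{loadings}.
#' @export
genotype_pca <- function(panel, n_components = 5) {
  geno <- if (is.list(panel)) panel$geno else panel
  if (n_components >= min(dim(geno))) stop("n_components too large")
  X <- scale(geno, center = TRUE, scale = FALSE)
  X[is.na(X)] <- 0
  if (all(abs(X) < 1e-12)) stop("constant genotype matrix")
  sv <- svd(X, nu = n_components, nv = n_components)
  flip <- vapply(seq_len(n_components), function(k) {
    v <- sv$v[, k]; sign(v[which.max(abs(v))])
  }, 0)
  scores <- sweep(sv$u %*% diag(sv$d[seq_len(n_components)],
                                n_components), 2L, flip, `*`)
  rownames(scores) <- rownames(geno)
  colnames(scores) <- paste0("PC", seq_len(n_components))
  list(scores = scores,
       explained_var = sv$d^2 / sum(sv$d^2),
       loadings = sweep(sv$v, 2L, flip, `*`))
}

admixture_loglik <- function(geno, Q, P, eps = 1e-9) {
  Fq <- Q %*% P
  Fq <- pmin(pmax(Fq, eps), 1 - eps)
  sum(geno * log(Fq) + (2 - geno) * log(1 - Fq), na.rm = TRUE)
}

admixture_em_once <- function(geno, K, max_iter, tol, eps = 1e-6) {
  n <- nrow(geno); m <- ncol(geno)
  obs <- !is.na(geno)
  g <- geno; g[!obs] <- 0
  Q <- matrix(stats::rgamma(n * K, 1), n, K); Q <- Q / rowSums(Q)
  base <- colSums(g) / (2 * colSums(obs))
  P <- matrix(pmin(pmax(rep(base, each = K) +
                          stats::rnorm(K * m, 0, 0.05), eps), 1 - eps), K, m)
  ll_trace <- numeric(0)
  ll_old <- -Inf
  for (iter in seq_len(max_iter)) {
    Fq <- pmin(pmax(Q %*% P, eps), 1 - eps)
    # responsibilities summed analytically: expected allele-copy counts per k
    A <- (g / Fq) * obs          # alt-copy scaling, n x m
    B <- ((2 - g) / (1 - Fq)) * obs
    Pnum <- matrix(0, K, m); Pden <- matrix(0, K, m)
    Qnew <- matrix(0, n, K)
    for (k in seq_len(K)) {
      ak <- outer(Q[, k], P[k, ]) * A      # expected alt copies from pop k
      bk <- outer(Q[, k], 1 - P[k, ]) * B  # expected ref copies from pop k
      Pnum[k, ] <- colSums(ak)
      Pden[k, ] <- colSums(ak + bk)
      Qnew[, k] <- rowSums(ak + bk)
    }
    P <- pmin(pmax(Pnum / pmax(Pden, 1e-300), eps), 1 - eps)
    Q <- Qnew / rowSums(Qnew)
    ll <- admixture_loglik(geno, Q, P, eps)
    ll_trace <- c(ll_trace, ll)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  list(Q = Q, P = P, loglik = ll_trace)
}

#' Maximum-likelihood admixture model by EM
#'
#' Fits per-sample ancestry proportions Q (n x K, rows summing to 1) and
#' ancestral alternate-allele frequencies P (K x markers) by EM on the
#' binomial admixture likelihood
#' \deqn{\ell = \sum_{i,l} g_{il}\log(\sum_k q_{ik} p_{kl}) +
#'   (2-g_{il})\log(\sum_k q_{ik}(1-p_{kl}))}
#' from seeded random initializations; the best of \code{restarts} runs (by
#' final log-likelihood) is returned. The log-likelihood is non-decreasing
#' across iterations within a run.
#'
#' @param panel genotype panel (or bare dosage matrix).
#' @param K number of ancestral components (1 <= K <= samples).
#' @param seed RNG seed.
#' @param max_iter,tol EM stopping rule (|delta loglik| < tol).
#' @param restarts random restarts (default 5).
#' @return list: \code{K}, \code{Q}, \code{P}, \code{loglik} (trace of the
#'   best run).
#' @export
admixture_fit <- function(panel, K, seed = 1, max_iter = 300, tol = 1e-4,
                          restarts = 5) {
  geno <- if (is.list(panel)) panel$geno else panel
  if (K < 1 || K > nrow(geno)) stop("K must be in [1, samples]")
  if (K == 1) {
    obs <- !is.na(geno); g <- geno; g[!obs] <- 0
    P <- matrix(colSums(g) / (2 * colSums(obs)), 1)
    Q <- matrix(1, nrow(geno), 1, dimnames = list(rownames(geno), NULL))
    return(list(K = 1L, Q = Q, P = P,
                loglik = admixture_loglik(geno, Q, P)))
  }
  set.seed(seed)
  best <- NULL
  for (r in seq_len(restarts)) {
    fit <- admixture_em_once(geno, K, max_iter, tol)
    if (is.null(best) || utils::tail(fit$loglik, 1) > utils::tail(best$loglik, 1))
      best <- fit
  }
  rownames(best$Q) <- rownames(geno)
  list(K = as.integer(K), Q = best$Q, P = best$P, loglik = best$loglik)
}

#' Align admixture components across runs
#'
#' Resolves label switching by matching columns of Q to a reference Q,
#' minimizing total absolute difference over component permutations
#' (exhaustive for K <= 7, greedy beyond).
#'
#' @param Q admixture matrix to relabel.
#' @param Q_ref reference with the same dimensions.
#' @return Q with columns permuted to best match \code{Q_ref}.
#' @export
align_components <- function(Q, Q_ref) {
  K <- ncol(Q)
  stopifnot(identical(dim(Q), dim(Q_ref)))
  cost <- sapply(seq_len(K), function(a)
    sapply(seq_len(K), function(b) sum(abs(Q[, a] - Q_ref[, b]))))
  cost <- matrix(cost, K, K)  # cost[b, a]: assign column a of Q to slot b
  if (K <= 7) {
    perms <- permutations_of(K)
    tot <- apply(perms, 1L, function(pm) sum(cost[cbind(seq_len(K), pm)]))
    best <- perms[which.min(tot), ]
  } else {
    best <- integer(K); used <- rep(FALSE, K)
    for (b in seq_len(K)) {
      a <- order(cost[b, ])[!used[order(cost[b, ])]][1]
      best[b] <- a; used[a] <- TRUE
    }
  }
  Q[, best, drop = FALSE]
}

permutations_of <- function(K) {
  if (K == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(K - 1L)
  do.call(rbind, lapply(seq_len(K), function(pos) {
    res <- apply(sub, 1L, function(r) append(r, K, after = pos - 1L))
    matrix(as.integer(res), ncol = K, byrow = TRUE)
  }))
}

#' Choose the number of admixture components by held-out deviance
#'
#' Masks a random fraction of the non-missing genotype entries, fits the
#' admixture model on the remainder for each K, and scores the masked
#' entries by binomial deviance \eqn{-2\sum[g\log f + (2-g)\log(1-f)]} at
#' the fitted allele-dose probabilities f. The recommended K minimizes the
#' held-out deviance (ties go to the smallest K).
#'
#' @param panel genotype panel (or bare dosage matrix).
#' @param K_range candidate K values (default 1:10).
#' @param mask_frac fraction of non-missing entries held out (default 0.05).
#' @param seed RNG seed (controls mask and EM starts).
#' @param restarts,max_iter,tol passed to \code{\link{admixture_fit}}.
#' @return list: \code{cv} data.frame(K, cv_deviance), \code{best_k}.
#' @export
choose_k <- function(panel, K_range = 1:10, mask_frac = 0.05, seed = 1,
                     restarts = 3, max_iter = 200, tol = 1e-3) {
  geno <- if (is.list(panel)) panel$geno else panel
  if (!length(K_range)) stop("empty K_range")
  set.seed(seed)
  obs_idx <- which(!is.na(geno))
  n_mask <- max(1L, round(mask_frac * length(obs_idx)))
  if (length(obs_idx) - n_mask < length(K_range))
    stop("insufficient data after masking")
  mask <- sample(obs_idx, n_mask)
  train <- geno; train[mask] <- NA
  held <- geno[mask]
  eps <- 1e-9
  dev <- vapply(K_range, function(K) {
    fit <- admixture_fit(train, K, seed = seed + K, restarts = restarts,
                         max_iter = max_iter, tol = tol)
    Fq <- pmin(pmax(fit$Q %*% fit$P, eps), 1 - eps)[mask]
    -2 * sum(held * log(Fq) + (2 - held) * log(1 - Fq))
  }, 0)
  list(cv = data.frame(K = K_range, cv_deviance = dev),
       best_k = K_range[which.min(dev)])
}

#' Fisher exact test of cluster membership against a metadata category
#'
#' Hard cluster labels are taken as the argmax of each sample's admixture
#' row; samples with unknown/missing category are excluded. The contingency
#' table is tested exactly for 2x2 tables or totals <= 30, and by seeded
#' Monte Carlo (>= 1e5 resamples) otherwise.
#'
#' @param Q admixture proportions (samples x K), rownames = sample IDs.
#' @param sample_table metadata with \code{sample} column.
#' @param category metadata column name (e.g. \code{"subspecies"}).
#' @param n_mc Monte Carlo resamples for large tables.
#' @param seed RNG seed for the Monte Carlo branch.
#' @return list: \code{p_value}, \code{table}, \code{method},
#'   \code{mc_se} (NA for the exact branch).
#' @export
cluster_vs_category <- function(Q, sample_table, category, n_mc = 1e5,
                                seed = 1) {
  cl <- apply(Q, 1L, which.max)
  cat_vals <- sample_table[[category]][match(rownames(Q), sample_table$sample)]
  keep <- !is.na(cat_vals) & cat_vals != "unknown"
  tab <- table(cluster = cl[keep], category = cat_vals[keep])
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2L || ncol(tab) < 2L)
    stop("need >= 2 levels on both margins")
  exact <- (nrow(tab) == 2L && ncol(tab) == 2L) || sum(tab) <= 30
  if (exact) {
    ft <- stats::fisher.test(tab)
    list(p_value = ft$p.value, table = tab, method = "exact", mc_se = NA_real_)
  } else {
    set.seed(seed)
    ft <- stats::fisher.test(tab, simulate.p.value = TRUE, B = n_mc)
    p <- ft$p.value
    list(p_value = p, table = tab, method = "monte-carlo",
         mc_se = sqrt(p * (1 - p) / n_mc))
  }
}

#' Identity-by-state distance matrix
#'
#' \eqn{d_{ij} = 1 -} mean allele-sharing score over markers non-missing in
#' both samples; the sharing score is 1, 0.5, 0 for dosage pairs differing
#' by 0, 1, 2. Pairs with no shared markers get NA with a warning.
#'
#' @param panel genotype panel (or bare dosage matrix).
#' @return samples x samples symmetric distance matrix, zero diagonal.
#' @export
ibs_distance <- function(panel) {
  geno <- if (is.list(panel)) panel$geno else panel
  if (nrow(geno) < 3L) stop("need >= 3 samples")
  obs <- !is.na(geno)
  g <- geno; g[!obs] <- 0
  storage.mode(g) <- "double"; storage.mode(obs) <- "double"
  shared <- tcrossprod(obs)                      # markers scored per pair
  # sum over shared markers of |gi - gj| via expansion:
  # |a-b| = a + b - 2*min(a,b); use indicator decomposition instead
  d_abs <- matrix(0, nrow(geno), nrow(geno))
  for (a in 0:2) for (b in 0:2) {
    if (a >= b) next
    Ia <- (geno == a) & obs; Ib <- (geno == b) & obs
    storage.mode(Ia) <- "double"; storage.mode(Ib) <- "double"
    cross <- tcrossprod(Ia, Ib)
    d_abs <- d_abs + (b - a) * (cross + t(cross))
  }
  D <- ifelse(shared > 0, d_abs / (2 * shared), NA_real_)
  if (anyNA(D)) warning("sample pair(s) with no shared markers")
  diag(D) <- 0
  dimnames(D) <- list(rownames(geno), rownames(geno))
  D
}

#' Write a NEXUS distances block
#'
#' Exports an IBS distance matrix in the NEXUS DISTANCES format consumed by
#' SplitsTree-style network tools.
#'
#' @param D symmetric distance matrix with sample dimnames.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_nexus_distances <- function(D, path) {
  n <- nrow(D)
  labels <- gsub("[^A-Za-z0-9_.]", "_", rownames(D))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#NEXUS", "", "BEGIN TAXA;",
               paste0("  DIMENSIONS NTAX=", n, ";"),
               "  TAXLABELS", paste0("    ", labels), "  ;", "END;", "",
               "BEGIN DISTANCES;",
               paste0("  DIMENSIONS NTAX=", n, ";"),
               "  FORMAT TRIANGLE=LOWER DIAGONAL LABELS=LEFT;",
               "  MATRIX"), con)
  for (i in seq_len(n))
    writeLines(paste0("    ", labels[i], " ",
                      paste(format(D[i, seq_len(i)], digits = 6),
                            collapse = " ")), con)
  writeLines(c("  ;", "END;"), con)
  invisible(path)
}
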
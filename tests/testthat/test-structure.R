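test_that("centered-IBS kinship has the expected scaling", {
  set.seed(61)
  g <- matrix(rbinom(30 * 500, 2, runif(500, 0.1, 0.5)), 30, 500, byrow = TRUE)
  g <- rbind(g, g[1, ])  # duplicate of sample 1
  rownames(g) <- paste0("s", seq_len(nrow(g)))
  K <- suppressWarnings(kinship_centered_ibs(toy_panel(g)))
  expect_true(isSymmetric(K))
  expect_equal(K["s1", "s31"], K["s1", "s1"], tolerance = 1e-6)
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > -1e-8))

  # unstructured panel: mean off-diagonal ~ 0
  set.seed(62)
  g2 <- matrix(rbinom(200 * 2000, 2, rep(runif(2000, 0.1, 0.5), each = 200)),
               200, 2000)
  K2 <- suppressWarnings(kinship_centered_ibs(toy_panel(g2)))
  expect_lt(abs(mean(K2[upper.tri(K2)])), 0.02)

  # fully inbred panel (no heterozygotes): mean diagonal ~ 2
  g3 <- matrix(2L * rbinom(100 * 1000, 1, rep(runif(1000, 0.1, 0.5),
                                              each = 100)), 100, 1000)
  K3 <- suppressWarnings(kinship_centered_ibs(toy_panel(g3)))
  expect_equal(mean(diag(K3)), 2, tolerance = 0.15)
})

test_that("PCA separates differentiated populations and is deterministic", {
  sim <- simulate_bn_panel(80, 600, K = 2, fst = 0.3, seed = 63)
  pca <- genotype_pca(sim$panel, 3)
  pc1 <- split(pca$scores[, 1], sim$truth$labels)
  expect_true(max(pc1[[1]]) < min(pc1[[2]]) || max(pc1[[2]]) < min(pc1[[1]]))
  expect_true(all(diff(pca$explained_var) <= 1e-12))
  # invariance to marker order
  perm <- sample(ncol(sim$panel$geno))
  p2 <- list(geno = sim$panel$geno[, perm], map = sim$panel$map[perm, ])
  pca2 <- genotype_pca(p2, 3)
  expect_equal(abs(pca$scores), abs(pca2$scores), tolerance = 1e-8)
})

test_that("K = 1 admixture reduces to observed frequencies", {
  set.seed(64)
  g <- matrix(rbinom(20 * 50, 2, 0.3), 20, 50)
  g[sample(length(g), 30)] <- NA
  fit <- admixture_fit(toy_panel(g), 1)
  expect_equal(as.numeric(fit$Q), rep(1, 20))
  expect_equal(as.numeric(fit$P),
               colSums(g, na.rm = TRUE) / (2 * colSums(!is.na(g))))
  # loglik equals the binomial likelihood at those frequencies
  f <- pmin(pmax(as.numeric(fit$P), 1e-9), 1 - 1e-9)
  ll <- sum(t(g) * log(f) + (2 - t(g)) * log(1 - f), na.rm = TRUE)
  expect_equal(fit$loglik, ll)
})

test_that("EM loglik never decreases and Q recovers hard BN truth", {
  sim <- simulate_bn_panel(90, 400, K = 3, fst = 0.3, seed = 65)
  fit <- admixture_fit(sim$panel, 3, seed = 2, restarts = 2)
  expect_true(all(diff(fit$loglik) > -1e-6))
  expect_true(all(abs(rowSums(fit$Q) - 1) < 1e-6))
  Qa <- align_components(fit$Q, sim$truth$Q)
  expect_lt(mean(abs(Qa - sim$truth$Q)), 0.05)
})

test_that("held-out deviance selects K = 1 for unstructured panels, reproducibly", {
  sim <- simulate_bn_panel(80, 300, K = 1, fst = 0.1, seed = 66)
  ck <- choose_k(sim$panel, K_range = 1:3, seed = 4, restarts = 2)
  expect_equal(ck$best_k, 1L)
  ck2 <- choose_k(sim$panel, K_range = 1:3, seed = 4, restarts = 2)
  expect_identical(ck$cv, ck2$cv)
})

test_that("cluster-category Fisher test matches hypergeometric arithmetic", {
  Q <- rbind(matrix(rep(c(0.9, 0.1), each = 5), 5),
             matrix(rep(c(0.1, 0.9), each = 5), 5))
  rownames(Q) <- paste0("s", 1:10)
  tab <- data.frame(sample = rownames(Q),
                    grp = rep(c("x", "y"), each = 5))
  res <- cluster_vs_category(Q, tab, "grp")
  expect_equal(res$method, "exact")
  expect_equal(res$p_value, 2 / choose(10, 5) * 1, tolerance = 1e-9)
  expect_error(cluster_vs_category(Q, transform(tab, grp = "x"), "grp"),
               "2 levels")
})

test_that("the exact test keeps its size under independent margins", {
  set.seed(67)
  reject <- vapply(1:500, function(r) {
    cl <- sample(1:2, 24, TRUE)
    gp <- sample(c("a", "b"), 24, TRUE)
    Q <- matrix(0, 24, 2); Q[cbind(1:24, cl)] <- 1
    rownames(Q) <- paste0("s", 1:24)
    tab <- data.frame(sample = rownames(Q), grp = gp)
    p <- tryCatch(cluster_vs_category(Q, tab, "grp")$p_value,
                  error = function(e) NA_real_)
    !is.na(p) && p <= 0.05
  }, TRUE)
  expect_lte(mean(reject), 0.08)
})

test_that("IBS distances behave like a metric on dosage space", {
  g_same <- rbind(c(0L, 1L, 2L), c(0L, 1L, 2L), c(2L, 1L, 0L))
  D <- ibs_distance(toy_panel(g_same))
  expect_equal(D[1, 2], 0)
  expect_equal(unname(diag(D)), rep(0, 3))
  g_opp <- rbind(rep(0L, 4), rep(2L, 4), rep(1L, 4))
  D2 <- ibs_distance(toy_panel(g_opp))
  expect_equal(D2[1, 2], 1)
  set.seed(68)
  g <- matrix(sample(0:2, 12 * 40, TRUE), 12, 40)
  D3 <- ibs_distance(toy_panel(g))
  for (i in 1:10) for (j in (i + 1):11) for (k in (j + 1):12)
    expect_lte(D3[i, k], D3[i, j] + D3[j, k] + 1e-12)
})

test_that("NEXUS export is a well-formed distances block", {
  set.seed(69)
  D <- ibs_distance(toy_panel(matrix(sample(0:2, 5 * 30, TRUE), 5, 30)))
  f <- tempfile(fileext = ".nex")
  write_nexus_distances(D, f)
  lines <- readLines(f)
  expect_equal(lines[1], "#NEXUS")
  expect_true(any(grepl("BEGIN DISTANCES;", lines)))
  expect_true(any(grepl("NTAX=5", lines)))
})

test_that("kinship eigenvectors agree with genotype PCA up to rotation", {
  sim <- simulate_bn_panel(60, 500, K = 2, fst = 0.25, seed = 70)
  K <- suppressWarnings(kinship_centered_ibs(sim$panel))
  eg <- eigen(K, symmetric = TRUE)
  pca <- genotype_pca(sim$panel, 2)
  # subspace correlation: canonical correlations of top-2 spaces near 1
  cc <- svd(crossprod(qr.Q(qr(eg$vectors[, 1:2])),
                      qr.Q(qr(pca$scores))))$d
  expect_gt(min(cc), 0.99)
})
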
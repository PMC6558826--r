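make_trait_table <- function(g_true, n_envs, n_reps, sd_e, seed,
                             trait = "t") {
  set.seed(seed)
  env_eff <- rnorm(n_envs, 0, 1)
  do.call(rbind, lapply(seq_len(n_envs), function(e)
    do.call(rbind, lapply(seq_len(n_reps), function(r)
      data.frame(sample = names(g_true), trait = trait,
                 env = paste0("E", e, "R", r),
                 value = 5 + env_eff[e] + g_true + rnorm(length(g_true), 0, sd_e))))))
}

test_that("BLUPs approach adjusted genotype means as residual variance vanishes", {
  set.seed(81)
  g_true <- setNames(rnorm(40, 0, 1), paste0("s", 1:40))
  tt <- make_trait_table(g_true, n_envs = 3, n_reps = 1, sd_e = 1e-3, seed = 81)
  bl <- fit_blups(tt, "t")
  expect_gt(cor(bl$blup[names(g_true)], g_true), 0.9999)
  expect_equal(unname(coef(lm(bl$blup[names(g_true)] ~ g_true))[2]), 1,
               tolerance = 1e-2)
})

test_that("REML variance components are recovered on balanced data", {
  set.seed(82)
  errs <- vapply(1:5, function(r) {
    g_true <- setNames(rnorm(100, 0, sqrt(2)), paste0("s", 1:100))
    tt <- make_trait_table(g_true, n_envs = 3, n_reps = 1, sd_e = 1,
                           seed = 820 + r)
    bl <- fit_blups(tt, "t")
    bl$sigma2_g / bl$sigma2_e
  }, 0)
  expect_lt(abs(mean(errs) - 2) / 2, 0.15)
})

test_that("shrinkage makes BLUPs beat raw means at low heritability", {
  set.seed(83)
  wins <- vapply(1:10, function(r) {
    g_true <- setNames(rnorm(80, 0, 0.4), paste0("s", 1:80))
    tt <- make_trait_table(g_true, n_envs = 3, n_reps = 1, sd_e = 1,
                           seed = 830 + r)
    bl <- fit_blups(tt, "t")
    raw <- tapply(tt$value, tt$sample, mean)[names(g_true)]
    cor(bl$blup[names(g_true)], g_true) >= cor(raw, g_true) - 0.02
  }, TRUE)
  expect_gte(mean(wins), 0.9)
})

test_that("MLM with identity kinship equals the OLS scan at every marker", {
  sim <- simulate_bn_panel(60, 150, K = 2, fst = 0.2, seed = 84)
  set.seed(84)
  y <- setNames(rnorm(60), rownames(sim$panel$geno))
  Ki <- diag(60); dimnames(Ki) <- list(names(y), names(y))
  m <- mlm_scan(y, sim$panel, Ki, n_pcs = 0)$records
  g <- glm_scan(y, sim$panel, n_pcs = 0)$records
  ok <- !is.na(m$p_value)
  expect_lt(max(abs(log10(m$p_value[ok]) - log10(g$p_value[ok]))), 1e-6)
  expect_equal(m$effect[ok], g$effect[ok], tolerance = 1e-6)
})

test_that("P3D p-values track full per-marker REML refits", {
  sim <- simulate_bn_panel(80, 50, K = 3, fst = 0.25, alpha = 0.2, seed = 85)
  p <- sim$panel
  K <- suppressWarnings(kinship_centered_ibs(p))
  set.seed(85)
  L <- chol(K + diag(1e-6, 80))
  y <- setNames(as.numeric(crossprod(L, rnorm(80))) + rnorm(80, 0, 0.7),
                rownames(p$geno))
  p3d <- mlm_scan(y, p, K, n_pcs = 0)
  eig <- eigen(K, symmetric = TRUE)
  lam <- pmax(eig$values, 0); U <- eig$vectors
  ystar <- as.numeric(crossprod(U, y))
  G <- p$geno; G[is.na(G)] <- 0
  full_p <- vapply(seq_len(50), function(j) {
    Xj <- cbind(1, G[, j])
    Xs <- crossprod(U, Xj)
    vc <- snppanel:::emma_reml_delta(ystar, Xs, lam)
    w <- 1 / (lam + vc$delta); sw <- sqrt(w)
    fit1 <- lm.fit(Xs * sw, ystar * sw)
    fit0 <- lm.fit(Xs[, 1, drop = FALSE] * sw, ystar * sw)
    rss1 <- sum(fit1$residuals^2); rss0 <- sum(fit0$residuals^2)
    Fst <- (rss0 - rss1) / (rss1 / (80 - 2))
    pf(Fst, 1, 80 - 2, lower.tail = FALSE)
  }, 0)
  ok <- !is.na(p3d$records$p_value)
  dd <- abs(log10(p3d$records$p_value[ok]) - log10(full_p[ok]))
  # P3D freezes the variance components, so the typical marker agrees to a
  # few thousandths of a log10 unit; only markers aligned with the leading
  # kinship eigenvectors can shift the per-marker refit materially
  expect_lt(median(dd), 0.05)
  expect_lt(mean(dd > 0.25), 0.1)
})

test_that("mixed model keeps nominal size under a structured polygenic null", {
  sim <- simulate_bn_panel(110, 2000, K = 3, fst = 0.2, alpha = 0.1,
                           seed = 86)
  p <- sim$panel
  K <- suppressWarnings(kinship_centered_ibs(p))
  set.seed(86)
  L <- chol(K + diag(1e-6, nrow(K)))
  y <- setNames(as.numeric(crossprod(L, rnorm(110))) +
                  rnorm(110, 0, sqrt(0.5)), rownames(p$geno))
  m <- mlm_scan(y, p, K, n_pcs = 0)$records
  frac_mlm <- mean(m$p_value < 0.05, na.rm = TRUE)
  expect_gte(frac_mlm, 0.03); expect_lte(frac_mlm, 0.07)
  g <- glm_scan(y, p, n_pcs = 0)$records
  expect_gt(mean(g$p_value < 0.05, na.rm = TRUE), 0.07)
})

test_that("a 30%-variance QTL is the top hit in nearly every replicate", {
  hits <- vapply(1:10, function(r) {
    sim <- simulate_bn_panel(150, 300, K = 2, fst = 0.15, alpha = 0.3,
                             seed = 860 + r)
    p <- sim$panel
    set.seed(860 + r)
    qtl <- 150L
    gq <- p$geno[, qtl]
    vg <- var(gq)
    y <- gq + rnorm(150, 0, sqrt(vg * 0.7 / 0.3))
    names(y) <- rownames(p$geno)
    K <- suppressWarnings(kinship_centered_ibs(p))
    m <- mlm_scan(y, p, K, n_pcs = 0)$records
    which.min(m$p_value) == qtl
  }, TRUE)
  expect_gte(mean(hits), 0.9)
})

test_that("effective test counting follows the eigenvalue rule", {
  # orthogonal design: 4 exactly uncorrelated markers -> Me = 4
  H <- rbind(c(0, 0, 0, 0), c(0, 2, 0, 2), c(0, 0, 2, 2), c(0, 2, 2, 0),
             c(2, 0, 0, 2), c(2, 2, 0, 0), c(2, 0, 2, 0), c(2, 2, 2, 2))
  storage.mode(H) <- "integer"
  p <- toy_panel(H)
  expect_equal(effective_tests(p), 4)
  # duplicating each marker gives eigenvalues {2, 0} per pair -> Me = M/2
  p2 <- toy_panel(H[, rep(1:4, each = 2)])
  expect_equal(effective_tests(p2), 4)
  thr <- thresholds(effective_tests(p2))
  expect_equal(thr$suggestive, 1 / 4)
  expect_equal(thr$significant, 0.05 / 4)
})

test_that("significant threshold is exactly one twentieth of suggestive", {
  for (me in c(1, 2.5, 137.2, 2695)) {
    thr <- thresholds(me)
    expect_equal(thr$significant / thr$suggestive, 0.05)
  }
})

test_that("QQ diagnostics: uniform grid gives lambda 1, deflation detected", {
  p_unif <- (1:2000) / 2001
  ql <- qq_lambda(p_unif)
  expect_equal(ql$lambda_gc, 1, tolerance = 0.01)
  expect_true(all(diff(ql$qq$expected) <= 0))
  expect_true(all(diff(ql$qq$observed) <= 0))
  expect_gt(qq_lambda(p_unif / 2)$lambda_gc, 1)
  expect_warning(qq_lambda(c(p_unif, 0)), "clipped")
})

test_that("candidate intervals report the printed-coordinate distances", {
  # index SNPs with flanking non-significant markers on two chromosomes
  records <- data.frame(
    marker = c("f1", "hit1", "f2", "f3", "hit2", "f4"),
    chrom = rep(c("Araip.B06", "Araip.B07"), each = 3),
    pos = c(3000000L, 3275121L, 4000000L,
            36000000L, 37296448L, 38000000L),
    p_value = c(0.5, 1e-10, 0.4, 0.6, 1e-9, 0.3),
    effect = 0, marker_r2 = 0.3)
  genes <- data.frame(
    gene = c("Araip.D6HPL", "Araip.L66QB", "far.gene"),
    chrom = c("Araip.B06", "Araip.B07", "Araip.B06"),
    start = c(3631192L, 37228337L, 9000000L),
    end = c(3632515L, 37230328L, 9100000L),
    strand = "+", annotation = c("fatty acid desaturase 2",
                                 "flavin-binding monooxygenase", "x"))
  thr <- thresholds(2695)
  cand <- candidate_regions(records, thr, genes)
  d6 <- cand[cand$gene == "Araip.D6HPL", ]
  expect_equal(d6$distance_kb, 356.07)
  l6 <- cand[cand$gene == "Araip.L66QB", ]
  expect_equal(l6$distance_kb, -66.12)
  expect_false("far.gene" %in% cand$gene)
})

test_that("intervals collect exactly the overlapping genes", {
  records <- data.frame(marker = c("a", "b", "c"), chrom = "c1",
                        pos = c(100L, 500L, 900L),
                        p_value = c(0.9, 1e-8, 0.8), effect = 0,
                        marker_r2 = 0.1)
  genes <- data.frame(gene = c("g1", "g2", "g3"), chrom = "c1",
                      start = c(150L, 450L, 2000L),
                      end = c(250L, 600L, 2100L), strand = "+",
                      annotation = "z")
  cand <- candidate_regions(records, thresholds(1000), genes)
  expect_setequal(cand$gene, c("g1", "g2"))
  empty <- candidate_regions(transform(records, p_value = 0.5),
                             thresholds(1000), genes)
  expect_equal(nrow(empty), 0L)
})
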
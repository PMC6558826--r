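test_that("EM haplotype frequencies reproduce textbook cases", {
  # unambiguous data: 5 AB/AB and 5 ab/ab homozygotes -> perfect LD
  g <- c(rep(2L, 5), rep(0L, 5))
  em <- ld_pair(g, g)
  expect_equal(em$d_coef, 0.25)
  expect_equal(em$r2, 1)
  expect_equal(em$dprime, 1)
  # equal counts of all four gametes -> independence
  gi <- c(2L, 2L, 0L, 0L); gj <- c(2L, 0L, 2L, 0L)
  expect_equal(ld_pair(gi, gj)$r2, 0, tolerance = 1e-12)
})

test_that("EM equals the grid-search likelihood oracle with double heterozygotes", {
  set.seed(41)
  n_checked <- 0
  while (n_checked < 8) {
    gi <- sample(0:2, 20, TRUE); gj <- sample(0:2, 20, TRUE)
    if (!any(gi == 1 & gj == 1)) next  # require at least one double het
    em <- ld_pair(gi, gj)
    if (is.na(em$r2)) next
    or <- oracle_ld_grid(gi, gj)
    expect_lt(abs(em$p_ab - or$p_ab), 2e-4)
    expect_lt(abs(em$r2 - or$r2), 1e-3)
    n_checked <- n_checked + 1
  }
})

test_that("EM reduces to direct haplotype counting without double heterozygotes", {
  set.seed(42)
  for (r in 1:5) {
    hi <- rbinom(30, 1, 0.4); hj <- as.integer(runif(30) < 0.3 + 0.5 * hi)
    gi <- hi + hi; gj <- hj + hj  # fully homozygous diploids
    em <- ld_pair(gi, gj)
    or <- oracle_r2(hi, hj)
    if (is.na(em$r2)) next
    expect_equal(em$r2, or$r2, tolerance = 1e-9)
    expect_equal(em$dprime, or$dprime, tolerance = 1e-9)
  }
})

test_that("r2 is symmetric in the pair and invariant to polarity swaps", {
  set.seed(43)
  gi <- sample(0:2, 40, TRUE); gj <- sample(0:2, 40, TRUE)
  expect_equal(ld_pair(gi, gj)$r2, ld_pair(gj, gi)$r2)
  expect_equal(ld_pair(gi, gj)$r2, ld_pair(2L - gi, gj)$r2, tolerance = 1e-9)
  expect_equal(ld_pair(gi, gj)$r2, ld_pair(gi, 2L - gj)$r2, tolerance = 1e-9)
})

test_that("sliding window emits the right pair set and distances", {
  set.seed(44)
  g <- matrix(sample(0:2, 30 * 5, TRUE), 30, 5)
  p <- toy_panel(g, pos = c(100L, 300L, 700L, 1500L, 3100L))
  ld <- sliding_window_ld(p, window = 50)
  expect_equal(nrow(ld), 10L)  # all pairs of 5 markers
  expect_equal(ld$dist_bp, abs(ld$pos_j - ld$pos_i))

  g2 <- matrix(sample(0:2, 40 * 100, TRUE), 40, 100)
  p2 <- toy_panel(g2)
  ld2 <- sliding_window_ld(p2, window = 2)
  expect_equal(nrow(ld2), 99L + 98L)  # adjacent + next-adjacent
})

test_that("background LD is low for independent chromosomes and seeded", {
  set.seed(45)
  g <- matrix(rbinom(200 * 60, 2, 0.35), 200, 60)
  p <- toy_panel(g, chrom = rep(c("c1", "c2", "c3"), each = 20))
  bg1 <- background_ld(p, n_pairs = 500, seed = 7)
  bg2 <- background_ld(p, n_pairs = 500, seed = 7)
  expect_identical(bg1, bg2)
  expect_lt(bg1, 0.2)
  expect_error(background_ld(toy_panel(g[, 1:20]), 100, 1), "2 chromosomes")
})

test_that("binned means follow the worked arithmetic and conserve pairs", {
  ld <- data.frame(dist_bp = c(50, 60, 200), r2 = c(0.8, 0.9, 0.4))
  b <- binned_mean_ld(ld)
  expect_equal(b$n[1], 2L); expect_equal(b$mean_r2[1], 0.85)
  expect_equal(b$n[3], 1L); expect_equal(b$mean_r2[3], 0.4)
  expect_equal(b$n[2], 0L); expect_true(is.na(b$mean_r2[2]))
  big <- data.frame(dist_bp = c(ld$dist_bp, 2e11), r2 = c(ld$r2, 0.1))
  b2 <- binned_mean_ld(big)
  expect_equal(sum(b2$n) + attr(b2, "overflow"), nrow(big))
})

test_that("decay fit recovers a known rho from on-curve data within 5%", {
  set.seed(46)
  rho <- 2e-6
  d <- runif(5000, 1e3, 5e6)
  r2 <- hill_weir_expectation(rho * d, 220) + rnorm(5000, 0, 0.02)
  fit <- fit_decay(data.frame(dist_bp = d, r2 = r2), n_fit = 220)
  expect_lt(abs(fit$rho_hat - rho) / rho, 0.05)
})

test_that("the expectation curve has the right intercept and limit", {
  expect_equal(hill_weir_expectation(0, 226), (10 / 22) * (1 + 36 / (22 * 226)),
               tolerance = 1e-12)
  # the curve plateaus at the finite-sample floor 1/n, not at zero
  expect_equal(hill_weir_expectation(1e9, 226), 1 / 226, tolerance = 1e-4)
  expect_lt(hill_weir_expectation(1e4, 226), hill_weir_expectation(1e2, 226))
})

test_that("decay distances are true roots and scale inversely with rho", {
  fit <- structure(list(rho_hat = 1e-6, n_fit = 220, rss = 0, n_pairs = 100),
                   class = "decay_fit")
  dd <- decay_distances(fit)
  expect_equal(decay_curve(fit, dd[["half_decay_bp"]]),
               0.5 * decay_curve(fit, 0), tolerance = 1e-6)
  expect_equal(decay_curve(fit, dd[["r2_02_bp"]]), 0.2, tolerance = 1e-6)
  fit2 <- structure(list(rho_hat = 2e-6, n_fit = 220, rss = 0, n_pairs = 100),
                    class = "decay_fit")
  dd2 <- decay_distances(fit2)
  expect_equal(dd[["half_decay_bp"]] / dd2[["half_decay_bp"]], 2,
               tolerance = 0.01)
  expect_equal(dd[["r2_02_bp"]] / dd2[["r2_02_bp"]], 2, tolerance = 0.01)
})

test_that("flat-contribution curves are flagged instead of fabricating roots", {
  fit <- structure(list(rho_hat = 1e-6, n_fit = 4, rss = 0, n_pairs = 100),
                   class = "decay_fit")
  # n = 4 keeps curve(0) > 0.2; force the non-bracketing branch via a cap
  dd <- decay_distances(fit, max_distance_bp = 10)
  expect_true(is.na(dd[["half_decay_bp"]]))
})

test_that("loess smooth tracks noiseless data and spans the distance range", {
  d <- seq(1e3, 1e6, length.out = 200)
  r2 <- 0.5 * exp(-d / 2e5)
  sm <- loess_smooth(data.frame(dist_bp = d, r2 = r2), span = 0.4)
  expect_lt(max(abs(sm$r2_smooth -
                      0.5 * exp(-sm$dist_bp / 2e5)), na.rm = TRUE), 0.02)
  expect_equal(range(sm$dist_bp), range(d))
  # very large span approaches a single global quadratic
  sm2 <- loess_smooth(data.frame(dist_bp = d, r2 = r2), span = 50)
  quad <- lm(r2 ~ poly(d, 2, raw = TRUE))
  pred <- predict(quad, newdata = data.frame(d = sm2$dist_bp))
  expect_lt(max(abs(sm2$r2_smooth - pred)), 0.02)
})

test_that("binned mean r2 decays with distance on mosaic-LD panels", {
  cfg <- sim_config(n_samples = 60, n_markers = 400, n_chromosomes = 5,
                    seed = 47)
  sim <- simulate_population(cfg)
  suppressMessages(flt <- filter_markers(sim$panel, 100, 0.05))
  ld <- sliding_window_ld(flt, window = 50)
  b <- binned_mean_ld(ld, c(500, 2000, 8000, 32000, 100000))
  m <- b$mean_r2[b$n >= 20]
  expect_gt(length(m), 2)
  # non-increasing up to sampling noise
  expect_true(all(diff(m) < 0.05))
  expect_gt(m[1], m[length(m)])
})

test_that("stratified LD with a single all-sample stratum matches the plain chain", {
  cfg <- sim_config(n_samples = 40, n_markers = 200, n_chromosomes = 4,
                    missing_rate = 0, seed = 48)
  sim <- simulate_population(cfg)
  tab <- sim$samples; tab$grp <- "all"
  suppressMessages(
    strat <- stratified_ld(sim$panel, tab, stratum_col = "grp",
                           min_known_alleles = 60, window = 20))
  suppressMessages(flt <- filter_markers(sim$panel, 60, 0.05))
  plain <- sliding_window_ld(flt, window = 20)
  expect_equal(strat$all$ld$r2, plain$r2)
  expect_equal(strat$all$fit$rho_hat,
               fit_decay(plain, n_fit = 80)$rho_hat)
})

test_that("per-stratum MAF filtering can drop markers kept genome-wide", {
  # marker polymorphic only in group B: genome-wide MAF passes, within-A fails
  set.seed(49)
  gA <- matrix(rbinom(12 * 30, 2, 0.3), 12, 30)
  gB <- matrix(rbinom(12 * 30, 2, 0.3), 12, 30)
  gA[, 1] <- 0L                     # monomorphic within A
  gB[, 1] <- rbinom(12, 2, 0.5)
  p <- toy_panel(rbind(gA, gB), chrom = rep(c("c1", "c2"), each = 15))
  tab <- data.frame(sample = rownames(p$geno),
                    grp = rep(c("A", "B"), each = 12))
  suppressMessages(
    strat <- stratified_ld(p, tab, stratum_col = "grp", min_samples = 10,
                           min_known_alleles = 10, window = 10))
  expect_false("m1" %in% strat$A$ld$marker_i)
  suppressMessages(fw <- filter_markers(p, 10, 0.05))
  expect_true("m1" %in% fw$map$marker)
})
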
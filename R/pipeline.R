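# Config-driven end-to-end runner: QC -> diversity -> LD (per MAF level) ->
# haplotype blocks -> structure -> GWAS, each stage writing TSV/JSON
# artifacts plus a manifest and run log.

#' Build a validated pipeline configuration
#'
#' Unknown keys are rejected; defaults mirror the standard analysis
#' sequence: MAF levels 0.05/0.1/0.2, 100 known alleles, 50-marker LD
#' window, 2 Mb block cap, K scanned over 1-10.
#'
#' @param ... overrides of the default fields (see source for the full
#'   list: \code{maf_levels}, \code{min_known_alleles}, \code{ld_window},
#'   \code{bin_edges_kb}, \code{background_pairs}, \code{max_span_kb},
#'   \code{k_range}, \code{restarts}, \code{traits}, \code{n_pcs},
#'   \code{model}, \code{out_dir}, \code{seed}).
#' @return list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(...) {
  cfg <- list(maf_levels = c(0.05, 0.1, 0.2), min_known_alleles = 100,
              ld_window = 50, bin_edges_kb = default_ld_bins(),
              background_pairs = 5000, max_span_kb = 2000,
              k_range = 1:10, restarts = 5, traits = NULL, n_pcs = 2,
              model = "mlm", out_dir = "pipeline_out", seed = 1)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config keys: ",
                            paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  if (!cfg$model %in% c("glm", "mlm")) stop("model must be glm or mlm")
  structure(cfg, class = "pipeline_config")
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", row.names = FALSE, quote = FALSE)
  path
}

#' Run the full characterization pipeline
#'
#' Executes QC, diversity, per-MAF-level LD (windowed pairs, binned means,
#' background LD, decay fit), haplotype blocks, structure (kinship, PCA,
#' admixture across a K range with CV choice, category tests when metadata
#' is supplied) and, when traits are supplied, BLUP + association scans with
#' effective-test thresholds and candidate regions. Each stage's artifacts
#' land under \code{cfg$out_dir}; a failing GWAS trait is logged and does
#' not abort the others. A manifest with MD5 checksums and a run log are
#' written last.
#'
#' @param panel genotype panel.
#' @param cfg \code{\link{pipeline_config}}.
#' @param sample_table optional sample metadata.
#' @param traits optional long-format trait table.
#' @param genes optional gene annotation table.
#' @return invisible list of in-memory stage results.
#' @export
run_pipeline <- function(panel, cfg = pipeline_config(), sample_table = NULL,
                         traits = NULL, genes = NULL) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(cfg$out_dir, "run.log")
  logf <- function(...) cat(format(Sys.time(), "%H:%M:%S"), ...,
                            "\n", file = log_path, append = TRUE)
  cat("", file = log_path)
  results <- list()
  logf("pipeline start; seed", cfg$seed, ";", nrow(panel$geno), "samples x",
       ncol(panel$geno), "markers")

  # QC / marker stats
  stats <- marker_summary(panel)
  write_tsv(stats, file.path(cfg$out_dir, "marker_stats.tsv"))
  het <- sample_heterozygosity(panel)
  write_tsv(data.frame(sample = names(het), heterozygosity = het),
            file.path(cfg$out_dir, "sample_heterozygosity.tsv"))
  results$marker_stats <- stats

  # diversity on the unfiltered panel
  div <- diversity_summary(panel)
  write_tsv(div, file.path(cfg$out_dir, "diversity.tsv"))
  results$diversity <- div
  logf("diversity: pi", signif(div$pi, 5), "theta", signif(div$theta_w, 5),
       "D", signif(div$tajima_d, 5))

  # LD chain per MAF level
  results$ld <- list()
  for (maf in cfg$maf_levels) {
    tag <- paste0("maf", maf)
    flt <- filter_markers(panel, cfg$min_known_alleles, maf)
    logf("LD", tag, ":", ncol(flt$geno), "markers after filter")
    ld <- sliding_window_ld(flt, cfg$ld_window)
    binned <- binned_mean_ld(ld, cfg$bin_edges_kb)
    bg <- background_ld(flt, cfg$background_pairs, seed = cfg$seed)
    fit <- fit_decay(ld, n_fit = 2 * nrow(flt$geno))
    dd <- decay_distances(fit)
    write_tsv(ld, file.path(cfg$out_dir, paste0("ld_pairs_", tag, ".tsv")))
    write_tsv(binned, file.path(cfg$out_dir, paste0("ld_binned_", tag, ".tsv")))
    jsonlite::write_json(
      list(rho_hat = fit$rho_hat, n_fit = fit$n_fit, rss = fit$rss,
           half_decay_bp = dd[["half_decay_bp"]],
           r2_02_bp = dd[["r2_02_bp"]], background_r2_90pct = unname(bg)),
      file.path(cfg$out_dir, paste0("ld_decay_", tag, ".json")),
      auto_unbox = TRUE, digits = NA)
    results$ld[[tag]] <- list(panel = flt, ld = ld, binned = binned,
                              background = bg, fit = fit, decay = dd)
  }

  # haplotype blocks on the first MAF level
  flt <- results$ld[[1]]$panel
  blocks <- find_blocks(flt, max_span_kb = cfg$max_span_kb)
  write_tsv(blocks, file.path(cfg$out_dir, "blocks.tsv"))
  write_tsv(block_summary(blocks), file.path(cfg$out_dir, "blocks_summary.tsv"))
  results$blocks <- blocks
  logf("blocks:", nrow(blocks), "found at", cfg$max_span_kb, "kb cap")

  # structure: kinship, PCA, admixture with CV choice of K
  K <- kinship_centered_ibs(flt)
  pca <- genotype_pca(flt, min(5, nrow(flt$geno) - 1))
  ck <- choose_k(flt, K_range = cfg$k_range, seed = cfg$seed,
                 restarts = min(cfg$restarts, 3))
  fit_q <- admixture_fit(flt, ck$best_k, seed = cfg$seed,
                         restarts = cfg$restarts)
  write_tsv(ck$cv, file.path(cfg$out_dir, "choose_k.tsv"))
  write_tsv(data.frame(sample = rownames(fit_q$Q), fit_q$Q),
            file.path(cfg$out_dir, "admixture_Q.tsv"))
  D <- ibs_distance(flt)
  write_nexus_distances(D, file.path(cfg$out_dir, "ibs_distances.nex"))
  results$structure <- list(kinship = K, pca = pca, choose_k = ck,
                            fit = fit_q, dist = D)
  logf("structure: best K =", ck$best_k)
  if (!is.null(sample_table)) {
    for (categ in intersect(c("subspecies", "market_type"),
                            names(sample_table))) {
      ft <- tryCatch(cluster_vs_category(fit_q$Q, sample_table, categ,
                                         seed = cfg$seed),
                     error = function(e) NULL)
      if (!is.null(ft))
        logf("fisher", categ, "p =", signif(ft$p_value, 3))
      results$structure$fisher[[categ]] <- ft
    }
  }

  # GWAS
  if (!is.null(traits)) {
    me <- effective_tests(flt)
    thr <- thresholds(me)
    jsonlite::write_json(thr, file.path(cfg$out_dir, "thresholds.json"),
                         auto_unbox = TRUE, digits = NA)
    trait_names <- if (is.null(cfg$traits)) unique(traits$trait) else cfg$traits
    results$gwas <- list()
    for (tr in trait_names) {
      res <- tryCatch({
        bl <- fit_blups(traits, tr)
        scan <- if (cfg$model == "mlm")
          mlm_scan(bl$blup, flt, K, n_pcs = cfg$n_pcs)
        else glm_scan(bl$blup, flt, n_pcs = cfg$n_pcs)
        rec <- scan$records
        write_tsv(rec, file.path(cfg$out_dir, paste0("gwas_", tr, ".tsv")))
        qq <- qq_lambda(rec$p_value[!is.na(rec$p_value)])
        write_tsv(qq$qq, file.path(cfg$out_dir, paste0("qq_", tr, ".tsv")))
        cand <- if (!is.null(genes)) candidate_regions(rec, thr, genes)
                else NULL
        if (!is.null(cand))
          write_tsv(cand, file.path(cfg$out_dir, paste0("candidates_", tr, ".tsv")))
        logf("gwas", tr, ": lambda_gc", signif(qq$lambda_gc, 3),
             "; min p", signif(min(rec$p_value, na.rm = TRUE), 3))
        list(blups = bl, records = rec, qq = qq, candidates = cand)
      }, error = function(e) {
        logf("gwas", tr, "FAILED:", conditionMessage(e))
        list(error = conditionMessage(e))
      })
      results$gwas[[tr]] <- res
    }
    results$thresholds <- thr
  }

  files <- setdiff(list.files(cfg$out_dir), c("manifest.tsv", "run.log"))
  manifest <- data.frame(
    file = files,
    md5 = vapply(file.path(cfg$out_dir, files), function(f)
      as.character(tools::md5sum(f)), ""), row.names = NULL)
  write_tsv(manifest, file.path(cfg$out_dir, "manifest.tsv"))
  logf("pipeline done;", length(files), "artifacts")
  invisible(results)
}
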
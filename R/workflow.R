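# Two-stage mt-PheWAS orchestration:
#   stage 1 (polygenic prioritization): GRMs + PCs, per-trait full/reduced
#     EM-REML, boundary LRT on the mitochondrial component;
#   stage 2 (single-variant scan): MAF filter, per-trait covariate-adjusted
#     regressions, significance accounting against the expected-by-chance
#     count.
# The scan runs on all traits, not only prioritized ones, so the
# PVE-versus-count consistency check is always reproducible; prioritization
# is reported (and can be enforced with prioritized_only = TRUE).

#' Assemble a pipeline run configuration
#'
#' Either from arguments or from a YAML file (`read_run_config()`). Paths may
#' be `NULL` when genotype/phenotype objects are passed to [run_pipeline()]
#' directly.
#'
#' @param plink_prefix Prefix of the input bed/bim/fam triplet.
#' @param phenotype_file TSV with `sample_id`, trait and covariate columns
#'   (`NA` for missing).
#' @param traits Named vector mapping trait column -> `"continuous"` or
#'   `"binary"`.
#' @param covariates Non-PC covariate columns (default age, sex).
#' @param maf_threshold Minor-allele-frequency cutoff for the mtSNP scan.
#' @param alpha_priority LRT prioritization threshold.
#' @param alpha_suggestive Upper edge of the suggestive band.
#' @param alpha_snp Per-variant significance threshold for the scan.
#' @param n_pcs Number of nuclear PCs used as covariates.
#' @param reml_tol,reml_max_iter EM-REML convergence controls.
#' @param prioritized_only Scan only prioritized/suggestive traits.
#' @param out_dir Output directory (`NULL`: nothing written).
#' @param seed Seed recorded with the outputs.
#' @return A `run_config` list.
#' @export
run_config <- function(plink_prefix = NULL, phenotype_file = NULL,
                       traits = NULL,
                       covariates = c("age", "sex"),
                       maf_threshold = 0.01,
                       alpha_priority = 0.05, alpha_suggestive = 0.055,
                       alpha_snp = 0.05,
                       n_pcs = 2, reml_tol = 1e-6, reml_max_iter = 200L,
                       prioritized_only = FALSE,
                       out_dir = NULL, seed = 1L) {
  traits <- unlist(traits)
  if (length(traits) == 0) stop("at least one trait must be configured", call. = FALSE)
  stopifnot(all(traits %in% c("continuous", "binary")),
            maf_threshold >= 0, maf_threshold <= 0.5,
            alpha_priority > 0, alpha_priority < 1,
            alpha_snp > 0, alpha_snp < 1, n_pcs >= 1)
  structure(list(plink_prefix = plink_prefix, phenotype_file = phenotype_file,
                 traits = traits, covariates = covariates,
                 maf_threshold = maf_threshold,
                 alpha_priority = alpha_priority,
                 alpha_suggestive = alpha_suggestive,
                 alpha_snp = alpha_snp, n_pcs = n_pcs,
                 reml_tol = reml_tol, reml_max_iter = as.integer(reml_max_iter),
                 prioritized_only = prioritized_only,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "run_config")
}

#' @rdname run_config
#' @param path YAML file whose keys match the `run_config()` arguments
#'   (`traits` as a mapping trait: type).
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) stop("unknown config keys: ", paste(unknown, collapse = ", "),
                            call. = FALSE)
  do.call(run_config, vals)
}

#' Fit full and reduced mixed models for one trait
#'
#' Complete-case helper behind the pipeline: subsets phenotype, covariates and
#' both GRMs to samples observed for this trait, fits nuclear+mito and
#' nuclear-only models by EM-REML, and runs the boundary LRT.
#'
#' @param phenotypes Data frame with `sample_id`, the trait and covariates.
#' @param trait Trait column name.
#' @param grm_nuc,grm_mt `relationship_matrix` objects over all samples.
#' @param covariates Covariate column names.
#' @param tol,max_iter Passed to [fit_em_reml()].
#' @return List with `full`, `reduced` (`vc_fit`) and `lrt` (`lrt_result`).
#' @export
fit_mito_model <- function(phenotypes, trait, grm_nuc, grm_mt,
                           covariates = c("age", "sex", "PC1", "PC2"),
                           tol = 1e-6, max_iter = 200L) {
  stopifnot("sample_id" %in% names(phenotypes),
            trait %in% names(phenotypes), all(covariates %in% names(phenotypes)))
  ph <- phenotypes[match(rownames(grm_nuc), phenotypes$sample_id), , drop = FALSE]
  cc <- stats::complete.cases(ph[[trait]], ph[, covariates, drop = FALSE])
  idx <- which(cc)
  y <- ph[[trait]][idx]
  X <- cbind(`(Intercept)` = 1, as.matrix(ph[idx, covariates, drop = FALSE]))
  An <- subset_rm(grm_nuc, idx)
  Am <- subset_rm(grm_mt, idx)
  full <- fit_em_reml(mixed_model_spec(y, X, list(An, Am)),
                      tol = tol, max_iter = max_iter)
  reduced <- fit_em_reml(mixed_model_spec(y, X, list(An)),
                         tol = tol, max_iter = max_iter)
  list(full = full, reduced = reduced, lrt = lrt_mito(full, reduced))
}

subset_rm <- function(A, idx) {
  new_relationship_matrix(unclass_rm(A)[idx, idx, drop = FALSE],
                          rownames(A)[idx], attr(A, "n_snps"), attr(A, "kind"))
}

#' Run the full two-stage mt-PheWAS pipeline
#'
#' read -> split genomes -> PCs -> GRMs -> per-trait full/reduced EM-REML ->
#' LRT table -> prioritization -> MAF filter -> single-mtSNP scan -> summary.
#' Per-trait model failures are caught, logged and skipped; the scan never
#' aborts for one bad variant.
#'
#' @param cfg A [run_config()].
#' @param genotypes Optional [genotype_matrix()] (else read from
#'   `cfg$plink_prefix`).
#' @param phenotypes Optional phenotype data frame (else read from
#'   `cfg$phenotype_file`).
#' @param quiet Suppress stage logging.
#' @return A `mtphewas_report` list: `lrt` (per-trait LRT/PVE table with
#'   prioritization flags), `fits` (per-trait model pairs), `scan`
#'   (association results), `summary` ([summarize_counts()] output with
#'   expected-by-chance), `pcs`, `config`, `config_hash`, `n_mt_tested`,
#'   `expected_by_chance`. If `cfg$out_dir` is set, writes `lrt.tsv`,
#'   `assoc_<trait>.tsv`, `summary.tsv` and a `run_info.yaml` there.
#' @export
run_pipeline <- function(cfg, genotypes = NULL, phenotypes = NULL,
                         quiet = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  t_all <- proc.time()[3]

  if (is.null(genotypes)) {
    if (is.null(cfg$plink_prefix)) stop("no genotypes given", call. = FALSE)
    genotypes <- read_plink(cfg$plink_prefix)
  }
  if (is.null(phenotypes)) {
    if (is.null(cfg$phenotype_file)) stop("no phenotypes given", call. = FALSE)
    phenotypes <- utils::read.table(cfg$phenotype_file, header = TRUE,
                                    sep = "\t", stringsAsFactors = FALSE)
    phenotypes$sample_id <- as.character(phenotypes$sample_id)
  }
  missing_cols <- setdiff(c("sample_id", names(cfg$traits), cfg$covariates),
                          names(phenotypes))
  if (length(missing_cols)) {
    stop("phenotype table lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }

  parts <- split_genomes(genotypes)
  say("split: %d nuclear / %d mito variants, %d samples",
      ncol(parts$nuclear), ncol(parts$mito), nrow(genotypes))

  t0 <- proc.time()[3]
  A_nuc <- nuclear_grm(parts$nuclear)
  pcs <- compute_pcs(A_nuc, k = cfg$n_pcs)
  A_mt <- mito_grm(parts$mito)
  say("GRMs + %d PCs done (%.1f s)", cfg$n_pcs, proc.time()[3] - t0)

  pheno <- dplyr::left_join(phenotypes, pcs, by = "sample_id")
  covs <- c(cfg$covariates, paste0("PC", seq_len(cfg$n_pcs)))

  fits <- list()
  lrt_rows <- list()
  for (tr in names(cfg$traits)) {
    t0 <- proc.time()[3]
    res <- tryCatch(
      fit_mito_model(pheno, tr, A_nuc, A_mt, covariates = covs,
                     tol = cfg$reml_tol, max_iter = cfg$reml_max_iter),
      error = function(e) e)
    if (inherits(res, "error")) {
      warning("trait '", tr, "' skipped: ", conditionMessage(res), call. = FALSE)
      next
    }
    fits[[tr]] <- res
    pv <- res$full$pve
    lrt_rows[[tr]] <- tibble::tibble(
      trait = tr, n = res$full$n,
      pve_nuc = pv$pve[1], pve_nuc_se = pv$se[1],
      pve_mt = pv$pve[2], pve_mt_se = pv$se[2],
      logLik_full = res$full$logLik, logLik_reduced = res$reduced$logLik,
      lrt = res$lrt$statistic,
      p_mixture = res$lrt$p_mixture, p_chisq1 = res$lrt$p_chisq1,
      converged = res$full$converged && res$reduced$converged)
    say("REML %s: n=%d pve_mt=%.4f p=%.3g (%.1f s)", tr, res$full$n,
        pv$pve[2], res$lrt$p_mixture, proc.time()[3] - t0)
  }
  if (!length(lrt_rows)) stop("all traits failed", call. = FALSE)
  lrt_tbl <- prioritize_phenotypes(purrr::list_rbind(lrt_rows),
                                   alpha = cfg$alpha_priority,
                                   alpha_suggestive = cfg$alpha_suggestive)

  mt_filtered <- filter_maf(parts$mito, cfg$maf_threshold)
  say("MAF filter (>= %.3f): %d of %d mtSNPs retained",
      cfg$maf_threshold, ncol(mt_filtered), ncol(parts$mito))

  scan_traits <- cfg$traits[names(cfg$traits) %in% lrt_tbl$trait]
  if (cfg$prioritized_only) {
    keep <- lrt_tbl$trait[lrt_tbl$prioritized | lrt_tbl$suggestive]
    scan_traits <- scan_traits[names(scan_traits) %in% keep]
  }
  t0 <- proc.time()[3]
  scan <- run_mt_scan(mt_filtered, pheno, scan_traits, covariates = covs)
  say("scan: %d tests (%.1f s)", nrow(scan), proc.time()[3] - t0)

  summary_tbl <- summarize_counts(
    scan, alpha = cfg$alpha_snp,
    pve_per_trait = lrt_tbl[, c("trait", "pve_mt")])

  report <- structure(list(
    lrt = lrt_tbl, fits = fits, scan = scan, summary = summary_tbl,
    pcs = pcs, config = cfg,
    config_hash = rlang::hash(cfg),
    n_mt_tested = ncol(mt_filtered),
    expected_by_chance = expected_false_positives(ncol(mt_filtered), cfg$alpha_snp)
  ), class = "mtphewas_report")

  if (!is.null(cfg$out_dir)) write_report(report, cfg$out_dir)
  say("pipeline done (%.1f s)", proc.time()[3] - t_all)
  report
}

#' @export
print.mtphewas_report <- function(x, ...) {
  cat("<mtphewas_report>\n")
  print(render_summary(x))
  invisible(x)
}

#' Combined per-trait summary of both pipeline stages
#'
#' One row per trait: mitochondrial PVE with SE, the LRT p-value under both
#' null conventions, the significant-variant count against the
#' expected-by-chance count, and the prioritization flag.
#'
#' @param report A `mtphewas_report` from [run_pipeline()].
#' @return A tibble; Spearman correlation of PVE and counts in attribute
#'   `"spearman_pve_count"`.
#' @export
render_summary <- function(report) {
  stopifnot(inherits(report, "mtphewas_report"))
  out <- dplyr::left_join(
    report$lrt[, c("trait", "n", "pve_mt", "pve_mt_se",
                   "p_mixture", "p_chisq1", "prioritized", "suggestive")],
    report$summary[, c("trait", "n_tested", "n_significant",
                       "expected_by_chance", "exceeds_expected")],
    by = "trait")
  attr(out, "spearman_pve_count") <- attr(report$summary, "spearman_pve_count")
  out
}

write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(x, f) utils::write.table(
    x, file.path(dir, f), quote = FALSE, sep = "\t", row.names = FALSE)
  wt(report$lrt, "lrt.tsv")
  wt(as.data.frame(render_summary(report)), "summary.tsv")
  write_assoc_tsv(report$scan, dir)
  yaml::write_yaml(
    list(config_hash = report$config_hash, seed = report$config$seed,
         n_mt_tested = report$n_mt_tested,
         expected_by_chance = report$expected_by_chance),
    file.path(dir, "run_info.yaml"))
  invisible(dir)
}
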
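# Single-mtSNP association scans: per-variant linear (continuous traits) or
# logistic (binary traits) regression of the phenotype on the haploid 0/1
# allele call, adjusted for age, sex and the first two nuclear PCs. Haploid
# genotypes are coded single-dose (0/1), so betas are per-allele effects.

assoc_row <- function(snp_id, trait, n, effect, or, se, statistic, p_value,
                      testable = TRUE, note = NA_character_) {
  tibble::tibble(snp_id = snp_id, trait = trait, n = as.integer(n),
                 effect = effect, or = or, se = se, statistic = statistic,
                 p_value = p_value, testable = testable, note = note)
}

#' Linear association of one haploid variant with a continuous trait
#'
#' Ordinary least squares of `y ~ covariates + snp`; Wald t test on the snp
#' coefficient, two-sided. Complete cases only; a variant monomorphic within
#' the complete cases is returned flagged untestable rather than erroring.
#'
#' @param y Continuous phenotype vector.
#' @param X_cov Covariate matrix (intercept added here; do not include one).
#' @param snp 0/1 allele calls.
#' @param snp_id,trait Labels carried into the result.
#' @return One-row tibble (`snp_id`, `trait`, `n`, `effect` = beta, `or` = NA,
#'   `se`, `statistic`, `p_value`, `testable`, `note`).
#' @export
linear_assoc <- function(y, X_cov, snp, snp_id = "snp", trait = "trait") {
  X_cov <- as.matrix(X_cov)
  cc <- stats::complete.cases(y, X_cov, snp)
  y <- y[cc]; snp <- snp[cc]
  X <- cbind(`(Intercept)` = 1, X_cov[cc, , drop = FALSE], snp = snp)
  n <- length(y)
  if (n == 0 || length(unique(snp)) < 2) {
    return(assoc_row(snp_id, trait, n, NA_real_, NA_real_, NA_real_, NA_real_,
                     NA_real_, testable = FALSE, note = "monomorphic"))
  }
  if (qr(X)$rank < ncol(X)) stop("rank-deficient design for ", snp_id, call. = FALSE)
  fit <- stats::lm.fit(X, y)
  p <- ncol(X)
  rss <- sum(fit$residuals^2)
  sigma2 <- rss / (n - p)
  XtXinv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(sigma2 * XtXinv[p, p])
  beta <- unname(fit$coefficients["snp"])
  tval <- beta / se
  pval <- 2 * stats::pt(abs(tval), df = n - p, lower.tail = FALSE)
  assoc_row(snp_id, trait, n, beta, NA_real_, se, tval, pval)
}

#' Logistic association of one haploid variant with a binary trait
#'
#' Maximum-likelihood logistic regression of case status on covariates plus
#' the variant; the effect is reported as an odds ratio with the Wald z test
#' on the log-odds coefficient. Complete or quasi-complete separation is
#' detected (non-convergence or fitted probabilities collapsing to 0/1) and
#' flagged instead of reporting a spurious estimate.
#'
#' @param y01 0/1 case status.
#' @inheritParams linear_assoc
#' @return One-row tibble as in [linear_assoc()], with `effect` = log-OR and
#'   `or` = odds ratio.
#' @export
logistic_assoc <- function(y01, X_cov, snp, snp_id = "snp", trait = "trait") {
  X_cov <- as.matrix(X_cov)
  cc <- stats::complete.cases(y01, X_cov, snp)
  y <- y01[cc]; snp <- snp[cc]
  Xc <- X_cov[cc, , drop = FALSE]
  n <- length(y)
  if (n == 0 || length(unique(snp)) < 2) {
    return(assoc_row(snp_id, trait, n, NA_real_, NA_real_, NA_real_, NA_real_,
                     NA_real_, testable = FALSE, note = "monomorphic"))
  }
  if (length(unique(y)) < 2) stop("outcome has a single class", call. = FALSE)
  dat <- data.frame(.y = y, Xc, snp = snp, check.names = FALSE)
  fit <- suppressWarnings(
    stats::glm(.y ~ ., data = dat, family = stats::binomial()))
  mu <- fit$fitted.values
  separated <- !fit$converged || any(mu < 1e-8) || any(mu > 1 - 1e-8)
  if (separated) {
    return(assoc_row(snp_id, trait, n, NA_real_, NA_real_, NA_real_, NA_real_,
                     NA_real_, testable = FALSE, note = "separation"))
  }
  sm <- summary(fit)$coefficients
  beta <- sm["snp", "Estimate"]
  se <- sm["snp", "Std. Error"]
  z <- beta / se
  pval <- 2 * stats::pnorm(abs(z), lower.tail = FALSE)
  assoc_row(snp_id, trait, n, beta, exp(beta), se, z, pval)
}

#' Run the single-mtSNP association scan
#'
#' One covariate-adjusted regression per (trait, variant) pair: linear for
#' continuous traits, logistic for binary ones, each on that trait's complete
#' cases. Individual untestable variants (monomorphic after case completion,
#' separated logistic fits) are flagged in the output; the scan never aborts
#' for one bad variant.
#'
#' @param g_mt Haploid [genotype_matrix()], already MAF-filtered (the
#'   mt-PheWAS convention drops variants with MAF below 1%).
#' @param phenotypes Data frame with `sample_id`, the trait columns and the
#'   covariate columns; rows are matched to `g_mt` by `sample_id`.
#' @param traits Named character vector or list mapping trait column ->
#'   `"continuous"` or `"binary"`.
#' @param covariates Covariate column names (default age, sex, PC1, PC2).
#' @return A tibble of class `mt_scan`, one row per (trait, variant).
#' @export
run_mt_scan <- function(g_mt, phenotypes,
                        traits,
                        covariates = c("age", "sex", "PC1", "PC2")) {
  stopifnot(inherits(g_mt, "genotype_matrix"), "sample_id" %in% names(phenotypes))
  traits <- unlist(traits)
  if (length(traits) == 0) {
    out <- assoc_row(character(0), character(0), integer(0), numeric(0),
                     numeric(0), numeric(0), numeric(0), numeric(0))[0, ]
    class(out) <- c("mt_scan", class(out))
    return(out)
  }
  stopifnot(all(traits %in% c("continuous", "binary")),
            all(names(traits) %in% names(phenotypes)),
            all(covariates %in% names(phenotypes)))
  ph <- phenotypes[match(sample_ids(g_mt), phenotypes$sample_id), , drop = FALSE]
  calls <- calls_matrix(g_mt)
  sn <- snp_info(g_mt)
  Xcov <- as.matrix(ph[, covariates, drop = FALSE])

  res <- purrr::map(names(traits), function(tr) {
    y <- ph[[tr]]
    purrr::map(seq_len(ncol(calls)), function(j) {
      snp <- calls[, j]
      if (traits[[tr]] == "continuous") {
        linear_assoc(y, Xcov, snp, snp_id = sn$snp_id[j], trait = tr)
      } else {
        logistic_assoc(y, Xcov, snp, snp_id = sn$snp_id[j], trait = tr)
      }
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()
  out <- dplyr::left_join(res,
                          dplyr::select(sn, "snp_id", "chrom", "pos", "a1"),
                          by = "snp_id") |>
    dplyr::relocate("chrom", "pos", "a1", .after = "snp_id")
  class(out) <- c("mt_scan", class(out))
  out
}

#' Expected number of chance associations
#'
#' Under a global null, testing `m` variants at significance level `alpha`
#' yields `m * alpha` associations by chance alone -- e.g. 86 mtSNPs at
#' alpha = 0.05 give 4.3.
#'
#' @param m Number of tests.
#' @param alpha Significance threshold.
#' @return `m * alpha`.
#' @export
expected_false_positives <- function(m, alpha = 0.05) {
  stopifnot(m >= 0, alpha >= 0, alpha <= 1)
  m * alpha
}

#' Per-trait significant-variant counts and PVE correlation
#'
#' Counts, per trait, the testable variants with `p < alpha`, compares each
#' count to the number expected by chance (`m * alpha` with m the per-trait
#' testable-variant count), and -- when per-trait mitochondrial PVE estimates
#' are supplied -- reports their Spearman rank correlation with the counts,
#' the consistency check between the polygenic prioritization stage and the
#' single-variant scan.
#'
#' @param results An `mt_scan` tibble from [run_mt_scan()].
#' @param alpha Significance threshold (default 0.05, uncorrected: this
#'   framework deliberately applies no multiple-testing correction).
#' @param pve_per_trait Optional data frame with columns `trait` and `pve_mt`.
#' @return A tibble of class `phewas_summary`: `trait`, `n_tested`,
#'   `n_significant`, `expected_by_chance`, `exceeds_expected` and (if
#'   supplied) `pve_mt`; Spearman correlation in attribute
#'   `"spearman_pve_count"`.
#' @export
summarize_counts <- function(results, alpha = 0.05, pve_per_trait = NULL) {
  stopifnot(alpha > 0, alpha < 1)
  out <- results |>
    dplyr::filter(.data$testable) |>
    dplyr::group_by(.data$trait) |>
    dplyr::summarise(
      n_tested = dplyr::n(),
      n_significant = sum(.data$p_value < alpha, na.rm = TRUE),
      .groups = "drop") |>
    dplyr::mutate(
      expected_by_chance = expected_false_positives(.data$n_tested, alpha),
      exceeds_expected = .data$n_significant > .data$expected_by_chance)
  rho <- NA_real_
  if (!is.null(pve_per_trait)) {
    stopifnot(all(c("trait", "pve_mt") %in% names(pve_per_trait)))
    out <- dplyr::left_join(out, pve_per_trait[, c("trait", "pve_mt")],
                            by = "trait")
    if (nrow(out) >= 3 && sum(stats::complete.cases(out$pve_mt, out$n_significant)) >= 3) {
      rho <- stats::cor(out$pve_mt, out$n_significant, method = "spearman",
                        use = "complete.obs")
    }
  }
  attr(out, "spearman_pve_count") <- rho
  attr(out, "alpha") <- alpha
  class(out) <- c("phewas_summary", class(out))
  out
}

#' Write association results as PLINK-style TSV
#'
#' One file per trait with columns CHR, SNP, BP, A1, TEST, NMISS, BETA or OR,
#' SE, STAT, P (the `.assoc` column ordering).
#'
#' @param results An `mt_scan` tibble.
#' @param dir Output directory.
#' @return Paths written, invisibly.
#' @export
write_assoc_tsv <- function(results, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (tr in unique(results$trait)) {
    r <- results[results$trait == tr, ]
    binary <- any(!is.na(r$or))
    tb <- data.frame(
      CHR = r$chrom, SNP = r$snp_id, BP = r$pos, A1 = r$a1, TEST = "ADD",
      NMISS = r$n, EFFECT = if (binary) r$or else r$effect,
      SE = r$se, STAT = r$statistic, P = r$p_value)
    names(tb)[7] <- if (binary) "OR" else "BETA"
    path <- file.path(dir, paste0("assoc_", tr, ".tsv"))
    utils::write.table(tb, path, quote = FALSE, sep = "\t", row.names = FALSE)
    paths <- c(paths, path)
  }
  invisible(paths)
}
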
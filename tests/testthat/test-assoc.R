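# Single-mtSNP association scans: closed forms, independent regression
# oracles, calibration, degenerate variants, summary counting.

test_that("noiseless linear association recovers the planted effect exactly", {
  set.seed(41)
  n <- 80
  snp <- rbinom(n, 1, 0.4)
  age <- rnorm(n, 50, 10)
  y <- 3 + 0.5 * age + 2 * snp          # exact linear signal, no noise
  r <- linear_assoc(y, cbind(age = age), snp, snp_id = "s1", trait = "t")
  expect_equal(r$effect, 2, tolerance = 1e-10)
  expect_lt(r$p_value, 1e-12)
  expect_equal(r$n, n)
  expect_true(is.na(r$or))
})

test_that("linear association matches a normal-equations OLS oracle", {
  set.seed(43)
  n <- 120
  X_cov <- cbind(age = rnorm(n, 46, 17), sex = rbinom(n, 1, 0.65))
  snp <- rbinom(n, 1, 0.3)
  y <- rnorm(n) + 0.4 * snp
  r <- linear_assoc(y, X_cov, snp)
  # oracle: explicit (X'X)^{-1} X'y with solve(), not lm
  X <- cbind(1, X_cov, snp)
  bh <- unname(solve(t(X) %*% X, t(X) %*% y))
  res <- y - X %*% bh
  s2 <- sum(res^2) / (n - 4)
  covb <- s2 * solve(t(X) %*% X)
  expect_equal(r$effect, bh[4, 1], tolerance = 1e-10)
  expect_equal(r$se, sqrt(covb[4, 4]), tolerance = 1e-10)
  expect_equal(r$statistic, bh[4, 1] / sqrt(covb[4, 4]), tolerance = 1e-10)
  expect_equal(r$p_value, 2 * pt(abs(r$statistic), n - 4, lower.tail = FALSE))
  # missing phenotype values shrink n and are dropped consistently
  y2 <- y; y2[1:10] <- NA
  r2 <- linear_assoc(y2, X_cov, snp)
  expect_equal(r2$n, n - 10L)
})

test_that("null linear p-values are uniform (Kolmogorov-Smirnov)", {
  set.seed(47)
  n <- 1000
  age <- rnorm(n, 46, 17)
  pvals <- replicate(200, {
    snp <- rbinom(n, 1, runif(1, 0.1, 0.5))
    y <- rnorm(n) + 0.02 * age
    linear_assoc(y, cbind(age = age), snp)$p_value
  })
  ks <- suppressWarnings(ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.001)
  # empirical size near alpha
  expect_lt(abs(mean(pvals < 0.05) - 0.05), 0.05)
})

test_that("covariate-free logistic association equals the 2x2 closed form", {
  # cells: carriers 30 cases / 20 controls, non-carriers 15 / 35 -> OR = 3.5
  y <- rep(c(1, 0, 1, 0), c(30, 20, 15, 35))
  snp <- rep(c(1, 1, 0, 0), c(30, 20, 15, 35))
  r <- logistic_assoc(y, matrix(numeric(0), 100, 0), snp)
  expect_equal(r$or, (30 * 35) / (20 * 15), tolerance = 1e-6)
  expect_equal(r$se, sqrt(1/30 + 1/20 + 1/15 + 1/35), tolerance = 1e-6)
  expect_equal(r$p_value, 2 * pnorm(abs(log(3.5) / r$se), lower.tail = FALSE),
               tolerance = 1e-6)
  # perfectly balanced table -> OR 1, p 1
  yb <- rep(c(1, 0, 1, 0), each = 25)
  sb <- rep(c(1, 1, 0, 0), each = 25)
  rb <- logistic_assoc(yb, matrix(numeric(0), 100, 0), sb)
  expect_equal(rb$or, 1, tolerance = 1e-8)
  expect_equal(rb$p_value, 1, tolerance = 1e-6)
})

test_that("covariate-adjusted logistic matches a hand-rolled IRLS oracle", {
  set.seed(53)
  n <- 200
  X_cov <- cbind(age = rnorm(n), sex = rbinom(n, 1, 0.5))
  snp <- rbinom(n, 1, 0.4)
  eta <- -0.3 + 0.2 * X_cov[, 1] + 0.5 * snp
  y <- rbinom(n, 1, plogis(eta))
  r <- logistic_assoc(y, X_cov, snp)
  # independent IRLS, written out by hand
  X <- cbind(1, X_cov, snp)
  b <- rep(0, 4)
  for (it in 1:50) {
    mu <- plogis(drop(X %*% b))
    W <- mu * (1 - mu)
    b_new <- b + solve(t(X) %*% (W * X), t(X) %*% (y - mu))
    if (max(abs(b_new - b)) < 1e-12) { b <- b_new; break }
    b <- b_new
  }
  mu <- plogis(drop(X %*% b))
  covb <- solve(t(X) %*% ((mu * (1 - mu)) * X))
  expect_equal(r$effect, b[4], tolerance = 1e-6)
  expect_equal(r$or, exp(b[4]), tolerance = 1e-6)
  expect_equal(r$se, sqrt(covb[4, 4]), tolerance = 1e-6)
})

test_that("monomorphic variants and separation are flagged, not fitted", {
  y <- rnorm(30)
  r <- linear_assoc(y, matrix(rnorm(30)), rep(1L, 30))
  expect_false(r$testable)
  expect_equal(r$note, "monomorphic")
  expect_true(is.na(r$p_value))
  # perfect separation: carrier status determines case status
  snp <- rep(c(1L, 0L), each = 25)
  ysep <- snp
  rs <- logistic_assoc(ysep, matrix(numeric(0), 50, 0), snp)
  expect_false(rs$testable)
  expect_equal(rs$note, "separation")
})

test_that("the scan covers every (trait, variant) pair and is order-invariant", {
  co <- cohort_300()
  g_mt <- filter_maf(split_genomes(co$g)$mito, 0.01)
  pcs <- compute_pcs(split_genomes(co$g)$nuclear, k = 2)
  ph <- dplyr::left_join(co$ph, pcs, by = "sample_id")
  traits <- c(lipid = "continuous", status = "binary")
  scan <- run_mt_scan(g_mt, ph, traits)
  expect_s3_class(scan, "mt_scan")
  expect_equal(nrow(scan), 2 * ncol(g_mt))
  expect_setequal(unique(scan$trait), names(traits))
  expect_true(all(c("snp_id", "chrom", "pos", "a1", "effect", "or", "p_value",
                    "testable") %in% names(scan)))
  expect_true(all(scan$p_value[scan$testable] >= 0 &
                  scan$p_value[scan$testable] <= 1))
  # binary rows carry odds ratios, continuous rows don't
  expect_true(all(is.na(scan$or[scan$trait == "lipid"])))
  expect_true(all(!is.na(scan$or[scan$trait == "status" & scan$testable])))
  # shuffling phenotype rows changes nothing (matching is by sample_id)
  scan2 <- run_mt_scan(g_mt, ph[sample(nrow(ph)), ], traits)
  expect_equal(as.data.frame(scan2), as.data.frame(scan))
  # empty trait map -> empty, well-formed result
  scan0 <- run_mt_scan(g_mt, ph, character(0))
  expect_equal(nrow(scan0), 0L)
  expect_s3_class(scan0, "mt_scan")
})

test_that("expected chance counts follow m * alpha", {
  expect_equal(expected_false_positives(86, 0.05), 4.3)
  expect_equal(expected_false_positives(0, 0.05), 0)
  expect_equal(expected_false_positives(100, 0.01), 1)
  expect_error(expected_false_positives(10, 1.5))
})

test_that("summary counts significant variants per trait and joins PVE", {
  mk <- function(trait, p, testable = TRUE) {
    tibble::tibble(snp_id = paste0("s", seq_along(p)), trait = trait,
                   p_value = p, testable = testable)
  }
  res <- dplyr::bind_rows(
    mk("a", c(rep(0.01, 13), runif(73, 0.3, 1))),   # 13 of 86 significant
    mk("b", runif(86, 0.3, 1)),                     # none
    mk("c", c(0.04, rep(0.9, 84), NA), c(rep(TRUE, 85), FALSE)))
  sm <- summarize_counts(res, alpha = 0.05,
                         pve_per_trait = tibble::tibble(
                           trait = c("a", "b", "c"), pve_mt = c(0.3, 0.0, 0.1)))
  expect_equal(sm$n_tested, c(86L, 86L, 85L))
  expect_equal(sm$n_significant, c(13L, 0L, 1L))
  expect_equal(sm$expected_by_chance, c(4.3, 4.3, 4.25))
  expect_equal(sm$exceeds_expected, c(TRUE, FALSE, FALSE))
  # counts ranked exactly like PVE here -> Spearman rho = 1
  expect_equal(attr(sm, "spearman_pve_count"), 1)
})

test_that("association TSV export writes one PLINK-style file per trait", {
  co <- cohort_300()
  g_mt <- filter_maf(split_genomes(co$g)$mito, 0.01)
  pcs <- compute_pcs(split_genomes(co$g)$nuclear, k = 2)
  ph <- dplyr::left_join(co$ph, pcs, by = "sample_id")
  scan <- run_mt_scan(g_mt, ph, c(lipid = "continuous", status = "binary"))
  dir <- file.path(tempdir(), "assoc_out")
  write_assoc_tsv(scan, dir)
  lin <- read.delim(file.path(dir, "assoc_lipid.tsv"))
  log <- read.delim(file.path(dir, "assoc_status.tsv"))
  expect_equal(names(lin), c("CHR", "SNP", "BP", "A1", "TEST", "NMISS",
                             "BETA", "SE", "STAT", "P"))
  expect_equal(names(log)[7], "OR")
  expect_equal(nrow(lin), ncol(g_mt))
  expect_equal(lin$P, scan$p_value[scan$trait == "lipid"], tolerance = 1e-12)
})
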
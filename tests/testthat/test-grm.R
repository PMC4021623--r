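# Relationship matrices: closed forms, brute-force oracles, invariances,
# principal components, GCTA file dialect.

brute_nuclear <- function(calls) {
  # direct double loop over the definition, mean-imputing missing dosages
  n <- nrow(calls); m <- ncol(calls)
  p <- colMeans(calls, na.rm = TRUE) / 2
  A <- matrix(0, n, n)
  for (j in seq_len(n)) for (k in seq_len(n)) {
    s <- 0
    for (i in seq_len(m)) {
      xj <- calls[j, i]; xk <- calls[k, i]
      if (is.na(xj)) xj <- 2 * p[i]
      if (is.na(xk)) xk <- 2 * p[i]
      s <- s + (xj - 2 * p[i]) * (xk - 2 * p[i]) / (2 * p[i] * (1 - p[i]))
    }
    A[j, k] <- s / m
  }
  A
}

brute_sharing <- function(calls) {
  n <- nrow(calls)
  S <- matrix(NA_real_, n, n)
  for (j in seq_len(n)) for (k in seq_len(n)) {
    both <- !is.na(calls[j, ]) & !is.na(calls[k, ])
    S[j, k] <- mean(calls[j, both] == calls[k, both])
  }
  S
}

test_that("nuclear GRM closed forms: single SNP and duplicated samples", {
  g <- gm(matrix(c(0L, 2L), 2, 1))
  A <- nuclear_grm(g)
  expect_equal(unclass(A)[, ], matrix(c(2, -2, -2, 2), 2), ignore_attr = TRUE)

  set.seed(2)
  calls <- matrix(rbinom(5 * 20, 2, 0.4), 5, 20)
  calls[5, ] <- calls[1, ]  # duplicate sample
  A2 <- suppressWarnings(nuclear_grm(gm(calls)))  # drop incidental monomorphics
  expect_equal(A2[1, 5], A2[1, 1])
})

test_that("both GRM kinds match brute-force double loops, with missingness", {
  set.seed(13)
  calls <- matrix(rbinom(8 * 30, 2, runif(30, 0.1, 0.9)), 8, 30, byrow = TRUE)
  calls[sample(length(calls), 20)] <- NA
  poly <- apply(calls, 2, function(x) {
    p <- mean(x, na.rm = TRUE) / 2; p > 0 && p < 1
  })
  A <- nuclear_grm(gm(calls[, poly]))
  expect_lt(max(abs(unclass(A)[, ] - brute_nuclear(calls[, poly]))), 1e-10)

  hap <- matrix(rbinom(6 * 10, 1, 0.5), 6, 10)
  hap[sample(length(hap), 6)] <- NA
  S <- mito_grm(gm(hap, chrom = rep("MT", 10)))
  expect_lt(max(abs(unclass(S)[, ] - brute_sharing(hap))), 1e-10)
})

test_that("mito sharing hits its extremes for identical and complementary haplotypes", {
  hap <- rbind(a = rep(c(0L, 1L), 43), b = rep(c(0L, 1L), 43),
               c = rep(c(1L, 0L), 43))
  S <- mito_grm(gm(hap, chrom = rep("MT", 86)))
  expect_equal(S["a", "b"], 1)
  expect_equal(S["a", "c"], 0)
  expect_true(all(S >= 0 & S <= 1))
  expect_equal(unname(diag(S)), rep(1, 3))
})

test_that("GRMs are invariant under A1/A2 allele relabeling", {
  co <- cohort_300()
  parts <- split_genomes(co$g)
  flip_some <- function(g, ploidy) {
    calls <- unclass(g)[, ]
    sn <- snp_info(g)
    set.seed(4)
    fl <- sample(ncol(calls), ncol(calls) %/% 2)
    calls[, fl] <- ploidy - calls[, fl]
    a1 <- sn$a1; a2 <- sn$a2
    a1[fl] <- sn$a2[fl]; a2[fl] <- sn$a1[fl]
    genotype_matrix(calls, sn$chrom, sn$pos, a1, a2, sn$snp_id, rownames(calls))
  }
  An <- nuclear_grm(parts$nuclear)
  An_fl <- nuclear_grm(flip_some(parts$nuclear, 2L))
  expect_equal(unclass(An)[, ], unclass(An_fl)[, ], tolerance = 1e-12)
  Am <- mito_grm(parts$mito)
  Am_fl <- mito_grm(flip_some(parts$mito, 1L))
  expect_equal(unclass(Am)[, ], unclass(Am_fl)[, ], tolerance = 1e-12)
})

test_that("GRMs are PSD and scaled as expected on clean simulated data", {
  co <- cohort_300()
  parts <- split_genomes(co$g)
  An <- nuclear_grm(parts$nuclear)
  Am <- mito_grm(parts$mito)
  for (A in list(An, Am)) {
    ev <- eigen(unclass(A)[, ], symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-8 * max(ev))
  }
  # mean diagonal of the additive GRM ~ 1 + F ~ 1 for unrelated samples
  expect_equal(mean(diag(An)), 1, tolerance = 0.05)
  expect_true(all(Am >= 0 & Am <= 1 + 1e-12))
})

test_that("PCs separate two diverged subpopulations and match a dense eigen oracle", {
  set.seed(31)
  n1 <- 25; n2 <- 25; m <- 200
  p1 <- runif(m, 0.1, 0.9)
  # strong, systematic divergence
  p2 <- pmin(pmax(p1 + sample(c(-1, 1), m, TRUE) * 0.4, 0.02), 0.98)
  calls <- rbind(
    matrix(rbinom(n1 * m, 2, rep(p1, each = n1)), n1, m),
    matrix(rbinom(n2 * m, 2, rep(p2, each = n2)), n2, m))
  g <- gm(calls)
  pcs <- compute_pcs(g, k = 2)
  lab <- rep(c(1, 2), c(n1, n2))
  expect_true(max(pcs$PC1[lab == 1]) < min(pcs$PC1[lab == 2]) ||
              min(pcs$PC1[lab == 1]) > max(pcs$PC1[lab == 2]))

  # dense oracle: standardize columns explicitly, eigendecompose the n x n
  # covariance of standardized genotypes
  p <- colMeans(calls) / 2
  keep <- p > 0 & p < 1
  Z <- sweep(calls[, keep], 2, 2 * p[keep]) /
    rep(sqrt(2 * p[keep] * (1 - p[keep])), each = n1 + n2)
  e <- eigen(tcrossprod(Z) / ncol(Z), symmetric = TRUE)
  for (j in 1:2) {
    v <- e$vectors[, j]
    v <- v * sign(v[which.max(abs(v))])
    expect_equal(pcs[[paste0("PC", j)]], v, tolerance = 1e-8)
  }
  expect_equal(attr(pcs, "eigenvalues"), e$values[1:2], tolerance = 1e-8)
})

test_that("PC on a rank-1 standardized matrix recovers the generating vector", {
  # two genotype groups -> standardized matrix has rank 1
  calls <- matrix(rep(c(0L, 2L), c(6, 6)), 12, 30)
  pcs <- compute_pcs(gm(calls), k = 1)
  v <- pcs$PC1 / max(abs(pcs$PC1))
  expect_equal(abs(v), rep(1, 12) / 1, tolerance = 1e-10)
  expect_true(all(v[1:6] * v[7:12][1] < 0))
  expect_error(compute_pcs(gm(calls), k = 12), "smaller")
})

test_that("GCTA binary GRM dialect round-trips and text export writes a square matrix", {
  co <- cohort_300()
  Am <- mito_grm(split_genomes(co$g)$mito)
  pre <- file.path(tempdir(), "grmrt")
  write_grm_gcta(Am, pre)
  back <- read_grm_gcta(pre, kind = "mito-sharing")
  # 4-byte floats: agreement to single precision
  expect_equal(unclass(back)[, ], unclass(Am)[, ], tolerance = 1e-6)
  expect_identical(rownames(back), rownames(Am))
  expect_equal(attr(back, "n_snps"), attr(Am, "n_snps"))

  write_grm_text(Am, pre)
  txt <- as.matrix(read.table(paste0(pre, ".grm.tsv"), header = TRUE,
                              row.names = 1, check.names = FALSE))
  expect_equal(unname(txt), unname(unclass(Am)[, ]), tolerance = 1e-12)
})
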
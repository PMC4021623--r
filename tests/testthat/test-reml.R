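# Restricted likelihood evaluation, EM-REML fitting, boundary LRT,
# phenotype prioritization.

# slow, transparent restricted log-likelihood via dense factorization only
dense_logl <- function(y, X, grms, sigma2) {
  n <- length(y); p <- ncol(X)
  V <- diag(sigma2[length(sigma2)], n)
  for (i in seq_along(grms)) V <- V + sigma2[i] * unclass(grms[[i]])[, ]
  Vinv <- solve(V)
  C <- t(X) %*% Vinv %*% X
  P <- Vinv - Vinv %*% X %*% solve(C) %*% t(X) %*% Vinv
  -0.5 * ((n - p) * log(2 * pi) + determinant(V)$modulus[1] +
            determinant(C)$modulus[1] + drop(t(y) %*% P %*% y))
}

test_that("GRM-free REML equals the least-squares closed form", {
  set.seed(17)
  n <- 60
  X <- cbind(1, rnorm(n), rbinom(n, 1, 0.5))
  y <- drop(X %*% c(2, 1, -0.5)) + rnorm(n, sd = 1.3)
  spec <- mixed_model_spec(y, X, list())
  fit <- fit_em_reml(spec)
  rss <- sum(lm(y ~ X - 1)$residuals^2)
  s2hat <- rss / (n - 3)
  expect_equal(unname(fit$sigma2["e"]), s2hat, tolerance = 1e-12)
  # closed-form restricted likelihood at the maximizer
  logl_closed <- -0.5 * ((n - 3) * log(2 * pi) + (n - 3) * log(s2hat) +
                           determinant(crossprod(X))$modulus[1] + (n - 3))
  expect_equal(fit$logLik, unname(logl_closed), tolerance = 1e-10)
  # doubling sigma2 changes logL by the closed-form amount
  d <- restricted_loglik(spec, 2 * s2hat) - restricted_loglik(spec, s2hat)
  expect_equal(d, -0.5 * ((n - 3) * log(2) + rss / (2 * s2hat) - rss / s2hat),
               tolerance = 1e-10)
})

test_that("rotated/low-rank likelihood matches dense factorization at n = 40", {
  set.seed(23)
  cfg <- simulation_config(n_samples = 40, m_nuc = 60, m_mt = 12, seed = 5)
  g <- simulate_genotypes(cfg)
  parts <- split_genomes(g)
  An <- nuclear_grm(parts$nuclear)
  Am <- mito_grm(parts$mito)
  X <- cbind(1, rnorm(40))
  y <- rnorm(40)
  spec <- mixed_model_spec(y, X, list(An, Am))
  for (s2 in list(c(0.5, 0.3, 0.7), c(1, 1, 1), c(0.01, 2, 0.2))) {
    expect_equal(restricted_loglik(spec, s2), dense_logl(y, X, list(An, Am), s2),
                 tolerance = 1e-8)
  }
  # forcing the dense path gives the same surface
  spec_d <- mixed_model_spec(y, X, list(An, Am),
                             kernel = reml_kernel(list(An, Am), dense_cutoff = 0))
  expect_equal(restricted_loglik(spec_d, c(0.5, 0.3, 0.7)),
               restricted_loglik(spec, c(0.5, 0.3, 0.7)), tolerance = 1e-8)
})

test_that("EM iteration is monotone and accelerated/plain agree at the optimum", {
  co <- cohort_300()
  parts <- split_genomes(co$g)
  An <- nuclear_grm(parts$nuclear); Am <- mito_grm(parts$mito)
  X <- cbind(1, co$ph$age, co$ph$sex)
  spec <- mixed_model_spec(co$ph$lipid, X, list(An, Am))
  fit <- fit_em_reml(spec)
  expect_true(all(diff(fit$logl_trace) > -1e-8))
  expect_true(fit$converged)
  plain <- fit_em_reml(spec, accelerate = FALSE, max_iter = 5000)
  expect_true(all(diff(plain$logl_trace) > -1e-8))
  expect_equal(fit$logLik, plain$logLik, tolerance = 1e-4)
  expect_equal(unname(fit$sigma2), unname(plain$sigma2), tolerance = 0.05)
})

test_that("nested models satisfy likelihood dominance and the LRT conventions", {
  co <- cohort_300()
  parts <- split_genomes(co$g)
  An <- nuclear_grm(parts$nuclear); Am <- mito_grm(parts$mito)
  X <- cbind(1, co$ph$age, co$ph$sex)
  full <- fit_em_reml(mixed_model_spec(co$ph$lipid, X, list(An, Am)))
  red <- fit_em_reml(mixed_model_spec(co$ph$lipid, X, list(An)))
  expect_gte(full$logLik, red$logLik - 1e-6)
  lrt <- lrt_mito(full, red)
  expect_gte(lrt$statistic, 0)
  expect_equal(lrt$p_chisq1, pchisq(lrt$statistic, 1, lower.tail = FALSE))
  expect_equal(lrt$p_mixture, lrt$p_chisq1 / 2)
  # mismatched sample sets rejected
  X2 <- X[-1, , drop = FALSE]
  red2 <- fit_em_reml(mixed_model_spec(co$ph$lipid[-1], X2,
                                       list(mtphewas:::subset_rm(An, 2:300))))
  expect_error(lrt_mito(full, red2), "sample set")
})

test_that("LRT p-value conventions match chi-square tail values", {
  f <- list(logLik = 0, n = 10, n_components = 2, sample_ids = NULL)
  r <- list(logLik = 0, n = 10, n_components = 1, sample_ids = NULL)
  class(f) <- class(r) <- "vc_fit"
  t0 <- lrt_mito(f, r)
  expect_equal(t0$statistic, 0)
  expect_equal(t0$p_mixture, 0.5)
  expect_equal(t0$p_chisq1, 1)
  f$logLik <- 2.706 / 2
  t1 <- lrt_mito(f, r)
  expect_equal(t1$p_chisq1, 0.100, tolerance = 1e-3)
  expect_equal(t1$p_mixture, 0.050, tolerance = 1e-3)
})

test_that("PVE uses contribution weights and recovers the generating shares", {
  co <- cohort_1000()
  ph <- simulate_phenotype(co$g, co$cfg, roots = co$roots)
  X <- cbind(1, ph$age, ph$sex)
  fit <- fit_em_reml(mixed_model_spec(ph$trait1, X, list(co$An, co$Am),
                                      kernel = co$k_full))
  expect_true(fit$converged)
  # targets (0.30, 0.05); a single replicate carries sampling noise of roughly
  # the reported SE, so require agreement within 3.5 delta-method SEs
  expect_lt(abs(fit$pve$pve[1] - 0.30), 3.5 * fit$pve$se[1])
  expect_lt(abs(fit$pve$pve[2] - 0.05), 3.5 * fit$pve$se[2])
  expect_true(all(fit$pve$pve >= 0), sum(fit$pve$pve) <= 1)
  td <- tidy(fit)
  expect_named(td, c("component", "variance", "se", "pve", "pve_se"))
  expect_equal(nrow(td), 3L)
  gl <- glance(fit)
  expect_true(gl$converged)
  expect_equal(gl$vp, sum(fit$weights * fit$sigma2))
})

test_that("a null mitochondrial component is driven to the floor", {
  co <- cohort_1000()
  cfg0 <- simulation_config(n_samples = 1000, m_nuc = 2000, m_mt = 100, seed = 77,
                            traits = tibble::tibble(
                              trait = "y", type = "continuous",
                              pve_nuc = 0.3, pve_mt = 0))
  ph <- simulate_phenotype(co$g, cfg0, roots = co$roots)
  X <- cbind(1, ph$age, ph$sex)
  fit <- fit_em_reml(mixed_model_spec(ph$y, X, list(co$An, co$Am),
                                      kernel = co$k_full))
  expect_lt(fit$pve$pve[2], 0.01)
})

test_that("phenotype prioritization sorts, flags and is label-invariant", {
  tb <- tibble::tibble(trait = c("A", "B", "C"),
                       p_mixture = c(0.046, 0.055, 0.30))
  pr <- prioritize_phenotypes(tb)
  expect_equal(pr$trait, c("A", "B", "C"))
  expect_equal(pr$prioritized, c(TRUE, FALSE, FALSE))
  expect_equal(pr$suggestive, c(FALSE, TRUE, FALSE))
  # all p = 1 -> nothing flagged
  pr1 <- prioritize_phenotypes(tibble::tibble(trait = c("x", "y"),
                                              p_mixture = c(1, 1)))
  expect_false(any(pr1$prioritized))
  # relabeling traits permutes rows but not the p-value ordering
  tb2 <- tb[c(3, 1, 2), ]
  tb2$trait <- c("zz", "aa", "mm")
  pr2 <- prioritize_phenotypes(tb2)
  expect_equal(pr2$p_mixture, sort(tb$p_mixture))
})
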
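#' Specify a variance-component mixed model
#'
#' Bundles phenotype, fixed-effect design and relationship matrices, checked
#' for alignment. The model is `y = X b + sum_i g_i + e` with
#' `g_i ~ N(0, s2_i A_i)` and `e ~ N(0, s2_e I)`. In the mt-PheWAS setting the
#' full model uses `grms = list(A_nuc, A_mt)` and the reduced model
#' `list(A_nuc)`; fixed effects are intercept, age, sex, PC1 and PC2.
#'
#' Binary traits are analyzed on the observed 0/1 scale with the same linear
#' mixed model (no liability transformation).
#'
#' @param y Numeric phenotype vector (no missing values; subset to complete
#'   cases first).
#' @param X Fixed-effects design matrix including the intercept column; must
#'   have full column rank.
#' @param grms List of `relationship_matrix` objects (may be empty), rows
#'   aligned with `y`.
#' @param kernel Optional precomputed [reml_kernel()] for `grms`; supply one
#'   when fitting many phenotypes against the same matrices.
#' @return A `mixed_model_spec` object.
#' @export
mixed_model_spec <- function(y, X, grms = list(), kernel = NULL) {
  y <- as.numeric(y)
  X <- as.matrix(X)
  n <- length(y)
  stopifnot(nrow(X) == n, !anyNA(y), !anyNA(X))
  if (qr(X)$rank < ncol(X)) stop("X is rank deficient", call. = FALSE)
  ids <- NULL
  for (A in grms) {
    stopifnot(nrow(A) == n, ncol(A) == n)
    if (is.null(ids) && !is.null(rownames(A))) ids <- rownames(A)
  }
  # contribution weight of each component to the sample variance of y:
  # c_i = (tr(A_i) - mean row sum) / (n - 1); equals 1 for A = I and ~1 for a
  # standardized GRM, but corrects for matrices (like raw allelic sharing)
  # whose entries have a large common mean
  w <- vapply(grms, function(A) {
    (sum(diag(A)) - sum(A) / n) / (n - 1)
  }, numeric(1))
  if (is.null(kernel)) kernel <- reml_kernel(grms)
  structure(list(y = y, X = X, grms = grms, kernel = kernel,
                 weights = c(w, 1), sample_ids = ids, n = n, p = ncol(X)),
            class = "mixed_model_spec")
}

#' Restricted log-likelihood at given variance components
#'
#' Evaluates `-(1/2) [ (n-p) log(2 pi) + log|V| + log|X'V^{-1}X| + y'Py ]`
#' with `V = sum_i s2_i A_i + s2_e I` and
#' `P = V^{-1} - V^{-1}X (X'V^{-1}X)^{-1} X'V^{-1}`. The `(n-p) log(2 pi)`
#' constant is included so the value matches the usual closed-form restricted
#' likelihood in the GRM-free case; any fixed constant cancels in likelihood
#' ratios.
#'
#' @param spec A [mixed_model_spec()].
#' @param sigma2 Variance components, one per GRM plus the residual last; all
#'   must keep `V` positive definite.
#' @return The restricted log-likelihood (scalar).
#' @export
restricted_loglik <- function(spec, sigma2) {
  stopifnot(inherits(spec, "mixed_model_spec"),
            length(sigma2) == length(spec$grms) + 1L)
  rot <- reml_rotate(spec$kernel, spec$y, spec$X)
  reml_eval(spec$kernel, rot$y, rot$X, sigma2, need_traces = FALSE)$logL
}

#' Fit variance components by EM-REML
#'
#' Maximizes the restricted likelihood over the variance components with the
#' expectation-maximization update
#' `s2_i <- [ s2_i^2 y'P A_i P y + tr(s2_i I - s2_i^2 A_i P) ] / n`
#' (residual included with `A_e = I`), starting from an equal split of the
#' phenotypic variance across components. EM keeps components non-negative
#' and never decreases the restricted likelihood; components are floored at
#' `1e-6 * var(y)` to guard underflow at the boundary.
#'
#' Because the plain fixed-point iteration approaches a boundary optimum
#' (a variance component that is truly zero) only at rate 1/iteration, the EM
#' map is by default iterated under SQUAREM squared extrapolation: two EM
#' steps, one extrapolated candidate, kept only when it does not decrease the
#' restricted likelihood (else the plain double step is used). The fixed
#' points -- and therefore the REML solution -- are identical to plain EM's,
#' and the recorded likelihood trace stays non-decreasing; `accelerate =
#' FALSE` gives the textbook iteration. Iteration stops when the likelihood
#' change between successive evaluations drops below `tol`, or after
#' `max_iter` EM-map evaluations (`converged = FALSE`, result still
#' returned).
#'
#' Standard errors come from the inverse average-information matrix at the
#' solution (EM itself provides none). PVE -- each genetic component's share
#' of the phenotypic variance -- uses contribution weights
#' `c_i = (tr(A_i) - mean row sum)/(n-1)` (1 for the residual), so PVE is
#' invariant to the scaling or common mean of a relationship matrix; for a
#' standardized GRM this reduces to the usual `s2_i / sum(s2)`. PVE standard
#' errors are delta-method.
#'
#' @param spec A [mixed_model_spec()].
#' @param tol Convergence tolerance on the restricted log-likelihood change.
#' @param max_iter Maximum number of EM-map evaluations.
#' @param init Optional starting variance components.
#' @param accelerate Use SQUAREM extrapolation (default) or the plain
#'   fixed-point iteration.
#' @return A `vc_fit` object: named `sigma2` and `se_sigma2`, a `pve` tibble
#'   (genetic components only), `logLik`, `n_iter` (EM-map evaluations),
#'   `converged`, the per-evaluation `logl_trace`, and bookkeeping fields.
#'   Methods: [tidy()], [glance()], `print()`.
#' @export
fit_em_reml <- function(spec, tol = 1e-6, max_iter = 500L, init = NULL,
                        accelerate = TRUE) {
  stopifnot(inherits(spec, "mixed_model_spec"))
  q <- length(spec$grms)
  n <- spec$n
  vy <- stats::var(spec$y)
  floor_val <- 1e-6 * vy

  if (q == 0) {
    # closed form: residual variance is RSS/(n-p)
    fit <- stats::lm.fit(spec$X, spec$y)
    s2e <- sum(fit$residuals^2) / (n - spec$p)
    logL <- restricted_loglik(spec, s2e)
    return(new_vc_fit(sigma2 = c(e = s2e), se = c(e = sqrt(2 * s2e^2 / (n - spec$p))),
                      pve = empty_pve(), logL = logL, n_iter = 0L, converged = TRUE,
                      trace = logL, spec = spec))
  }

  comp_names <- c(paste0("G", seq_len(q)), "e")
  theta <- if (is.null(init)) rep(vy / (q + 1), q + 1) else as.numeric(init)
  stopifnot(length(theta) == q + 1, all(theta > 0))

  rot <- reml_rotate(spec$kernel, spec$y, spec$X)
  em_step <- function(s2) {
    ev <- reml_eval(spec$kernel, rot$y, rot$X, s2)
    if (!is.finite(ev$logL)) stop("restricted log-likelihood is not finite", call. = FALSE)
    s2new <- s2 + s2^2 * (ev$quad - ev$trAP) / n
    if (anyNA(s2new)) stop("NaN in EM update", call. = FALSE)
    list(s2 = pmax(s2new, floor_val), logL = ev$logL, ev = ev)
  }

  trace <- numeric(0)
  logL_prev <- -Inf
  converged <- FALSE
  n_eval <- 0L
  sigma2 <- theta
  ev <- NULL
  while (n_eval < max_iter) {
    e0 <- em_step(theta)
    n_eval <- n_eval + 1L
    trace <- c(trace, e0$logL)
    sigma2 <- theta
    ev <- e0$ev
    if (abs(e0$logL - logL_prev) < tol) { converged <- TRUE; break }
    logL_prev <- e0$logL
    if (!accelerate) { theta <- e0$s2; next }

    theta1 <- e0$s2
    e1 <- em_step(theta1)
    n_eval <- n_eval + 1L
    trace <- c(trace, e1$logL)
    sigma2 <- theta1
    ev <- e1$ev
    if (abs(e1$logL - logL_prev) < tol) { converged <- TRUE; break }
    logL_prev <- e1$logL
    theta2 <- e1$s2

    r <- theta1 - theta
    v <- theta2 - 2 * theta1 + theta
    vnorm <- sqrt(sum(v^2))
    if (vnorm < 1e-14) { theta <- theta2; next }
    alpha <- max(-sqrt(sum(r^2)) / vnorm, -1e4)
    alpha <- min(alpha, -1)
    cand <- pmax(theta - 2 * alpha * r + alpha^2 * v, floor_val)
    e_sq <- tryCatch(em_step(cand), error = function(e) NULL)
    if (!is.null(e_sq)) n_eval <- n_eval + 1L
    if (!is.null(e_sq) && e_sq$logL >= e1$logL - 1e-10) {
      trace <- c(trace, e_sq$logL)
      sigma2 <- cand
      ev <- e_sq$ev
      if (abs(e_sq$logL - logL_prev) < tol) { converged <- TRUE; break }
      logL_prev <- e_sq$logL
      theta <- e_sq$s2
    } else {
      theta <- theta2  # reject extrapolation; logL(theta2) >= logL(theta1)
    }
  }

  # average-information matrix at the solution: AI_ij = y'P A_i P A_j P y / 2
  se <- rep(NA_real_, q + 1)
  AI <- matrix(NA_real_, q + 1, q + 1)
  Pt <- vector("list", q + 1)
  for (i in seq_len(q + 1)) {
    ti <- drop(ev$Amult(i, ev$Py))
    Pt[[i]] <- list(t = ti, Pt = drop(ev$Pmult(ti)))
  }
  for (i in seq_len(q + 1)) for (j in i:(q + 1)) {
    AI[i, j] <- AI[j, i] <- 0.5 * sum(Pt[[i]]$t * Pt[[j]]$Pt)
  }
  vcov_s2 <- tryCatch(solve(AI), error = function(e) NULL)
  if (!is.null(vcov_s2) && all(diag(vcov_s2) >= 0)) {
    se <- sqrt(diag(vcov_s2))
  }

  names(sigma2) <- comp_names
  names(se) <- comp_names
  pve <- make_pve(sigma2, vcov_s2, q, spec$weights)
  new_vc_fit(sigma2 = sigma2, se = se, pve = pve, logL = ev$logL,
             n_iter = n_eval, converged = converged, trace = trace, spec = spec,
             vcov = vcov_s2)
}

# PVE with contribution weights: pve_i = w_i s2_i / sum_j w_j s2_j
make_pve <- function(sigma2, vcov_s2, q, w) {
  S <- sum(w * sigma2)
  pve <- w[seq_len(q)] * sigma2[seq_len(q)] / S
  pve_se <- rep(NA_real_, q)
  if (!is.null(vcov_s2)) {
    for (i in seq_len(q)) {
      grad <- -w[i] * sigma2[i] * w / S^2
      grad[i] <- grad[i] + w[i] / S
      v <- drop(crossprod(grad, vcov_s2 %*% grad))
      if (is.finite(v) && v >= 0) pve_se[i] <- sqrt(v)
    }
  }
  tibble::tibble(component = names(sigma2)[seq_len(q)],
                 pve = unname(pve), se = pve_se)
}

empty_pve <- function() {
  tibble::tibble(component = character(), pve = numeric(), se = numeric())
}

new_vc_fit <- function(sigma2, se, pve, logL, n_iter, converged, trace, spec,
                       vcov = NULL) {
  structure(list(sigma2 = sigma2, se_sigma2 = se, pve = pve,
                 logLik = logL, n_iter = n_iter, converged = converged,
                 logl_trace = trace, n = spec$n, p = spec$p,
                 n_components = length(spec$grms),
                 weights = spec$weights,
                 vp = sum(spec$weights * sigma2),
                 sample_ids = spec$sample_ids, vcov_sigma2 = vcov),
            class = "vc_fit")
}

#' @export
print.vc_fit <- function(x, ...) {
  cat(sprintf("<vc_fit> n = %d, %d genetic component(s), logL = %.4f (%s, %d evals)\n",
              x$n, x$n_components, x$logLik,
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  print(tidy(x))
  invisible(x)
}

#' Tidy a variance-component fit
#'
#' One row per variance component with estimate, standard error and (for
#' genetic components) the proportion of phenotypic variance explained.
#'
#' @param x A `vc_fit`.
#' @param ... Unused.
#' @return A tibble with columns `component`, `variance`, `se`, `pve`, `pve_se`.
#' @export
tidy.vc_fit <- function(x, ...) {
  tb <- tibble::tibble(component = names(x$sigma2),
                       variance = unname(x$sigma2),
                       se = unname(x$se_sigma2))
  dplyr::left_join(tb,
                   dplyr::rename(x$pve, pve_se = "se"),
                   by = "component")
}

#' @rdname tidy.vc_fit
#' @export
glance.vc_fit <- function(x, ...) {
  tibble::tibble(logLik = x$logLik, n = x$n, n_iter = x$n_iter,
                 converged = x$converged, vp = x$vp)
}

#' Likelihood-ratio test for the mitochondrial variance component
#'
#' Compares the full model (nuclear + mitochondrial GRMs) with the reduced
#' model (nuclear GRM only). The statistic is `max(0, 2 (logL_full -
#' logL_reduced))`. Because the null value of the tested variance lies on the
#' boundary of its parameter space, the default null distribution is the
#' equal mixture `0.5 chi^2_0 + 0.5 chi^2_1`, giving
#' `p = 0.5 P(chi^2_1 >= statistic)` (so a statistic of exactly 0 has p = 0.5);
#' the plain `chi^2_1` p-value is reported alongside.
#'
#' @param full,reduced `vc_fit` objects on the identical sample set and fixed
#'   effects; `full` must contain exactly one more genetic component.
#' @return An `lrt_result`: one-row tibble with `statistic`, `p_mixture`,
#'   `p_chisq1`, `df`, and the models' log-likelihoods.
#' @export
lrt_mito <- function(full, reduced) {
  stopifnot(inherits(full, "vc_fit"), inherits(reduced, "vc_fit"))
  if (full$n != reduced$n ||
      (!is.null(full$sample_ids) && !is.null(reduced$sample_ids) &&
       !identical(full$sample_ids, reduced$sample_ids))) {
    stop("full and reduced fits are not on the same sample set", call. = FALSE)
  }
  if (full$n_components != reduced$n_components + 1L) {
    stop("full model must have exactly one more variance component", call. = FALSE)
  }
  stat <- max(0, 2 * (full$logLik - reduced$logLik))
  out <- tibble::tibble(
    statistic = stat,
    df = 1L,
    p_mixture = 0.5 * stats::pchisq(stat, df = 1, lower.tail = FALSE),
    p_chisq1 = stats::pchisq(stat, df = 1, lower.tail = FALSE),
    logLik_full = full$logLik,
    logLik_reduced = reduced$logLik,
    convention = "0.5*chisq0 + 0.5*chisq1"
  )
  class(out) <- c("lrt_result", class(out))
  out
}

#' Rank phenotypes by mitochondrial LRT evidence
#'
#' Sorts traits by ascending likelihood-ratio p-value and flags those meeting
#' the prioritization threshold, plus a "suggestive" band just above it.
#'
#' @param lrt_table Tibble with columns `trait` and a p-value column.
#' @param alpha Prioritization threshold (default 0.05).
#' @param alpha_suggestive Upper bound of the suggestive band (default 0.055).
#' @param p_col Which p-value column to rank on (default `"p_mixture"`).
#' @return The table sorted by p, with logical columns `prioritized` and
#'   `suggestive` added.
#' @export
prioritize_phenotypes <- function(lrt_table, alpha = 0.05,
                                  alpha_suggestive = 0.055,
                                  p_col = "p_mixture") {
  stopifnot("trait" %in% names(lrt_table), p_col %in% names(lrt_table),
            alpha > 0, alpha_suggestive >= alpha)
  p <- lrt_table[[p_col]]
  lrt_table |>
    dplyr::mutate(prioritized = p <= alpha,
                  suggestive = p > alpha & p <= alpha_suggestive) |>
    dplyr::arrange(.data[[p_col]])
}
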
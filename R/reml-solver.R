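# Internal REML linear algebra.
#
# The restricted likelihood of y ~ N(Xb, V), V = sum_i s2_i A_i + s2_e I, is
# evaluated through one of two equivalent routes:
#
#   * rotated/low-rank: rotate everything by the eigenvectors of the first GRM
#     so its contribution to V is diagonal; remaining GRMs enter through their
#     positive-eigenvalue factors B_j (A_j = B_j B_j'), and V^{-1} is applied
#     with the Woodbury identity. Per-iteration cost O(n r^2) for total extra
#     rank r, after a one-off eigendecomposition. This is exact algebra, not
#     an approximation, and it is what makes replicate-heavy simulations cheap.
#   * dense: Cholesky of V in the original basis; used when the extra rank is
#     not small relative to n, and as the transparent reference path.
#
# reml_kernel() does the one-off work for a fixed (X-independent) GRM set so
# that many phenotypes can be fit against the same kernels.

#' Precompute the REML kernel for a set of relationship matrices
#'
#' Factorizes the GRMs once (eigendecomposition of the first; low-rank factors
#' of the rest) so repeated model fits against the same matrices -- e.g. many
#' traits or simulation replicates -- skip the expensive linear algebra.
#' Passed to [fit_em_reml()] / [restricted_loglik()] via their `kernel`
#' argument; [mixed_model_spec()] builds one automatically when not supplied.
#'
#' @param grms List of `relationship_matrix` (or plain symmetric matrices),
#'   ordered as in the model; the first is eigendecomposed in full.
#' @param dense_cutoff If the combined rank of the non-leading GRMs exceeds
#'   `dense_cutoff * n`, fall back to dense Cholesky evaluation.
#' @return An opaque `reml_kernel` object.
#' @export
reml_kernel <- function(grms, dense_cutoff = 0.5) {
  grms <- lapply(grms, function(A) {
    A <- unclass(A)
    attributes(A)[setdiff(names(attributes(A)), "dim")] <- NULL
    A
  })
  q <- length(grms)
  n <- if (q > 0) nrow(grms[[1]]) else NA_integer_
  if (q == 0) {
    return(structure(list(q = 0L, mode = "none"), class = "reml_kernel"))
  }
  for (A in grms) stopifnot(nrow(A) == n, ncol(A) == n)

  e1 <- eigen(grms[[1]], symmetric = TRUE)
  d1 <- pmax(e1$values, 0)
  U <- e1$vectors
  Bs <- list()
  ranks <- integer(0)
  if (q > 1) {
    for (j in 2:q) {
      ej <- eigen(grms[[j]], symmetric = TRUE)
      keep <- ej$values > max(ej$values, 0) * 1e-10
      r <- sum(keep)
      Bj <- ej$vectors[, keep, drop = FALSE] %*%
        diag(sqrt(ej$values[keep]), r, r)
      Bs[[j - 1L]] <- crossprod(U, Bj)  # rotated factor
      ranks <- c(ranks, r)
    }
  }
  mode <- if (q == 1 || sum(ranks) <= dense_cutoff * n) "rotated" else "dense"
  structure(list(q = q, n = n, mode = mode, U = U, d1 = d1,
                 B = Bs, ranks = ranks, grms = if (mode == "dense") grms else NULL),
            class = "reml_kernel")
}

# One evaluation of the restricted likelihood machinery at sigma2.
# Returns logL plus the pieces the EM update and the AI matrix need.
# yr, Xr are y and X rotated into the kernel basis (identity for dense mode).
reml_eval <- function(kern, yr, Xr, sigma2, need_traces = TRUE) {
  n <- length(yr)
  p <- ncol(Xr)
  q <- kern$q
  s2e <- sigma2[q + 1L]

  if (q == 0L) {
    # V = s2e I: ordinary least squares in closed form
    if (s2e <= 0) {
      stop("V is not positive definite at the current variance components",
           call. = FALSE)
    }
    qrX <- qr(Xr)
    res <- qr.resid(qrX, yr)
    v <- res / s2e
    logdetV <- n * log(s2e)
    logdetC <- determinant(crossprod(Xr))$modulus[1] - p * log(s2e)
    logL <- -0.5 * ((n - p) * log(2 * pi) + logdetV + logdetC + sum(res^2) / s2e)
    if (!need_traces) return(list(logL = logL, Py = v))
    return(list(logL = logL, Py = v,
                trAP = (n - p) / s2e, quad = sum(v * v),
                Pmult = function(u) qr.resid(qrX, u) / s2e,
                Amult = function(i, u) u))
  }

  if (kern$mode == "dense") {
    V <- diag(s2e, n)
    for (i in seq_len(q)) V <- V + sigma2[i] * kern$grms[[i]]
    ch <- tryCatch(chol(V), error = function(e)
      stop("V is not positive definite at the current variance components",
           call. = FALSE))
    Vinv <- chol2inv(ch)
    M <- Vinv %*% Xr
    C <- crossprod(Xr, M)
    Cch <- chol(C)
    Cinv <- chol2inv(Cch)
    P <- Vinv - M %*% Cinv %*% t(M)
    v <- drop(P %*% yr)
    logdetV <- 2 * sum(log(diag(ch)))
    logdetC <- 2 * sum(log(diag(Cch)))
    yPy <- sum(yr * v)
    logL <- -0.5 * ((n - p) * log(2 * pi) + logdetV + logdetC + yPy)
    if (!need_traces) return(list(logL = logL, Py = v))
    trAP <- numeric(q + 1L)
    quad <- numeric(q + 1L)
    for (i in seq_len(q)) {
      trAP[i] <- sum(kern$grms[[i]] * P)   # tr(A P), both symmetric
      quad[i] <- drop(crossprod(v, kern$grms[[i]] %*% v))
    }
    trAP[q + 1L] <- sum(diag(P))
    quad[q + 1L] <- sum(v * v)
    Pmult <- function(u) P %*% u
    Amult <- function(i, u) if (i <= q) kern$grms[[i]] %*% u else u
    return(list(logL = logL, Py = v, trAP = trAP, quad = quad,
                Pmult = Pmult, Amult = Amult))
  }

  # rotated/low-rank mode
  d1 <- kern$d1
  Delta <- sigma2[1L] * d1 + s2e
  if (any(Delta <= 0)) {
    stop("V is not positive definite at the current variance components",
         call. = FALSE)
  }
  r <- if (q > 1) sum(kern$ranks) else 0L
  if (r > 0) {
    B <- do.call(cbind, lapply(seq_along(kern$B), function(j)
      sqrt(sigma2[j + 1L]) * kern$B[[j]]))
    BD <- B / Delta
    K <- chol(diag(r) + crossprod(B, BD))
    Vinv_mult <- function(u) {
      z <- crossprod(B, u / Delta)
      s <- backsolve(K, backsolve(K, z, transpose = TRUE))
      u / Delta - BD %*% s
    }
    logdetV <- sum(log(Delta)) + 2 * sum(log(diag(K)))
    Kinv <- backsolve(K, diag(r))
    W <- BD %*% Kinv
    diagVinv <- 1 / Delta - rowSums(W * W)
  } else {
    Vinv_mult <- function(u) u / Delta
    logdetV <- sum(log(Delta))
    diagVinv <- 1 / Delta
  }

  M <- Vinv_mult(Xr)                       # V^{-1} X
  C <- crossprod(Xr, M)
  Cch <- chol(C)
  Pmult <- function(u) {
    vu <- Vinv_mult(u)
    s <- backsolve(Cch, backsolve(Cch, crossprod(Xr, vu), transpose = TRUE))
    vu - M %*% s
  }
  v <- drop(Pmult(yr))
  logdetC <- 2 * sum(log(diag(Cch)))
  yPy <- sum(yr * v)
  logL <- -0.5 * ((n - p) * log(2 * pi) + logdetV + logdetC + yPy)
  if (!need_traces) return(list(logL = logL, Py = v))

  ML <- M %*% backsolve(Cch, diag(p))      # so P = Vinv - ML ML'
  diagP <- diagVinv - rowSums(ML * ML)

  trAP <- numeric(q + 1L)
  quad <- numeric(q + 1L)
  trAP[1L] <- sum(d1 * diagP)
  quad[1L] <- sum(d1 * v * v)
  if (q > 1) {
    for (j in 2:q) {
      Bj <- kern$B[[j - 1L]]
      PB <- Pmult(Bj)
      trAP[j] <- sum(Bj * PB)
      quad[j] <- sum(crossprod(Bj, v)^2)
    }
  }
  trAP[q + 1L] <- sum(diagP)
  quad[q + 1L] <- sum(v * v)
  Amult <- function(i, u) {
    if (i == 1L) u * d1
    else if (i <= q) {
      Bj <- kern$B[[i - 1L]]
      Bj %*% crossprod(Bj, u)
    } else u
  }
  list(logL = logL, Py = v, trAP = trAP, quad = quad,
       Pmult = Pmult, Amult = Amult)
}

# rotate (y, X) into kernel basis
reml_rotate <- function(kern, y, X) {
  if (kern$mode == "rotated") {
    list(y = drop(crossprod(kern$U, y)), X = crossprod(kern$U, X))
  } else {
    list(y = y, X = X)
  }
}
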
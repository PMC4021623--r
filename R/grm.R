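# Genetic relationship matrices. Two kinds:
#   nuclear-additive : GCTA-style standardized-dosage cross-products,
#                      A_jk = (1/m) sum_i (x_ij - 2p_i)(x_ik - 2p_i) / (2 p_i (1-p_i))
#   mito-sharing     : haploid allelic sharing (mean identity-by-state),
#                      S_jk = (1/m_jk) sum_i 1{x_ij = x_ik} over jointly
#                      observed sites.

new_relationship_matrix <- function(values, sample_ids, n_snps, kind) {
  dimnames(values) <- list(sample_ids, sample_ids)
  structure(values, n_snps = as.integer(n_snps), kind = kind,
            class = c("relationship_matrix", "matrix", "array"))
}

#' @export
print.relationship_matrix <- function(x, ...) {
  cat(sprintf("<relationship_matrix kind=%s> %d samples, %d SNPs\n",
              attr(x, "kind"), nrow(x), attr(x, "n_snps")))
  invisible(x)
}

#' Nuclear additive genetic relationship matrix
#'
#' GCTA-convention additive GRM from diploid genotypes: dosages are centered at
#' twice the sample A1 frequency and scaled by the binomial standard deviation
#' `sqrt(2 p (1-p))`; missing calls are mean-imputed (zero after centering);
#' entries average the per-SNP products over the m SNPs used. Monomorphic
#' variants carry no information and are excluded with a warning.
#'
#' @param g A diploid [genotype_matrix()].
#' @return A `relationship_matrix` of kind `"nuclear-additive"`.
#' @export
nuclear_grm <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (any(snp_info(g)$ploidy != 2L)) {
    stop("nuclear_grm() requires diploid variants only; use split_genomes()", call. = FALSE)
  }
  calls <- calls_matrix(g)
  p <- colMeans(calls, na.rm = TRUE) / 2
  poly <- !is.na(p) & p > 0 & p < 1
  if (!any(poly)) stop("no polymorphic variants; cannot build a GRM", call. = FALSE)
  if (any(!poly)) {
    warning(sum(!poly), " monomorphic variant(s) excluded from the nuclear GRM",
            call. = FALSE)
  }
  x <- calls[, poly, drop = FALSE]
  p <- p[poly]
  w <- sweep(x, 2L, 2 * p, `-`)
  w <- sweep(w, 2L, sqrt(2 * p * (1 - p)), `/`)
  w[is.na(w)] <- 0
  m <- ncol(w)
  new_relationship_matrix(tcrossprod(w) / m, rownames(calls), m, "nuclear-additive")
}

#' Mitochondrial allelic-sharing relationship matrix
#'
#' The mitochondrial genome is haploid, so relatedness is measured by allelic
#' sharing rather than additive dosage: entry (j, k) is the fraction of
#' jointly observed mtSNPs at which samples j and k carry the same allele
#' (mean identity-by-state). Without missingness this equals
#' `(X X' + (1-X)(1-X)') / m` for 0/1 haplotype matrix `X`, hence the matrix
#' is positive semidefinite with unit diagonal; entries lie in `[0, 1]`.
#'
#' A standardized variant (`standardized = TRUE`) is available for sensitivity
#' analysis: centered presence calls scaled by `sqrt(p (1-p))`, cross-products
#' averaged as in the nuclear GRM.
#'
#' @param g A haploid [genotype_matrix()].
#' @param standardized Use the standardized-haploid estimator instead of mean
#'   identity-by-state.
#' @return A `relationship_matrix` of kind `"mito-sharing"` (or
#'   `"mito-standardized"`).
#' @export
mito_grm <- function(g, standardized = FALSE) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (any(snp_info(g)$ploidy != 1L)) {
    stop("mito_grm() requires haploid variants only; use split_genomes()", call. = FALSE)
  }
  calls <- calls_matrix(g)
  if (ncol(calls) == 0) stop("no mitochondrial variants", call. = FALSE)

  if (standardized) {
    p <- colMeans(calls, na.rm = TRUE)
    poly <- !is.na(p) & p > 0 & p < 1
    if (!any(poly)) stop("no polymorphic mitochondrial variants", call. = FALSE)
    x <- calls[, poly, drop = FALSE]
    p <- p[poly]
    w <- sweep(x, 2L, p, `-`)
    w <- sweep(w, 2L, sqrt(p * (1 - p)), `/`)
    w[is.na(w)] <- 0
    m <- ncol(w)
    return(new_relationship_matrix(tcrossprod(w) / m, rownames(calls), m,
                                   "mito-standardized"))
  }

  obs <- !is.na(calls)
  x1 <- calls
  x1[!obs] <- 0L
  x0 <- 1L - calls
  x0[!obs] <- 0L
  matches <- tcrossprod(x1) + tcrossprod(x0)
  counts <- tcrossprod(obs * 1L)
  if (any(counts == 0)) {
    bad <- which(counts == 0, arr.ind = TRUE)[1, ]
    stop(sprintf("samples %s and %s share no observed mtSNPs; sharing undefined",
                 rownames(calls)[bad[1]], rownames(calls)[bad[2]]), call. = FALSE)
  }
  new_relationship_matrix(matches / counts, rownames(calls), ncol(calls),
                          "mito-sharing")
}

#' Principal components of nuclear genotypes
#'
#' Computes per-sample scores on the top `k` eigenvectors of the covariance of
#' column-standardized genotypes (center `2p`, scale `sqrt(2p(1-p))`, missing
#' calls zero after centering) -- the usual population-stratification PCs.
#' The sample covariance of standardized genotypes equals the nuclear GRM, so
#' scores are its leading eigenvectors. Sign convention: the largest-magnitude
#' loading of each component is positive.
#'
#' @param g A diploid [genotype_matrix()], or a precomputed nuclear
#'   `relationship_matrix`.
#' @param k Number of components (default 2: PC1 and PC2 enter the mt-PheWAS
#'   models as stratification covariates).
#' @return A tibble with columns `sample_id`, `PC1` ... `PCk`, carrying the
#'   eigenvalues in attribute `"eigenvalues"`.
#' @export
compute_pcs <- function(g, k = 2) {
  if (inherits(g, "genotype_matrix")) {
    A <- nuclear_grm(g)
  } else if (inherits(g, "relationship_matrix")) {
    A <- g
  } else stop("g must be a genotype_matrix or relationship_matrix", call. = FALSE)
  n <- nrow(A)
  stopifnot(k >= 1)
  if (k >= n) stop("k must be smaller than the number of samples", call. = FALSE)
  e <- eigen(unclass_rm(A), symmetric = TRUE)
  vec <- e$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(vec[, j]))
    if (vec[i, j] < 0) vec[, j] <- -vec[, j]
  }
  out <- tibble::tibble(sample_id = rownames(A))
  for (j in seq_len(k)) out[[paste0("PC", j)]] <- vec[, j]
  attr(out, "eigenvalues") <- e$values[seq_len(k)]
  out
}

unclass_rm <- function(A) {
  y <- unclass(A)
  attr(y, "n_snps") <- NULL
  attr(y, "kind") <- NULL
  y
}

#' Write / read a GRM in the GCTA binary dialect
#'
#' `<prefix>.grm.bin` holds the lower triangle including the diagonal,
#' row-major, as 4-byte little-endian floats; `<prefix>.grm.N.bin` the per-pair
#' SNP counts in the same order; `<prefix>.grm.id` two tab-separated ID
#' columns (FID, IID). `write_grm_text()` writes the full square matrix as TSV.
#'
#' @param A A `relationship_matrix`.
#' @param prefix Output path prefix.
#' @return `prefix` (writers) or a `relationship_matrix` (reader).
#' @export
write_grm_gcta <- function(A, prefix) {
  stopifnot(inherits(A, "relationship_matrix"))
  n <- nrow(A)
  idx <- grm_tri_index(n)
  con <- file(paste0(prefix, ".grm.bin"), "wb")
  writeBin(as.numeric(A[idx]), con, size = 4, endian = "little")
  close(con)
  con <- file(paste0(prefix, ".grm.N.bin"), "wb")
  writeBin(rep(as.numeric(attr(A, "n_snps")), length(idx)), con,
           size = 4, endian = "little")
  close(con)
  ids <- rownames(A)
  utils::write.table(data.frame(ids, ids), paste0(prefix, ".grm.id"),
                     quote = FALSE, sep = "\t", row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' @rdname write_grm_gcta
#' @param kind Kind tag to attach on read (the binary format does not store it).
#' @export
read_grm_gcta <- function(prefix, kind = "nuclear-additive") {
  ids <- utils::read.table(paste0(prefix, ".grm.id"), colClasses = "character")[[2]]
  n <- length(ids)
  npair <- n * (n + 1) / 2
  v <- readBin(paste0(prefix, ".grm.bin"), "numeric", n = npair, size = 4,
               endian = "little")
  nsnp <- readBin(paste0(prefix, ".grm.N.bin"), "numeric", n = npair, size = 4,
                  endian = "little")
  A <- matrix(0, n, n)
  A[grm_tri_index(n)] <- v
  A <- A + t(A) - diag(diag(A))
  new_relationship_matrix(A, ids, round(max(nsnp)), kind)
}

# linear indices of the row-major lower triangle (GCTA pair order):
# (1,1), (2,1), (2,2), (3,1), ...
grm_tri_index <- function(n) {
  unlist(lapply(seq_len(n), function(i) i + (seq_len(i) - 1L) * n))
}

#' @rdname write_grm_gcta
#' @export
write_grm_text <- function(A, prefix) {
  stopifnot(inherits(A, "relationship_matrix"))
  utils::write.table(as.data.frame(unclass_rm(A)), paste0(prefix, ".grm.tsv"),
                     quote = FALSE, sep = "\t", row.names = TRUE, col.names = NA)
  invisible(prefix)
}
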
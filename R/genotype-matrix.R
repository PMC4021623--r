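#' Construct a genotype matrix
#'
#' A `genotype_matrix` stores allele counts for n samples at m variants together
#' with per-variant metadata. Diploid autosomal calls count copies of the A1
#' allele (0, 1, 2 or `NA`); haploid mitochondrial calls are 0, 1 or `NA`.
#' Ploidy is tied to the chromosome code: variants on the mitochondrial
#' chromosome (code `"MT"`, `"M"` or `"26"`) are haploid, all others diploid.
#' A heterozygous-coded call at a haploid site is invalid and must be `NA`
#' (the reader applies this rule automatically).
#'
#' @param calls Integer matrix, samples in rows, variants in columns.
#' @param chrom Character vector of chromosome codes, one per variant.
#' @param pos Integer vector of 1-based base-pair positions.
#' @param a1,a2 Character vectors of the two alleles per variant. Calls count
#'   copies of `a1`.
#' @param snp_ids Variant identifiers; defaults to `colnames(calls)`, and for
#'   mitochondrial variants with no name the label `mt<pos>` is used.
#' @param sample_ids Sample identifiers; defaults to `rownames(calls)`.
#'
#' @return An object of class `genotype_matrix`.
#' @seealso [read_plink()], [split_genomes()], [allele_frequencies()]
#' @export
genotype_matrix <- function(calls, chrom, pos, a1, a2,
                            snp_ids = NULL, sample_ids = NULL) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  m <- ncol(calls)
  n <- nrow(calls)
  chrom <- as.character(chrom)
  stopifnot(length(chrom) == m, length(pos) == m,
            length(a1) == m, length(a2) == m)
  ploidy <- ifelse(is_mito_chrom(chrom), 1L, 2L)

  if (is.null(snp_ids)) snp_ids <- colnames(calls)
  if (is.null(snp_ids)) {
    snp_ids <- ifelse(ploidy == 1L, paste0("mt", pos), paste0("snp", seq_len(m)))
  }
  if (is.null(sample_ids)) sample_ids <- rownames(calls)
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(n))
  snp_ids <- as.character(snp_ids)
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(snp_ids)) stop("snp_ids must be unique", call. = FALSE)
  if (anyDuplicated(sample_ids)) stop("sample_ids must be unique", call. = FALSE)

  bad_hap <- ploidy == 1L &
    matrixStats_any_gt(calls, 1L)
  if (any(bad_hap)) {
    stop("haploid calls must be 0, 1 or NA; found calls > 1 at ",
         sum(bad_hap), " mitochondrial variant(s)", call. = FALSE)
  }
  rng <- range(calls, na.rm = TRUE)
  if (!all(is.na(calls)) && (rng[1] < 0L || rng[2] > 2L)) {
    stop("calls must lie in {0, 1, 2, NA}", call. = FALSE)
  }

  dimnames(calls) <- list(sample_ids, snp_ids)
  structure(
    calls,
    snps = tibble::tibble(
      snp_id = snp_ids, chrom = chrom, pos = as.integer(pos),
      a1 = as.character(a1), a2 = as.character(a2), ploidy = ploidy
    ),
    class = c("genotype_matrix", "matrix", "array")
  )
}

# per-column "any call above k" helper (NA-safe)
matrixStats_any_gt <- function(x, k) {
  apply(x, 2L, function(col) any(col > k, na.rm = TRUE))
}

is_mito_chrom <- function(chrom) {
  toupper(as.character(chrom)) %in% c("MT", "M", "26", "CHRM", "CHRMT")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  sn <- snp_info(x)
  cat(sprintf("<genotype_matrix> %d samples x %d variants (%d diploid, %d haploid)\n",
              nrow(x), ncol(x), sum(sn$ploidy == 2L), sum(sn$ploidy == 1L)))
  invisible(x)
}

#' Variant metadata of a genotype matrix
#'
#' @param g A [genotype_matrix()].
#' @return A tibble with columns `snp_id`, `chrom`, `pos`, `a1`, `a2`, `ploidy`.
#' @export
snp_info <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  attr(g, "snps")
}

#' @rdname snp_info
#' @export
sample_ids <- function(g) rownames(g)

#' Subset a genotype matrix
#'
#' Keeps class and variant metadata in sync. Indexing with `drop = TRUE` is not
#' supported; the result is always a `genotype_matrix`.
#'
#' @param x A [genotype_matrix()].
#' @param i,j Sample / variant indices (any base indexing form).
#' @param ... Unused.
#' @param drop Ignored (always `FALSE`).
#' @export
`[.genotype_matrix` <- function(x, i, j, ..., drop = FALSE) {
  snps <- attr(x, "snps")
  cls <- class(x)
  y <- unclass(x)
  attr(y, "snps") <- NULL
  if (missing(i)) i <- seq_len(nrow(y))
  if (missing(j)) j <- seq_len(ncol(y))
  if (is.character(j)) j <- match(j, snps$snp_id)
  y <- y[i, j, drop = FALSE]
  snps <- snps[j, , drop = FALSE]
  structure(y, snps = snps, class = cls)
}

# plain integer matrix of calls, attributes stripped
calls_matrix <- function(g) {
  y <- unclass(g)
  attr(y, "snps") <- NULL
  class(y) <- NULL
  y
}
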
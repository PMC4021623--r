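#' Per-variant allele frequencies and minor allele frequency
#'
#' The A1 allele frequency is the count of A1 alleles among non-missing calls
#' divided by `ploidy * n_nonmissing`, so haploid mitochondrial sites use a
#' one-allele-per-sample denominator. Variants with no non-missing calls get
#' `NA` frequencies and are flagged undefined.
#'
#' @param g A [genotype_matrix()].
#' @return A tibble with one row per variant: `snp_id`, `chrom`, `pos`,
#'   `ploidy`, `freq_a1`, `maf`, `n_obs` (non-missing samples).
#' @export
allele_frequencies <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  sn <- snp_info(g)
  calls <- calls_matrix(g)
  n_obs <- colSums(!is.na(calls))
  ac <- colSums(calls, na.rm = TRUE)
  denom <- sn$ploidy * n_obs
  freq <- unname(ifelse(denom > 0, ac / denom, NA_real_))
  tibble::tibble(
    snp_id = sn$snp_id, chrom = sn$chrom, pos = sn$pos, ploidy = sn$ploidy,
    freq_a1 = freq,
    maf = pmin(freq, 1 - freq),
    n_obs = as.integer(unname(n_obs))
  )
}

#' Filter variants by minor allele frequency
#'
#' Retains variants with `maf >= threshold`, preserving order. Variants whose
#' frequency is undefined (all calls missing) are always dropped, with a
#' warning. The operation is idempotent at a fixed threshold.
#'
#' @param g A [genotype_matrix()].
#' @param threshold MAF threshold in `[0, 0.5]`; the mt-PheWAS default is 0.01
#'   (variants below 1% minor allele frequency are excluded before the
#'   single-mtSNP scan).
#' @return A filtered [genotype_matrix()]; may have zero variants.
#' @export
filter_maf <- function(g, threshold = 0.01) {
  stopifnot(inherits(g, "genotype_matrix"),
            threshold >= 0, threshold <= 0.5)
  af <- allele_frequencies(g)
  undef <- is.na(af$maf)
  if (any(undef)) {
    warning(sum(undef), " variant(s) with all calls missing dropped", call. = FALSE)
  }
  keep <- !undef & af$maf >= threshold
  g[, which(keep)]
}

#' Split a genotype matrix into nuclear and mitochondrial parts
#'
#' Partitions variants by ploidy (equivalently, chromosome code). Every input
#' variant lands in exactly one part; order is preserved within parts.
#'
#' @param g A [genotype_matrix()].
#' @return A list with elements `nuclear` and `mito`, each a [genotype_matrix()].
#' @export
split_genomes <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  hap <- snp_info(g)$ploidy == 1L
  list(nuclear = g[, which(!hap)], mito = g[, which(hap)])
}
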
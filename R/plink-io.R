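# PLINK 1 binary triplet reader/writer (bed v1.0, SNP-major).
#
# bed layout: magic bytes 0x6C 0x1B, mode byte 0x01, then for each variant
# ceiling(n/4) bytes; each byte packs four samples, least-significant pair
# first. Two-bit codes: 00 = homozygous A1 (2 copies of A1), 01 = missing,
# 10 = heterozygous (1 copy), 11 = homozygous A2 (0 copies).

# 256 x 4 lookup: byte value -> A1 counts of the four packed samples
plink_decode_lut <- local({
  lut <- NULL
  function() {
    if (is.null(lut)) {
      code <- c(2L, NA_integer_, 1L, 0L)  # indexed by 2-bit value + 1
      b <- 0:255
      lut <<- cbind(
        code[bitwAnd(b, 3L) + 1L],
        code[bitwAnd(bitwShiftR(b, 2L), 3L) + 1L],
        code[bitwAnd(bitwShiftR(b, 4L), 3L) + 1L],
        code[bitwAnd(bitwShiftR(b, 6L), 3L) + 1L]
      )
    }
    lut
  }
})

#' Read a PLINK binary genotype triplet
#'
#' Decodes bed/bim/fam files into a [genotype_matrix()]. Variants whose bim
#' chromosome code is `26`, `M` or `MT` are treated as haploid mitochondrial
#' sites: their calls are recoded from diploid dosage (0/2) to allele presence
#' (0/1) and any heterozygous-coded call is set missing, since a haploid
#' genome cannot be heterozygous. Mitochondrial variants keep their bim
#' identifier; if the bim identifier is `.` they are relabeled `mt<pos>`.
#'
#' @param prefix Path prefix; `<prefix>.bed/.bim/.fam` are read. Alternatively
#'   give the three paths explicitly.
#' @param bed,bim,fam Explicit file paths (override `prefix`).
#' @return A [genotype_matrix()]. Sample IDs are taken from the fam IID column.
#' @examples
#' g <- simulate_genotypes(simulation_config(n_samples = 5, m_nuc = 4, m_mt = 3, seed = 1))
#' pre <- file.path(tempdir(), "toy")
#' write_plink(g, pre)
#' g2 <- read_plink(pre)
#' identical(unclass(g2)[, ], unclass(g)[, ])
#' @export
read_plink <- function(prefix = NULL, bed = NULL, bim = NULL, fam = NULL) {
  if (!is.null(prefix)) {
    if (is.null(bed)) bed <- paste0(prefix, ".bed")
    if (is.null(bim)) bim <- paste0(prefix, ".bim")
    if (is.null(fam)) fam <- paste0(prefix, ".fam")
  }
  bim_tbl <- utils::read.table(bim, header = FALSE, colClasses = "character",
                               col.names = c("chrom", "snp_id", "cm", "pos", "a1", "a2"))
  fam_tbl <- utils::read.table(fam, header = FALSE, colClasses = "character")
  n <- nrow(fam_tbl)
  m <- nrow(bim_tbl)
  bpv <- ceiling(n / 4)  # bytes per variant

  raw <- readBin(bed, what = "raw", n = 3 + m * bpv + 1)
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b)) {
    stop("not a PLINK bed file (bad magic bytes): ", bed, call. = FALSE)
  }
  if (raw[3] != as.raw(0x01)) {
    stop("only SNP-major bed files (mode byte 0x01) are supported", call. = FALSE)
  }
  payload <- raw[-(1:3)]
  if (length(payload) != m * bpv) {
    stop(sprintf("bed payload is %d bytes but %d variants x %d samples need %d (truncated or mismatched bim/fam?)",
                 length(payload), m, n, m * bpv), call. = FALSE)
  }

  lut <- plink_decode_lut()
  bytes <- matrix(as.integer(payload), nrow = bpv, ncol = m)
  calls <- matrix(NA_integer_, nrow = n, ncol = m)
  take <- seq_len(n)
  for (j in seq_len(m)) {
    dec <- t(lut[bytes[, j] + 1L, , drop = FALSE])  # 4 x bpv, sample-order down columns
    calls[, j] <- dec[take]
  }

  hap <- is_mito_chrom(bim_tbl$chrom)
  if (any(hap)) {
    hc <- calls[, hap, drop = FALSE]
    hc[hc == 1L] <- NA_integer_  # het-coded haploid call -> missing
    hc[hc == 2L] <- 1L           # two copies -> allele present
    calls[, hap] <- hc
  }
  ids <- bim_tbl$snp_id
  relabel <- hap & (ids == "." | ids == "")
  ids[relabel] <- paste0("mt", bim_tbl$pos[relabel])

  genotype_matrix(calls,
                  chrom = bim_tbl$chrom, pos = as.integer(bim_tbl$pos),
                  a1 = bim_tbl$a1, a2 = bim_tbl$a2,
                  snp_ids = ids, sample_ids = fam_tbl[[2]])
}

#' Write a PLINK binary genotype triplet
#'
#' Emits the same SNP-major bed dialect [read_plink()] consumes, bit-exactly:
#' haploid calls are written as homozygous dosage (1 copy -> code 00, i.e.
#' two copies of A1 in diploid coding), so a write/read round trip is the
#' identity on calls.
#'
#' @param g A [genotype_matrix()].
#' @param prefix Output path prefix for `.bed/.bim/.fam`.
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(g, prefix) {
  stopifnot(inherits(g, "genotype_matrix"))
  sn <- snp_info(g)
  calls <- calls_matrix(g)
  n <- nrow(calls)
  m <- ncol(calls)

  # haploid presence -> diploid dosage for encoding
  hap <- sn$ploidy == 1L
  if (any(hap)) {
    hc <- calls[, hap, drop = FALSE]
    hc[hc == 1L] <- 2L
    calls[, hap] <- hc
  }
  # A1-count -> 2-bit code: 2->0b00, NA->0b01, 1->0b10, 0->0b11
  twobit <- matrix(3L, n, m)
  twobit[is.na(calls)] <- 1L
  twobit[!is.na(calls) & calls == 1L] <- 2L
  twobit[!is.na(calls) & calls == 2L] <- 0L

  bpv <- ceiling(n / 4)
  pad <- bpv * 4 - n
  if (pad > 0) twobit <- rbind(twobit, matrix(0L, pad, m))
  i1 <- seq(1, bpv * 4, by = 4)
  bytes <- twobit[i1, , drop = FALSE] +
    4L  * twobit[i1 + 1, , drop = FALSE] +
    16L * twobit[i1 + 2, , drop = FALSE] +
    64L * twobit[i1 + 3, , drop = FALSE]

  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(as.vector(bytes)), con)

  utils::write.table(
    data.frame(sn$chrom, sn$snp_id, 0L, sn$pos, sn$a1, sn$a2),
    paste0(prefix, ".bim"),
    quote = FALSE, sep = "\t", row.names = FALSE, col.names = FALSE)
  ids <- sample_ids(g)
  utils::write.table(
    data.frame(ids, ids, 0L, 0L, 0L, -9L),
    paste0(prefix, ".fam"),
    quote = FALSE, sep = "\t", row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}
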
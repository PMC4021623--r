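# Shared fixtures, built in code and memoized so expensive objects (GRMs,
# kernels) are constructed once per test run.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# hand-built genotype matrix from a calls matrix; chroms default diploid "1"
gm <- function(calls, chrom = rep("1", ncol(calls)), pos = seq_len(ncol(calls)),
               a1 = rep("A", ncol(calls)), a2 = rep("G", ncol(calls))) {
  genotype_matrix(calls, chrom = chrom, pos = pos, a1 = a1, a2 = a2)
}

# mid-sized simulated cohort with GRMs and kernels, shared across reml tests
cohort_1000 <- function() {
  memo("cohort_1000", {
    cfg <- simulation_config(n_samples = 1000, m_nuc = 2000, m_mt = 100, seed = 42)
    g <- simulate_genotypes(cfg)
    parts <- split_genomes(g)
    An <- nuclear_grm(parts$nuclear)
    Am <- mito_grm(parts$mito)
    list(cfg = cfg, g = g, parts = parts, An = An, Am = Am,
         k_full = reml_kernel(list(An, Am)),
         k_red = reml_kernel(list(An)),
         roots = list(nuclear = grm_root(An), mito = grm_root(Am)))
  })
}

# small cohort for cheap end-to-end and association checks
cohort_300 <- function() {
  memo("cohort_300", {
    traits <- tibble::tibble(
      trait = c("lipid", "marker", "status"),
      type = c("continuous", "continuous", "binary"),
      pve_nuc = c(0.25, 0.10, 0.15),
      pve_mt = c(0.08, 0, 0),
      mean = c(180, 50, NA), sd = c(40, 15, NA),
      prevalence = c(NA, NA, 0.3))
    cfg <- simulation_config(n_samples = 300, m_nuc = 400, m_mt = 40,
                             traits = traits, seed = 7)
    g <- simulate_genotypes(cfg)
    ph <- simulate_phenotype(g, cfg)
    list(cfg = cfg, g = g, ph = ph)
  })
}
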
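# Synthetic mt-PheWAS data with known variance architecture.
#
# Nuclear variants are i.i.d. binomial dosages at uniform allele frequencies.
# Mitochondrial haplotypes are drawn from a small set of ancestral haplotypes
# (a haplogroup analog) with per-site mutation, which gives the sharing matrix
# the block structure that makes a small mitochondrial variance component
# identifiable; i.i.d. haploid sites would leave it nearly unidentifiable.
# A fraction of mito sites is ancestrally monomorphic with a small mutation
# rate, producing the sub-1%-MAF sites the MAF filter is meant to remove.

#' Configuration for the synthetic mt-PheWAS generator
#'
#' Defaults describe a desk-scale cohort shaped like an EMR biobank
#' mt-PheWAS: modest nuclear polygenic signal, very small mitochondrial
#' signal, age and sex covariates, mostly-female adult cohort.
#'
#' @param n_samples,m_nuc,m_mt Cohort and panel sizes.
#' @param maf_range Nuclear allele-frequency range (uniform draw).
#' @param n_haplotypes Number of ancestral mitochondrial haplotypes.
#' @param mutation_rate Per-site flip probability at ancestrally polymorphic
#'   mito sites.
#' @param frac_rare_mt Fraction of mito sites that are ancestrally monomorphic
#'   with flip rate `rare_mutation_rate`, yielding minor allele frequencies
#'   well below 1%.
#' @param rare_mutation_rate Flip rate at those rare sites.
#' @param traits Tibble with one row per trait: `trait`, `type`
#'   (`"continuous"`/`"binary"`), `pve_nuc`, `pve_mt`, `mean`, `sd`
#'   (reporting scale for continuous traits), `prevalence` (binary traits).
#'   `NULL` gives a single continuous trait with `pve_nuc` 0.30 / `pve_mt`
#'   0.05 -- a clearly detectable architecture for method checks.
#' @param beta_age,beta_sex Fixed-effect sizes on the standardized trait scale.
#' @param age_mean,age_sd,prop_female Covariate distribution (defaults: age
#'   46.1 (16.8) years, 65.4% female).
#' @param seed Integer seed; fixes every draw.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_samples = 2000, m_nuc = 5000, m_mt = 130,
                              maf_range = c(0.05, 0.5),
                              n_haplotypes = 6, mutation_rate = 0.02,
                              frac_rare_mt = 44 / 130,
                              rare_mutation_rate = 0.003,
                              traits = NULL,
                              beta_age = 0.01, beta_sex = 0.1,
                              age_mean = 46.1, age_sd = 16.8,
                              prop_female = 0.654,
                              seed = 1L) {
  if (is.null(traits)) {
    traits <- tibble::tibble(trait = "trait1", type = "continuous",
                             pve_nuc = 0.30, pve_mt = 0.05,
                             mean = 0, sd = 1, prevalence = NA_real_)
  }
  traits <- tibble::as_tibble(traits)
  needed <- c("trait", "type", "pve_nuc", "pve_mt")
  stopifnot(all(needed %in% names(traits)))
  if (!"mean" %in% names(traits)) traits$mean <- 0
  if (!"sd" %in% names(traits)) traits$sd <- 1
  if (!"prevalence" %in% names(traits)) traits$prevalence <- NA_real_
  stopifnot(all(traits$pve_nuc >= 0), all(traits$pve_mt >= 0),
            all(traits$pve_nuc + traits$pve_mt < 1),
            all(traits$type %in% c("continuous", "binary")),
            frac_rare_mt >= 0, frac_rare_mt <= 1,
            n_haplotypes >= 1)
  structure(list(n_samples = n_samples, m_nuc = m_nuc, m_mt = m_mt,
                 maf_range = maf_range, n_haplotypes = n_haplotypes,
                 mutation_rate = mutation_rate, frac_rare_mt = frac_rare_mt,
                 rare_mutation_rate = rare_mutation_rate, traits = traits,
                 beta_age = beta_age, beta_sex = beta_sex,
                 age_mean = age_mean, age_sd = age_sd,
                 prop_female = prop_female, seed = as.integer(seed)),
            class = "simulation_config")
}

#' Simulate nuclear + mitochondrial genotypes
#'
#' Diploid nuclear calls are Binomial(2, p) with per-variant `p` uniform on
#' `cfg$maf_range`. Haploid mitochondrial calls: each individual inherits one
#' of `n_haplotypes` ancestral haplotypes (uniformly), then each site flips
#' with the site's mutation rate. All draws are fixed by `cfg$seed`.
#'
#' @param cfg A [simulation_config()].
#' @return A [genotype_matrix()] with nuclear variants on chromosome 1 and
#'   mito variants (labeled `mt<pos>`) on MT.
#' @export
simulate_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed)
  n <- cfg$n_samples
  ids <- sprintf("S%05d", seq_len(n))

  p_nuc <- stats::runif(cfg$m_nuc, cfg$maf_range[1], cfg$maf_range[2])
  nuc <- matrix(stats::rbinom(n * cfg$m_nuc, 2L, rep(p_nuc, each = n)),
                nrow = n, ncol = cfg$m_nuc)

  m_mt <- cfg$m_mt
  n_rare <- round(cfg$frac_rare_mt * m_mt)
  rare <- seq_len(m_mt) <= n_rare  # first block rare, positions shuffled below
  h <- cfg$n_haplotypes
  anc <- matrix(stats::rbinom(h * m_mt, 1L, 0.5), nrow = h, ncol = m_mt)
  anc[, rare] <- 0L  # ancestrally monomorphic sites
  hap_of <- sample.int(h, n, replace = TRUE)
  mt <- anc[hap_of, , drop = FALSE]
  rate <- ifelse(rare, cfg$rare_mutation_rate, cfg$mutation_rate)
  flips <- matrix(stats::rbinom(n * m_mt, 1L, rep(rate, each = n)),
                  nrow = n, ncol = m_mt)
  mt <- (mt + flips) %% 2L

  pos_mt <- sort(sample.int(16569L, m_mt))
  calls <- cbind(nuc, mt)
  out <- genotype_matrix(
    calls,
    chrom = c(rep("1", cfg$m_nuc), rep("MT", m_mt)),
    pos = c(seq_len(cfg$m_nuc) * 1000L, pos_mt),
    a1 = rep("A", cfg$m_nuc + m_mt),
    a2 = rep("G", cfg$m_nuc + m_mt),
    snp_ids = c(sprintf("rs%06d", seq_len(cfg$m_nuc)), paste0("mt", pos_mt)),
    sample_ids = ids)
  # generating truth, for ground-truth checks downstream
  attr(out, "sim_truth") <- list(p_nuc = p_nuc, haplotype = hap_of, rare_mt = rare)
  out
}

#' Simulate phenotypes with a known variance architecture
#'
#' Generates, per configured trait, `y = X beta + g_nuc + g_mt + e` on a
#' standardized scale: genetic values are multivariate normal with covariance
#' proportional to the respective GRM (drawn through its eigendecomposition,
#' tiny negative eigenvalues clipped to zero) and each random part is rescaled
#' so its realized sample variance equals its target share exactly --
#' `pve_nuc`, `pve_mt` and `1 - pve_nuc - pve_mt`. Continuous traits are then
#' shifted/scaled to the configured reporting mean and SD. Binary traits
#' threshold the latent liability at its empirical `1 - prevalence` quantile,
#' so case fractions match the configuration exactly.
#'
#' @param g A [genotype_matrix()] from [simulate_genotypes()].
#' @param cfg The same [simulation_config()].
#' @param grms Optional precomputed `list(nuclear = , mito = )` relationship
#'   matrices (else computed here).
#' @param roots Optional precomputed `list(nuclear = , mito = )` symmetric
#'   square roots from [grm_root()]; supply these when drawing many phenotype
#'   replicates on fixed genotypes, to skip the per-call eigendecomposition.
#' @return A tibble: `sample_id`, `age` (years), `sex` (1 = female, 0 = male),
#'   one column per trait. Attribute `"genetic_values"` stores the per-trait
#'   realized genetic components for ground-truth checks.
#' @export
simulate_phenotype <- function(g, cfg, grms = NULL, roots = NULL) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed + 1L)
  n <- nrow(g)
  if (is.null(roots)) {
    if (is.null(grms)) {
      parts <- split_genomes(g)
      grms <- list(nuclear = nuclear_grm(parts$nuclear),
                   mito = mito_grm(parts$mito))
    }
    roots <- list(nuclear = grm_root(grms$nuclear), mito = grm_root(grms$mito))
  }
  rn <- roots$nuclear
  rm_ <- roots$mito

  age <- stats::rnorm(n, cfg$age_mean, cfg$age_sd)
  sex <- stats::rbinom(n, 1L, cfg$prop_female)

  out <- tibble::tibble(sample_id = sample_ids(g), age = age, sex = sex)
  gvals <- list()
  for (i in seq_len(nrow(cfg$traits))) {
    tr <- cfg$traits[i, ]
    u_nuc <- scale_to_var(drop(rn %*% stats::rnorm(ncol(rn))), tr$pve_nuc)
    u_mt <- scale_to_var(drop(rm_ %*% stats::rnorm(ncol(rm_))), tr$pve_mt)
    e <- scale_to_var(stats::rnorm(n), 1 - tr$pve_nuc - tr$pve_mt)
    fixed <- cfg$beta_age * (age - cfg$age_mean) / cfg$age_sd +
      cfg$beta_sex * sex
    latent <- fixed + u_nuc + u_mt + e
    if (tr$type == "continuous") {
      out[[tr$trait]] <- tr$mean + tr$sd * latent
    } else {
      thr <- stats::quantile(latent, 1 - tr$prevalence, names = FALSE)
      out[[tr$trait]] <- as.integer(latent > thr)
    }
    gvals[[tr$trait]] <- list(nuc = u_nuc, mt = u_mt)
  }
  attr(out, "genetic_values") <- gvals
  out
}

#' Symmetric square root of a relationship matrix
#'
#' Eigendecomposition-based square root `R` with `R R' = A`; tiny negative
#' eigenvalues (numerical) are clipped to zero. Used by the phenotype
#' generator to draw multivariate-normal genetic values; precompute it once
#' when drawing many replicates on fixed genotypes.
#'
#' @param A A `relationship_matrix` (or plain symmetric matrix).
#' @return An n x n matrix.
#' @export
grm_root <- function(A) {
  e <- eigen(unclass_rm(A), symmetric = TRUE)
  d <- pmax(e$values, 0)
  e$vectors %*% (t(e$vectors) * sqrt(d))
}

scale_to_var <- function(u, target) {
  if (target <= 0) return(rep(0, length(u)))
  v <- stats::var(u)
  if (v <= 0) stop("degenerate genetic value draw; cannot rescale", call. = FALSE)
  (u - mean(u)) * sqrt(target / v)
}

#' Desk-scale fixture shaped like an EMR biobank mt-PheWAS
#'
#' 2000 samples, 5000 nuclear SNPs, 130 mtSNPs of which about 44 fall below
#' 1% MAF; eight cardiometabolic-style traits (six continuous, two binary)
#' with nuclear PVE up to ~3% and mitochondrial PVE up to ~0.33%, one trait
#' (`total_cholesterol`) carrying the largest mito signal; ages ~ N(46, 17),
#' 65% female. Trait means and SDs are plausible for an adult EMR cohort; the
#' genotypes and effects are entirely synthetic.
#'
#' @param seed Integer seed.
#' @return List with `genotypes`, `phenotypes`, `config`.
#' @export
make_paper_like_fixture <- function(seed = 1L) {
  traits <- tibble::tibble(
    trait = c("bmi", "total_cholesterol", "hdl", "ldl", "triglycerides",
              "mch", "hypertension", "t2d"),
    type = c(rep("continuous", 6), "binary", "binary"),
    pve_nuc = c(0.020, 0.020, 0.010, 0.015, 0.0295, 0.0033, 0.015, 0.020),
    pve_mt  = c(0.0010, 0.0033, 0.0005, 0.0008, 0.0010, 0.0002, 0.0008, 0.0030),
    mean = c(28.8, 179.2, 52.7, 102.1, 116.6, 28.4, NA, NA),
    sd = c(6.6, 38.9, 16.9, 35.3, 69.3, 2.6, NA, NA),
    prevalence = c(rep(NA, 6), 6147 / (6147 + 2664), 1338 / (1338 + 8151)))
  cfg <- simulation_config(n_samples = 2000, m_nuc = 5000, m_mt = 130,
                           traits = traits, seed = seed)
  g <- simulate_genotypes(cfg)
  ph <- simulate_phenotype(g, cfg)
  list(genotypes = g, phenotypes = ph, config = cfg)
}
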
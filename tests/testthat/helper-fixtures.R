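# Shared fixture builders: everything is generated in code at test time.

# A small unphased genotype matrix with full control over codes.
toy_gm <- function(genotypes, positions = seq_len(nrow(genotypes)),
                   ref = rep("A", nrow(genotypes)),
                   alt = rep("G", nrow(genotypes)),
                   ancestral = ref, region_length = max(positions, 1),
                   ...) {
  genotype_matrix(positions, ref, alt, ancestral, genotypes,
                  region_length, ...)
}

# Manifest from a per-sample population vector; group_of maps population to
# group (identity by default), coords are per population.
toy_manifest <- function(samples, populations, group_of = NULL,
                         lat = NULL, lon = NULL) {
  pops <- unique(populations)
  if (is.null(group_of)) group_of <- setNames(pops, pops)
  if (is.null(lat)) lat <- setNames(rep(0, length(pops)), pops)
  if (is.null(lon)) lon <- setNames(rep(0, length(pops)), pops)
  sample_manifest(data.frame(
    sample = samples, population = populations,
    group = unname(group_of[populations]),
    lat = unname(lat[populations]), lon = unname(lon[populations]),
    stringsAsFactors = FALSE))
}

with_seed2 <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

# Random biallelic genotype matrix under Hardy-Weinberg with allele
# frequencies p (one per site).
hwe_gm <- function(p, n_ind, seed = 1) {
  with_seed2(seed, {
    g <- t(vapply(p, function(pp) rbinom(n_ind, 2, pp), integer(n_ind)))
    toy_gm(g)
  })
}

# Simulated single-population phased dataset for oracle comparisons.
neutral_sim <- function(n_chrom = 10, theta = 5, seed = 1, n_loci = 1) {
  simulate_dataset(demographic_model(1), n_chrom, theta = theta, L = 1e4,
                   seed = seed, n_loci = n_loci)
}

# Independent Weir-Cockerham oracle via the three-level ANOVA mean-square
# formulation on gamete indicators (a genuinely different derivation path
# from the frequency-based variance components in the package).
wc_anova_oracle <- function(geno_list) {
  # geno_list: per population, integer vector of genotype codes (0/1/2)
  r <- length(geno_list)
  ni <- vapply(geno_list, length, integer(1))
  ntot <- sum(ni)
  pi_ <- vapply(geno_list, function(g) mean(g) / 2, numeric(1))
  pbar <- sum(ni * pi_) / ntot
  nc <- (ntot - sum(ni^2) / ntot) / (r - 1)
  SS_G <- sum(vapply(geno_list, function(g) sum(g == 1) / 2, numeric(1)))
  SS_I <- 2 * sum(unlist(mapply(function(g, p) (g / 2 - p)^2, geno_list,
                                pi_, SIMPLIFY = FALSE)))
  SS_P <- 2 * sum(ni * (pi_ - pbar)^2)
  MS_G <- SS_G / ntot
  MS_I <- SS_I / (ntot - r)
  MS_P <- SS_P / (r - 1)
  c(c = MS_G, b = (MS_I - MS_G) / 2, a = (MS_P - MS_I) / (2 * nc))
}
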
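#' Segregating and private segregating sites
#'
#' @param x A [genotype_matrix()].
#' @param unit_samples Sample ids of the unit.
#' @param all_samples Sample ids of the full panel (default: all samples in
#'   `x`); `Sp` counts sites segregating in the unit but monomorphic in
#'   `setdiff(all_samples, unit_samples)`.
#' @return A list with `S` and `Sp`.
#' @export
count_segregating <- function(x, unit_samples, all_samples = sample_ids(x)) {
  if (!length(unit_samples)) stop("empty unit")
  if (!all(unit_samples %in% all_samples))
    stop("unit_samples must be a subset of all_samples")
  seg <- function(samples) {
    ac <- allele_counts(x, samples)
    ac$alt > 0L & ac$alt < ac$n_chrom
  }
  in_unit <- seg(unit_samples)
  comp <- setdiff(all_samples, unit_samples)
  private <- if (length(comp)) in_unit & !seg(comp) else in_unit
  list(S = sum(in_unit), Sp = sum(private))
}

# Harmonic sums used throughout
harmonic <- function(n) sum(1 / seq_len(n))
harmonic2 <- function(n) sum(1 / seq_len(n)^2)

#' Watterson's theta with a coalescent-variance confidence interval
#'
#' `theta = S / (a_n * L)` per bp, with `a_n = sum(1/i), i < n_chrom`.  The
#' CI is a normal approximation using the neutral-coalescent variance of S,
#' `var(S) = a_n * theta_L + b_n * theta_L^2` (theta_L the per-region
#' estimate, `b_n = sum(1/i^2)`).
#'
#' @param S Number of segregating sites.
#' @param n_chrom Number of sampled chromosomes (>= 2).
#' @param L Region length in bp.
#' @param conf Confidence level (default 0.95).
#' @return List with `estimate` (per bp) and `ci` (length-2 vector).
#' @export
watterson_theta <- function(S, n_chrom, L, conf = 0.95) {
  if (n_chrom < 2) stop("n_chrom must be >= 2")
  stopifnot(L > 0, S >= 0)
  a <- harmonic(n_chrom - 1)
  b <- harmonic2(n_chrom - 1)
  theta_L <- S / a
  sd_S <- sqrt(a * theta_L + b * theta_L^2)
  z <- qnorm(1 - (1 - conf) / 2)
  est <- S / (a * L)
  list(estimate = est,
       ci = c(max(0, est - z * sd_S / (a * L)), est + z * sd_S / (a * L)))
}

#' Nucleotide diversity (pi) with a coalescent-variance CI
#'
#' Missing-data-aware frequency formula: per site,
#' `n_s/(n_s - 1) * 2 * p * (1 - p)` with `n_s` the called chromosomes and
#' `p` the alternate (derived, if polarized) allele frequency; summed over
#' sites and divided by L.  The CI uses Tajima's neutral variance of pi,
#' `var(pi_L) = b1 * pi_L + b2 * pi_L^2` with
#' `b1 = (n + 1) / (3(n - 1))`, `b2 = 2(n^2 + n + 3) / (9 n (n - 1))`.
#'
#' @inheritParams count_segregating
#' @param L Region length in bp.
#' @param conf Confidence level.
#' @return List with `estimate` (per bp), `ci`, and `pi_total`
#'   (the per-region sum, used by Tajima's D).
#' @export
nucleotide_diversity <- function(x, unit_samples, L = x$region_length,
                                 conf = 0.95) {
  if (!length(unit_samples)) stop("empty unit")
  ac <- allele_counts(x, unit_samples)
  use <- ac$n_chrom >= 2
  n_s <- ac$n_chrom[use]
  p <- ac$alt[use] / n_s
  pi_total <- sum(n_s / (n_s - 1) * 2 * p * (1 - p))
  n <- 2L * length(unit_samples)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  sd_pi <- sqrt(b1 * pi_total + b2 * pi_total^2)
  z <- qnorm(1 - (1 - conf) / 2)
  est <- pi_total / L
  list(estimate = est,
       ci = c(max(0, est - z * sd_pi / L), est + z * sd_pi / L),
       pi_total = pi_total)
}

#' Observed SNP heterozygosity per bp
#'
#' Mean heterozygote fraction per site (heterozygote count over genotyped
#' individuals), summed over sites and divided by L.
#'
#' @inheritParams nucleotide_diversity
#' @return H per bp.
#' @export
observed_heterozygosity <- function(x, unit_samples, L = x$region_length) {
  g <- x$genotypes[, unit_samples, drop = FALSE]
  n_called <- rowSums(!is.na(g))
  n_het <- rowSums(g == 1L, na.rm = TRUE)
  sum(ifelse(n_called > 0, n_het / n_called, 0)) / L
}

#' Mean windowed haplotype heterozygosity
#'
#' The region is cut into `ceiling(L / window_size)` non-overlapping windows
#' anchored at position 1.  Within each window, haplotype heterozygosity is
#' the unbiased `n/(n - 1) * (1 - sum(f_h^2))` over distinct haplotype
#' strings among the unit's `2 * nInd` phased haplotypes; windows with no
#' segregating site contribute 0.  Returns the unweighted mean over windows.
#'
#' @inheritParams nucleotide_diversity
#' @param window_size Window size in bp (default 10 kb).
#' @return Mean haplotype heterozygosity in `[0, 1]`.
#' @export
haplotype_heterozygosity <- function(x, unit_samples, window_size = 1e4) {
  if (!x$phased || is.null(x$haplotypes))
    stop("haplotype heterozygosity needs phased input; phase externally ",
         "(e.g. with a phasing tool) or use simulated haplotypes")
  j <- match(unit_samples, sample_ids(x))
  hcols <- as.vector(rbind(2L * j - 1L, 2L * j))
  h <- x$haplotypes[, hcols, drop = FALSE]
  n <- ncol(h)
  nwin <- ceiling(x$region_length / window_size)
  win <- pmin(floor((x$positions - 1) / window_size) + 1L, nwin)
  het <- numeric(nwin)
  for (w in seq_len(nwin)) {
    rows <- which(win == w)
    if (!length(rows)) next
    hs <- apply(h[rows, , drop = FALSE], 2, paste, collapse = "")
    f <- table(hs) / n
    if (length(f) > 1)
      het[w] <- n / (n - 1) * (1 - sum(f^2))
  }
  mean(het)
}

#' Tajima's D with simulation-based significance
#'
#' `D = (pi_total - S/a_n) / sqrt(e1 * S + e2 * S * (S - 1))` with Tajima's
#' constants from `n_chrom`.  The two-sided P-value is the fraction of
#' standard-neutral coalescent replicates, conditioned on `n_chrom` and `S`
#' (S mutations placed on branches proportionally to length), with
#' `|D_sim| >= |D|`.
#'
#' @param S Segregating sites (>= 1; `S = 0` returns `D = NA`).
#' @param pi_total Sum of per-site heterozygosity over the region (average
#'   pairwise differences).
#' @param n_chrom Number of chromosomes.
#' @param n_reps Null-simulation replicates (default 10000).
#' @param seed Optional seed for the null simulation.
#' @return List with `D` and `P`.
#' @export
tajimas_d <- function(S, pi_total, n_chrom, n_reps = 10000, seed = NULL) {
  if (S < 1) return(list(D = NA_real_, P = NA_real_))
  n <- n_chrom
  a1 <- harmonic(n - 1); a2 <- harmonic2(n - 1)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  D <- (pi_total - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
  sims <- with_seed(seed, cpp_sim_tajima_null(n, S, n_reps))
  list(D = D, P = mean(abs(sims) >= abs(D)))
}

#' Per-unit diversity table
#'
#' Computes the standard per-unit summary: nInd, S, Sp, Watterson's theta
#' and pi (per bp, reported x 1e-5, with CIs), observed SNP heterozygosity
#' (x 1e-5), mean windowed haplotype heterozygosity (when phased), and
#' Tajima's D with its simulation P-value.
#'
#' @param x A [genotype_matrix()].
#' @param manifest A [sample_manifest()].
#' @param level `"population"`, `"group"`, or `"both"`.
#' @param window_size Window size for haplotype heterozygosity.
#' @param d_reps Replicates for the Tajima's D null distribution.
#' @param seed Seed for the D null simulation.
#' @return A data.frame, one row per unit.
#' @export
diversity_table <- function(x, manifest, level = c("both", "population",
                                                   "group"),
                            window_size = 1e4, d_reps = 10000, seed = 1) {
  level <- match.arg(level)
  units <- list()
  if (level %in% c("both", "group"))
    for (u in unique(manifest$group))
      units[[u]] <- list(level = "group",
                         samples = samples_of(manifest, u, "group"))
  if (level %in% c("both", "population"))
    for (u in unique(manifest$population))
      units[[u]] <- list(level = "population",
                         samples = samples_of(manifest, u, "population"))
  L <- x$region_length
  rows <- lapply(names(units), function(u) {
    ids <- intersect(units[[u]]$samples, sample_ids(x))
    seg <- count_segregating(x, ids)
    n_chrom <- 2L * length(ids)
    th <- watterson_theta(seg$S, n_chrom, L)
    pi <- nucleotide_diversity(x, ids, L)
    H <- observed_heterozygosity(x, ids, L)
    hh <- if (x$phased && !is.null(x$haplotypes))
      haplotype_heterozygosity(x, ids, window_size) else NA_real_
    td <- tajimas_d(seg$S, pi$pi_total, n_chrom, n_reps = d_reps, seed = seed)
    data.frame(unit = u, level = units[[u]]$level, nInd = length(ids),
               S = seg$S, Sp = seg$Sp,
               theta = th$estimate * 1e5, theta_lo = th$ci[1] * 1e5,
               theta_hi = th$ci[2] * 1e5,
               pi = pi$estimate * 1e5, pi_lo = pi$ci[1] * 1e5,
               pi_hi = pi$ci[2] * 1e5,
               H = H * 1e5, HapHet = hh, TajimaD = td$D, P = td$P)
  })
  do.call(rbind, rows)
}
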
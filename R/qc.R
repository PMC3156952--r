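#' Dataset-construction filters
#'
#' Applies the fixed filter order used when assembling a multi-population
#' SNP matrix from resequencing calls: (1) drop individuals whose call rate
#' (fraction of non-missing sites, computed on the input matrix) is below
#' `call_rate_min`; (2) drop sites monomorphic across all retained samples;
#' (3) drop sites with more than two observed alleles.  Hardy-Weinberg
#' screening is a separate step ([hwe_filter()]) so that its Bonferroni
#' denominator is the post-filter site count.
#'
#' @param x A [genotype_matrix()].
#' @param call_rate_min Minimum per-individual call rate (default 0.80);
#'   individuals strictly below the threshold are removed.
#' @return A list with elements `matrix` (filtered) and `log`
#'   (a `filter_log`).
#' @export
filter_dataset <- function(x, call_rate_min = 0.80) {
  stopifnot(n_sites(x) >= 1, n_samples(x) >= 1)
  call_rate <- colMeans(!is.na(x$genotypes))
  keep_ind <- call_rate >= call_rate_min
  if (!any(keep_ind))
    stop("no samples survive call-rate filter")
  x1 <- subset_gm(x, j = which(keep_ind))

  fixed <- site_is_monomorphic(x1)
  multi <- grepl(",", x1$alt, fixed = TRUE)
  keep_site <- !fixed & !multi
  x2 <- subset_gm(x1, i = which(keep_site))

  log <- filter_log(
    individuals_removed = sum(!keep_ind),
    sites_in = n_sites(x),
    sites_fixed = sum(fixed),
    sites_multiallelic = sum(multi & !fixed),
    sites_hwe = 0L,
    sites_out = n_sites(x2))
  list(matrix = x2, log = log)
}

site_is_monomorphic <- function(x, samples = sample_ids(x)) {
  ac <- allele_counts(x, samples)
  ac$alt == 0L | ac$alt == ac$n_chrom
}

filter_log <- function(individuals_removed = 0L, sites_in = 0L,
                       sites_fixed = 0L, sites_multiallelic = 0L,
                       sites_hwe = 0L, sites_out = 0L,
                       M = NA_integer_, alpha = NA_real_) {
  structure(list(individuals_removed = individuals_removed,
                 sites_in = sites_in, sites_fixed = sites_fixed,
                 sites_multiallelic = sites_multiallelic,
                 sites_hwe = sites_hwe, sites_out = sites_out,
                 M = M, alpha = alpha),
            class = "filter_log")
}

#' @export
print.filter_log <- function(x, ...) {
  cat("filter_log:\n")
  for (nm in names(x)) cat(sprintf("  %-20s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' @rdname filter_dataset
#' @param log A `filter_log`.
#' @param path Output path for the JSON serialization.
#' @export
write_filter_log <- function(log, path) {
  jsonlite::write_json(unclass(log), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Fill reference genotypes where no variant call was attempted
#'
#' In reference-based SNP calling only non-reference genotypes are emitted,
#' so a population in which a site is invariant has no calls there at all;
#' those cells are filled in as homozygous reference (code 0) and flagged in
#' the provenance matrix `x$filled`.
#'
#' @param x A [genotype_matrix()].
#' @param population_site_mask Logical matrix, sites x populations (column
#'   names are population labels), marking cells where no call was attempted.
#' @param manifest A [sample_manifest()] used to expand populations to
#'   samples.
#' @return The filled [genotype_matrix()].
#' @export
fill_reference_genotypes <- function(x, population_site_mask, manifest) {
  m <- population_site_mask
  if (!is.matrix(m) || nrow(m) != n_sites(x))
    stop("mask must be a sites x populations logical matrix")
  pops <- colnames(m)
  if (is.null(pops) || !all(pops %in% manifest$population))
    stop("mask shape mismatch: column names must be known populations")
  filled <- x$filled
  if (is.null(filled))
    filled <- matrix(FALSE, n_sites(x), n_samples(x),
                     dimnames = dimnames(x$genotypes))
  g <- x$genotypes
  for (p in pops) {
    rows <- which(m[, p])
    if (!length(rows)) next
    cols <- match(samples_of(manifest, p), sample_ids(x))
    cols <- cols[!is.na(cols)]
    block <- g[rows, cols, drop = FALSE]
    if (any(!is.na(block)))
      stop("mask covers already-called genotypes in population '", p,
           "' (contradictory input)")
    g[rows, cols] <- 0L
    filled[rows, cols] <- TRUE
  }
  x$genotypes <- g
  x$filled <- filled
  x
}

#' Exact Hardy-Weinberg test for one biallelic site
#'
#' Exact conditional test (no mid-P correction): the P-value is the summed
#' probability of all heterozygote counts, given the observed allele counts,
#' whose probability does not exceed that of the observed count.
#'
#' @param n_hom_ref,n_het,n_hom_alt Genotype counts.
#' @return The exact P-value.
#' @export
hwe_exact_test <- function(n_hom_ref, n_het, n_hom_alt) {
  n <- n_hom_ref + n_het + n_hom_alt
  n_alt <- 2L * n_hom_alt + n_het
  n_minor <- min(n_alt, 2L * n - n_alt)
  if (n == 0 || n_minor == 0) return(1)
  hets <- seq.int(n_minor %% 2L, n_minor, by = 2L)
  # log P(het = h | allele counts) up to a constant
  lp <- lgamma(n + 1) - lgamma(hets + 1) -
    lgamma((n_minor - hets) / 2 + 1) -
    lgamma(n - (n_minor + hets) / 2 + 1) + hets * log(2)
  p <- exp(lp - max(lp))
  p <- p / sum(p)
  obs <- which(hets == n_het)
  if (!length(obs)) stop("heterozygote count incompatible with allele count")
  sum(p[p <= p[obs] * (1 + 1e-12)])
}

#' Combined-Z Hardy-Weinberg filter across populations
#'
#' Per population and site, an exact Hardy-Weinberg test P-value is computed
#' (populations monomorphic at the site, or with fewer than 2 genotyped
#' diploids, contribute nothing).  P-values are mapped to Z-scores by
#' `Z = qnorm(1 - P)` (clamped to keep Z finite), combined across the k
#' contributing populations as `sum(Z) / sqrt(k)` (Stouffer, equal weights),
#' and converted back to a two-sided P.  Sites with combined
#' `P < alpha / M` *in the violation direction* (positive combined Z) are
#' removed, where M is the number of sites tested; the negative-Z tail
#' reflects the discreteness of the exact P-value, not HWE departure (see
#' the methods vignette).
#'
#' @param x A [genotype_matrix()].
#' @param manifest A [sample_manifest()].
#' @param alpha Nominal level before Bonferroni correction (default 0.01).
#' @return A list with `matrix`, `log` (a `filter_log` carrying `M` and
#'   `alpha`), and `p_combined` (per-site combined P, NA when untestable).
#' @export
hwe_filter <- function(x, manifest, alpha = 0.01) {
  pops <- unique(manifest$population)
  S <- n_sites(x)
  zsum <- numeric(S)
  k <- integer(S)
  for (p in pops) {
    cols <- match(intersect(samples_of(manifest, p), sample_ids(x)),
                  sample_ids(x))
    if (length(cols) < 2) next
    g <- x$genotypes[, cols, drop = FALSE]
    n0 <- rowSums(g == 0L, na.rm = TRUE)
    n1 <- rowSums(g == 1L, na.rm = TRUE)
    n2 <- rowSums(g == 2L, na.rm = TRUE)
    testable <- (n0 + n1 + n2) >= 2 & (n1 + n2) > 0 & (n0 + n1) > 0
    if (!any(testable)) next
    pv <- vapply(which(testable),
                 function(i) hwe_exact_test(n0[i], n1[i], n2[i]), numeric(1))
    pv <- pmin(pmax(pv, 1e-15), 1 - 1e-15)
    zsum[testable] <- zsum[testable] + qnorm(1 - pv)
    k[testable] <- k[testable] + 1L
  }
  tested <- k > 0L
  M <- sum(tested)
  p_comb <- z_comb <- rep(NA_real_, S)
  zc <- zsum[tested] / sqrt(k[tested])
  z_comb[tested] <- zc
  p_comb[tested] <- 2 * pnorm(-abs(zc))
  # Removal is one-sided in the violation direction (positive combined Z,
  # i.e. small per-population P-values).  The exact-test P is discrete and
  # stochastically larger than uniform under the null, so the negative-Z
  # tail carries clamping artifacts, not evidence against HWE; removing
  # there would break the type-I guarantee.
  drop <- tested & z_comb > 0 & p_comb < alpha / max(M, 1L)
  x2 <- subset_gm(x, i = which(!drop))
  log <- filter_log(sites_in = S, sites_hwe = sum(drop), sites_out = S - sum(drop),
                    M = M, alpha = alpha)
  list(matrix = x2, log = log, p_combined = p_comb, z_combined = z_comb)
}

#' Polarize alleles into ancestral/derived states
#'
#' Relabels each site so that the reference column holds the ancestral
#' allele and the alternate column the derived allele.  Where the outgroup
#' allele matches one of the two alleles, the other one is derived; where it
#' is unknown or matches neither, the global minor allele is taken as
#' derived (fallback).  Applying the function twice equals applying it once.
#'
#' @param x A [genotype_matrix()].
#' @param outgroup_alleles Character vector, one outgroup nucleotide per
#'   site, `NA` when unknown.
#' @return The polarized [genotype_matrix()]; per-site method in
#'   `attr(, "polarize_method")` (`"outgroup"` or `"minor"`).
#' @export
polarize_alleles <- function(x, outgroup_alleles) {
  if (length(outgroup_alleles) != n_sites(x))
    stop("need one outgroup allele per site")
  og <- toupper(as.character(outgroup_alleles))
  og[og %in% c(".", "", "N")] <- NA_character_
  ac <- allele_counts(x)
  alt_freq <- ifelse(ac$n_chrom > 0, ac$alt / ac$n_chrom, 0)
  method <- ifelse(!is.na(og) & (og == x$ref | og == x$alt),
                   "outgroup", "minor")
  # ancestral is ref unless evidence says otherwise
  swap <- (method == "outgroup" & og == x$alt) |
    (method == "minor" & alt_freq > 0.5)
  swap[is.na(swap)] <- FALSE
  if (any(swap)) {
    i <- which(swap)
    tmp <- x$ref[i]
    x$ref[i] <- x$alt[i]
    x$alt[i] <- tmp
    x$genotypes[i, ] <- 2L - x$genotypes[i, , drop = FALSE]
    if (!is.null(x$haplotypes))
      x$haplotypes[i, ] <- 1L - x$haplotypes[i, , drop = FALSE]
  }
  x$ancestral <- x$ref
  attr(x, "polarize_method") <- method
  x
}

#' Subsample the panel to equalize unit sizes
#'
#' Draws a uniform random subsample without replacement of `n_per_unit`
#' samples from each unit (population or continental group); units with at
#' most `n_per_unit` samples are kept whole.
#'
#' @param manifest A [sample_manifest()].
#' @param level `"population"`, `"group"` or `"continent"`.
#' @param n_per_unit Target number of individuals per unit.
#' @param seed Integer seed; the same seed reproduces the same selection.
#' @return The subsampled [sample_manifest()].
#' @export
subsample_panel <- function(manifest, level = c("population", "group",
                                                "continent"),
                            n_per_unit, seed = 1) {
  level <- match.arg(level)
  if (level == "continent") level <- "group"
  lab <- manifest[[level]]
  with_seed(seed, {
    keep <- unlist(lapply(unique(lab), function(u) {
      ids <- manifest$sample[lab == u]
      if (length(ids) <= n_per_unit) ids else sample(ids, n_per_unit)
    }))
  })
  sample_manifest(manifest[manifest$sample %in% keep, ])
}

#' Dataset bookkeeping summaries
#'
#' Derived quantities routinely reported when a multi-population SNP panel
#' is assembled: the percentage of SNPs specific to one set of populations,
#' the percentage of newly discovered SNPs absent from a reference panel,
#' the SNP density (bp per SNP), and the number of sites retained after
#' Hardy-Weinberg screening.
#'
#' @param n_total Total SNPs in the merged panel.
#' @param n_specific SNPs restricted to the focal populations.
#' @param n_discovered SNPs found in the newly sequenced samples.
#' @param n_novel Newly discovered SNPs absent from the reference panel.
#' @param L Region length in bp.
#' @param n_tested_hwe Sites entering the Hardy-Weinberg screen.
#' @param n_failed_hwe Sites removed by the screen.
#' @return A list with `specific_pct`, `novel_pct`, `bp_per_snp`,
#'   `hwe_retained`.
#' @export
dataset_bookkeeping <- function(n_total, n_specific, n_discovered, n_novel,
                                L, n_tested_hwe, n_failed_hwe) {
  stopifnot(n_total > 0, n_discovered > 0, L > 0)
  list(specific_pct = 100 * n_specific / n_total,
       novel_pct = 100 * n_novel / n_discovered,
       bp_per_snp = L / n_discovered,
       hwe_retained = n_tested_hwe - n_failed_hwe)
}
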
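#' Genotype matrix for a single resequenced region
#'
#' The central container of the pipeline: biallelic SNP genotypes for a set
#' of diploid samples within one named region, together with ancestral-allele
#' annotation.  Genotype codes count copies of the alternate allele
#' (0, 1, 2); missing calls are `NA`.
#'
#' @param positions Integer vector of 1-based bp coordinates within the
#'   region, strictly increasing.
#' @param ref,alt Single-nucleotide reference and alternate alleles per site.
#'   `alt` may contain comma-separated strings for multi-allelic records;
#'   those sites can only be removed downstream, never analysed.
#' @param ancestral Ancestral allele per site, `NA` when unknown.
#' @param genotypes Integer matrix, sites x samples, entries in
#'   `c(0L, 1L, 2L, NA)`; column names are sample ids.
#' @param region_length Region length L in bp; must be at least
#'   `max(positions)`.
#' @param region Region name (metadata only, never used in arithmetic).
#' @param phased Logical; whether haplotypes are available.
#' @param haplotypes Optional integer matrix, sites x (2 * n samples), 0/1
#'   copies of the alternate allele.  Haplotype columns `2i - 1` and `2i`
#'   belong to sample `i`.
#' @param filled Optional logical matrix marking genotypes that were
#'   filled in with the homozygous-reference code (provenance flag).
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(positions, ref, alt, ancestral, genotypes,
                            region_length, region = "region1",
                            phased = FALSE, haplotypes = NULL,
                            filled = NULL) {
  positions <- as.integer(positions)
  S <- length(positions)
  if (S > 1 && any(diff(positions) <= 0))
    stop("positions must be strictly increasing")
  if (length(ref) != S || length(alt) != S || length(ancestral) != S)
    stop("ref, alt and ancestral must have one entry per site")
  if (!is.matrix(genotypes) || nrow(genotypes) != S)
    stop("genotypes must be a sites x samples matrix")
  storage.mode(genotypes) <- "integer"
  ok <- is.na(genotypes) | genotypes %in% 0:2
  if (!all(ok))
    stop("genotype codes must be 0, 1, 2 or NA")
  biallelic <- !grepl(",", alt, fixed = TRUE)
  if (any(biallelic & ref == alt))
    stop("ref and alt must differ at every biallelic site")
  if (region_length < if (S) max(positions) else 1L)
    stop("region_length must be >= max(positions)")
  if (is.null(colnames(genotypes)))
    colnames(genotypes) <- paste0("sample", seq_len(ncol(genotypes)))
  if (!is.null(haplotypes)) {
    if (nrow(haplotypes) != S || ncol(haplotypes) != 2L * ncol(genotypes))
      stop("haplotypes must be sites x (2 * n samples)")
    storage.mode(haplotypes) <- "integer"
  }
  if (!is.null(filled) && !identical(dim(filled), dim(genotypes)))
    stop("filled flag matrix must match genotype dimensions")
  structure(list(
    region = region, region_length = as.numeric(region_length),
    positions = positions, ref = as.character(ref), alt = as.character(alt),
    ancestral = as.character(ancestral), genotypes = genotypes,
    phased = isTRUE(phased), haplotypes = haplotypes, filled = filled
  ), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf(
    "genotype_matrix: %d sites x %d samples, region '%s' (%g bp)%s\n",
    n_sites(x), n_samples(x), x$region, x$region_length,
    if (x$phased) ", phased" else ""))
  n_anc <- sum(!is.na(x$ancestral))
  cat(sprintf("  ancestral allele known at %d/%d sites\n", n_anc, n_sites(x)))
  invisible(x)
}

#' @rdname genotype_matrix
#' @param x A `genotype_matrix`.
#' @export
n_sites <- function(x) length(x$positions)

#' @rdname genotype_matrix
#' @export
n_samples <- function(x) ncol(x$genotypes)

#' @rdname genotype_matrix
#' @export
sample_ids <- function(x) colnames(x$genotypes)

# Subset sites (i) and/or samples (j), keeping haplotype/provenance slots
# aligned.  Internal but reused across modules.
subset_gm <- function(x, i = NULL, j = NULL) {
  if (is.null(i)) i <- seq_len(n_sites(x))
  if (is.null(j)) j <- seq_len(n_samples(x))
  if (is.character(j)) j <- match(j, sample_ids(x))
  hap <- x$haplotypes
  if (!is.null(hap)) {
    hcols <- as.vector(rbind(2L * j - 1L, 2L * j))
    hap <- hap[i, hcols, drop = FALSE]
  }
  genotype_matrix(
    positions = x$positions[i], ref = x$ref[i], alt = x$alt[i],
    ancestral = x$ancestral[i],
    genotypes = x$genotypes[i, j, drop = FALSE],
    region_length = x$region_length, region = x$region,
    phased = x$phased, haplotypes = hap,
    filled = if (is.null(x$filled)) NULL else x$filled[i, j, drop = FALSE])
}

# Alternate-allele count and called-chromosome count per site for a sample
# subset; the workhorse of most statistics.
allele_counts <- function(x, samples = sample_ids(x)) {
  g <- x$genotypes[, samples, drop = FALSE]
  called <- !is.na(g)
  list(alt = rowSums(g, na.rm = TRUE), n_chrom = 2L * rowSums(called))
}

#' Sample manifest
#'
#' Maps every sample to a population, continental group, and the geographic
#' origin (decimal degrees) used for great-circle distances.  Population to
#' group and population to origin mappings must be one-to-one.
#'
#' @param df A data.frame with columns `sample`, `population`, `group`,
#'   `lat`, `lon`.
#' @return A `sample_manifest` (a validated data.frame).
#' @export
sample_manifest <- function(df) {
  need <- c("sample", "population", "group", "lat", "lon")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("manifest is missing columns: ", paste(miss, collapse = ", "))
  df <- as.data.frame(df)[need]
  if (anyDuplicated(df$sample))
    stop("duplicate sample ids in manifest")
  if (any(is.na(df$population)) || any(!nzchar(df$population)))
    stop("every sample needs a population label")
  by_pop <- unique(df[c("population", "group", "lat", "lon")])
  if (anyDuplicated(by_pop$population))
    stop("each population must map to exactly one group and origin")
  df$sample <- as.character(df$sample)
  class(df) <- c("sample_manifest", "data.frame")
  df
}

#' @rdname sample_manifest
#' @param manifest A `sample_manifest`.
#' @param unit A population or group label.
#' @param level `"population"` or `"group"` (alias `"continent"`).
#' @return `samples_of()`: character vector of sample ids in the unit.
#' @export
samples_of <- function(manifest, unit, level = c("population", "group",
                                                 "continent")) {
  level <- match.arg(level)
  if (level == "continent") level <- "group"
  lab <- manifest[[level]]
  if (!unit %in% lab)
    stop("unknown ", level, " label: ", unit)
  manifest$sample[lab == unit]
}

#' Region analysis configuration
#'
#' @param region Region name.
#' @param L Region length in bp.
#' @param window_size Window size in bp for haplotype statistics
#'   (default 10 kb, giving `ceiling(L / window_size)` windows).
#' @param generation_time Generation time in years (default 25).
#' @param mu Mutation rate per bp per generation.
#' @return A `region_config` list.
#' @export
region_config <- function(region = "region1", L = 1e5, window_size = 1e4,
                          generation_time = 25, mu = 1.48e-8) {
  stopifnot(L > 0, window_size > 0, generation_time > 0, mu > 0)
  structure(list(region = region, L = L, window_size = window_size,
                 generation_time = generation_time, mu = mu),
            class = "region_config")
}
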
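#' Weir-Cockerham FST
#'
#' Multi-locus Weir-Cockerham theta-hat from diploid genotypes: per locus the
#' variance components a (among populations), b (among individuals within
#' populations), and c (within individuals) are computed from sample sizes,
#' allele frequencies, and observed heterozygote frequencies; the estimate
#' is the ratio of sums `sum(a) / sum(a + b + c)`.  Negative estimates are
#' reported as computed.
#'
#' Pairwise mode (`unit_b` given) pools each unit into one population;
#' within-group mode (`unit_b = NULL`, `level = "group"`) uses all
#' populations inside `unit_a` as the subpopulations.
#'
#' @param x A [genotype_matrix()].
#' @param manifest A [sample_manifest()].
#' @param unit_a,unit_b Unit labels at `level`; `unit_b = NULL` requests the
#'   within-group estimate for group `unit_a`.
#' @param level `"population"` or `"group"`.
#' @param percent Report as percent (x 100, the conventional table scale)?
#' @return The FST estimate.
#' @export
wc_fst <- function(x, manifest, unit_a, unit_b = NULL,
                   level = c("group", "population"), percent = FALSE) {
  level <- match.arg(level)
  if (is.null(unit_b)) {
    pops <- unique(manifest$population[manifest$group == unit_a])
    if (length(pops) < 2)
      stop("within-group mode needs a group with >= 2 populations")
    groups <- lapply(pops, function(p) samples_of(manifest, p, "population"))
  } else {
    groups <- list(samples_of(manifest, unit_a, level),
                   samples_of(manifest, unit_b, level))
  }
  est <- wc_fst_components(x, groups)$fst
  if (percent) 100 * est else est
}

# groups: list of character vectors of sample ids (one per subpopulation).
# Returns per-locus components and the ratio-of-sums estimate.
wc_fst_components <- function(x, groups) {
  r <- length(groups)
  ni <- hi <- pi_ <- matrix(0, n_sites(x), r)
  for (j in seq_len(r)) {
    ids <- intersect(groups[[j]], sample_ids(x))
    g <- x$genotypes[, ids, drop = FALSE]
    ni[, j] <- rowSums(!is.na(g))
    hi[, j] <- ifelse(ni[, j] > 0, rowSums(g == 1L, na.rm = TRUE) / ni[, j], 0)
    pi_[, j] <- ifelse(ni[, j] > 0,
                       rowSums(g, na.rm = TRUE) / (2 * ni[, j]), 0)
  }
  usable <- rowSums(ni >= 2) == r
  if (!any(usable))
    stop("every locus has a unit with < 2 genotyped individuals")
  ni <- ni[usable, , drop = FALSE]
  hi <- hi[usable, , drop = FALSE]
  pi_ <- pi_[usable, , drop = FALSE]
  nbar <- rowMeans(ni)
  nc <- (r * nbar - rowSums(ni^2) / (r * nbar)) / (r - 1)
  pbar <- rowSums(ni * pi_) / (r * nbar)
  s2 <- rowSums(ni * (pi_ - pbar)^2) / ((r - 1) * nbar)
  hbar <- rowSums(ni * hi) / (r * nbar)
  a <- nbar / nc *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  list(a = a, b = b, c = cc, fst = sum(a) / sum(a + b + cc))
}

#' Pairwise FST matrix
#'
#' Builds the conventional report matrix at the requested level, in percent.
#' At the group level the diagonal holds the within-group among-population
#' estimate (NA for groups with a single population); at the population
#' level the diagonal is NA.
#'
#' @inheritParams wc_fst
#' @return A symmetric numeric matrix (percent).
#' @export
fst_matrix <- function(x, manifest, level = c("group", "population")) {
  level <- match.arg(level)
  units <- unique(manifest[[level]])
  k <- length(units)
  m <- matrix(NA_real_, k, k, dimnames = list(units, units))
  for (i in seq_len(k))
    for (j in seq_len(k)) {
      if (j < i) next
      if (i == j) {
        if (level == "group" &&
            length(unique(manifest$population[manifest$group ==
                                              units[i]])) >= 2)
          m[i, i] <- wc_fst(x, manifest, units[i], NULL, level = "group",
                            percent = TRUE)
      } else {
        m[i, j] <- m[j, i] <- wc_fst(x, manifest, units[i], units[j],
                                     level = level, percent = TRUE)
      }
    }
  m
}

#' Nei's standard genetic distance
#'
#' `D = -ln(I)` with `I = J_ab / sqrt(J_a * J_b)`, where `J_ab` is the mean
#' over loci of the cross-population product of allele frequencies and
#' `J_a`, `J_b` the mean homozygosities.  `I <= 0` returns `Inf`.
#'
#' @param freqs_a,freqs_b Per-locus allele-frequency vectors: either numeric
#'   vectors of alternate-allele frequencies at the same biallelic loci, or
#'   lists of per-locus frequency vectors over matching allele sets.
#' @return Nei's D.
#' @export
nei_distance <- function(freqs_a, freqs_b) {
  if (is.numeric(freqs_a)) {
    freqs_a <- lapply(freqs_a, function(p) c(p, 1 - p))
    freqs_b <- lapply(freqs_b, function(p) c(p, 1 - p))
  }
  if (length(freqs_a) != length(freqs_b))
    stop("frequency lists must cover the same loci")
  jab <- mean(mapply(function(a, b) sum(a * b), freqs_a, freqs_b))
  ja <- mean(vapply(freqs_a, function(a) sum(a^2), numeric(1)))
  jb <- mean(vapply(freqs_b, function(b) sum(b^2), numeric(1)))
  I <- jab / sqrt(ja * jb)
  if (I <= 0) return(Inf)
  -log(I)
}

#' Nei distance matrix between units
#'
#' @inheritParams wc_fst
#' @return Symmetric matrix of Nei's D with zero diagonal.
#' @export
nei_matrix <- function(x, manifest, level = c("population", "group")) {
  level <- match.arg(level)
  units <- unique(manifest[[level]])
  freqs <- lapply(units, function(u) {
    ac <- allele_counts(x, intersect(samples_of(manifest, u, level),
                                     sample_ids(x)))
    ifelse(ac$n_chrom > 0, ac$alt / ac$n_chrom, 0)
  })
  k <- length(units)
  m <- matrix(0, k, k, dimnames = list(units, units))
  for (i in seq_len(k))
    for (j in seq_len(k))
      if (j > i) m[i, j] <- m[j, i] <- nei_distance(freqs[[i]], freqs[[j]])
  m
}

#' Principal-coordinates analysis of a distance matrix
#'
#' Classical scaling (metric MDS): double-centre `-0.5 * D^2`, eigen
#' decompose, and scale eigenvectors by the square root of their (positive)
#' eigenvalues.  The variance fraction of each retained component is its
#' eigenvalue over the sum of positive eigenvalues.  Sign convention: the
#' largest-magnitude loading on each axis is positive.
#'
#' @param d Symmetric distance matrix with unit labels as dimnames.
#' @param n_components Number of components to retain.
#' @return A `pcoa_result` with `coordinates` (units x components) and
#'   `variance_fraction`.
#' @export
pcoa <- function(d, n_components = 2) {
  d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-8))
    stop("distance matrix must be symmetric")
  n_components <- min(n_components, nrow(d) - 1)
  sc <- cmdscale(d, k = n_components, eig = TRUE)
  coords <- sc$points
  for (j in seq_len(ncol(coords))) {
    i <- which.max(abs(coords[, j]))
    if (coords[i, j] < 0) coords[, j] <- -coords[, j]
  }
  pos <- sc$eig[sc$eig > 0]
  colnames(coords) <- paste0("PC", seq_len(ncol(coords)))
  structure(list(coordinates = coords,
                 variance_fraction = sc$eig[seq_len(n_components)] / sum(pos),
                 eigenvalues = sc$eig),
            class = "pcoa_result")
}

#' @export
print.pcoa_result <- function(x, ...) {
  cat("pcoa_result:", nrow(x$coordinates), "units,",
      ncol(x$coordinates), "components\n")
  cat("variance explained:",
      paste0(sprintf("%.1f%%", 100 * x$variance_fraction), collapse = ", "),
      "\n")
  invisible(x)
}

#' Great-circle distance (haversine)
#'
#' @param lat1,lon1,lat2,lon2 Decimal degrees.
#' @param radius_km Sphere radius (default 6371 km).
#' @return Distance in km.
#' @export
great_circle_km <- function(lat1, lon1, lat2, lon2, radius_km = 6371) {
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  2 * radius_km * asin(pmin(1, sqrt(a)))
}

#' Heterozygosity-distance correlation
#'
#' Correlates per-unit SNP heterozygosity against the great-circle distance
#' from a reference origin (default Addis Ababa, a proposed point of modern
#' human origin), with a two-sided t-test P-value.
#'
#' @param H Named numeric vector of per-unit heterozygosity.
#' @param coords Data frame with columns `unit`, `lat`, `lon` covering the
#'   names of `H`, or a [sample_manifest()] (population origins are used).
#' @param origin `c(lat, lon)` of the reference origin in decimal degrees.
#' @return A `geo_correlation` list: `distance_km` (named), `r`, `p`.
#' @export
geo_correlation <- function(H, coords, origin = c(lat = 9.03, lon = 38.74)) {
  if (length(H) < 3) stop("need at least 3 units")
  if (inherits(coords, "sample_manifest"))
    coords <- unique(data.frame(unit = coords$population, lat = coords$lat,
                                lon = coords$lon))
  m <- match(names(H), coords$unit)
  if (anyNA(m)) stop("missing coordinates for: ",
                     paste(names(H)[is.na(m)], collapse = ", "))
  d <- great_circle_km(coords$lat[m], coords$lon[m], origin[1], origin[2])
  names(d) <- names(H)
  ct <- cor.test(d, H, method = "pearson")
  structure(list(distance_km = d, r = unname(ct$estimate),
                 p = ct$p.value), class = "geo_correlation")
}
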
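#' Demographic models in diffusion scaling
#'
#' A model has `npop` present-day populations with relative sizes (units of
#' the reference size `N_ref`) and backward exponential growth rates, plus a
#' time-ordered event list applied backward in time.  Times are in units of
#' `2 * N_ref` generations.  Present-day size `nu` with backward rate
#' `alpha` means the size at time t was `nu * exp(-alpha * t)`.
#'
#' @param npop Number of present-day populations.
#' @param sizes Relative sizes at time 0.
#' @param growth Backward exponential growth rates at time 0.
#' @param migration Scaled per-lineage migration rate to each other active
#'   population (symmetric island style); 0 disables migration.
#' @param events List of events from [ev_size()], [ev_join()],
#'   [ev_migration()]; sorted stably by time.
#' @param labels Population labels.
#' @return A `demographic_model`.
#' @export
demographic_model <- function(npop, sizes = rep(1, npop),
                              growth = rep(0, npop), migration = 0,
                              events = list(),
                              labels = paste0("pop", seq_len(npop))) {
  stopifnot(npop >= 1, length(sizes) == npop, length(growth) == npop,
            all(sizes > 0), migration >= 0, length(labels) == npop)
  for (e in events) {
    if (!inherits(e, "demographic_event")) stop("events must be built with ev_*()")
    if (e$type == 1L && (e$a > npop || e$b > npop || e$a == e$b))
      stop("join event references an invalid population")
    if (e$type == 0L && e$a > npop)
      stop("size event references an invalid population")
  }
  times <- vapply(events, function(e) e$time, numeric(1))
  if (length(events)) events <- events[order(times)]
  # exactly one root: every population except one must eventually be joined
  joined <- vapply(events, function(e)
    if (e$type == 1L) as.integer(e$a) else NA_integer_, integer(1))
  structure(list(npop = npop, sizes = as.numeric(sizes),
                 growth = as.numeric(growth), migration = migration,
                 events = events, labels = labels,
                 n_roots = npop - sum(!is.na(joined))),
            class = "demographic_model")
}

#' @rdname demographic_model
#' @param time Event time (units of `2 * N_ref` generations).
#' @param pop,from,to Population indices (1-based).
#' @param size New relative size at `time`.
#' @param rate New scaled migration rate, or backward growth rate for
#'   [ev_size()].
#' @export
ev_size <- function(time, pop, size, rate = 0)
  structure(list(time = time, type = 0L, a = pop, b = 1L, size = size,
                 growth = rate), class = "demographic_event")

#' @rdname demographic_model
#' @export
ev_join <- function(time, from, to)
  structure(list(time = time, type = 1L, a = from, b = to, size = 0,
                 growth = 0), class = "demographic_event")

#' @rdname demographic_model
#' @export
ev_migration <- function(time, rate)
  structure(list(time = time, type = 2L, a = 1L, b = 1L, size = rate,
                 growth = 0), class = "demographic_event")

#' @export
print.demographic_model <- function(x, ...) {
  cat(sprintf("demographic_model: %d population(s): %s\n", x$npop,
              paste(x$labels, collapse = ", ")))
  cat(sprintf("  sizes: %s; growth: %s; migration: %g\n",
              paste(signif(x$sizes, 4), collapse = ", "),
              paste(signif(x$growth, 4), collapse = ", "), x$migration))
  for (e in x$events) {
    desc <- switch(as.character(e$type),
      "0" = sprintf("set size of %s to %.4g (growth %.4g)",
                    x$labels[e$a], e$size, e$growth),
      "1" = sprintf("join %s into %s", x$labels[e$a], x$labels[e$b]),
      "2" = sprintf("set migration rate to %.4g", e$size))
    cat(sprintf("  t = %.5g: %s\n", e$time, desc))
  }
  invisible(x)
}

model_to_cpp <- function(m) {
  ev <- m$events
  list(npop = m$npop, sizes = m$sizes, growth = m$growth,
       migration = m$migration,
       ev_time = vapply(ev, `[[`, numeric(1), "time"),
       ev_type = vapply(ev, `[[`, integer(1), "type"),
       ev_a = vapply(ev, function(e) as.integer(e$a), integer(1)),
       ev_b = vapply(ev, function(e) as.integer(e$b), integer(1)),
       ev_size = vapply(ev, `[[`, numeric(1), "size"),
       ev_growth = vapply(ev, `[[`, numeric(1), "growth"))
}

#' Simulate a polarized dataset under a demographic model
#'
#' Simulates `n_loci` independent non-recombining sub-loci spanning the
#' region (the default single locus treats the region as one genealogy;
#' sub-loci approximate recombination and power the block bootstrap).
#' Mutations follow the infinite-sites model with total scaled rate `theta`
#' (`= 4 * N_ref * mu * L`), positions drawn uniformly within each
#' sub-locus (collisions redrawn), and the ancestral allele known by
#' construction.
#'
#' @param model A [demographic_model()].
#' @param sample_sizes Integer vector: sampled chromosomes per present-day
#'   population.
#' @param theta Total scaled mutation rate for the region; alternatively
#'   give `mu` and `N_ref` and leave `theta = NULL`.
#' @param L Region length in bp.
#' @param seed Integer seed.
#' @param n_loci Number of independent equal-length sub-loci.
#' @param mu,N_ref Mutation rate per bp per generation and reference size,
#'   used when `theta` is NULL.
#' @return A `sim_replicate`: `haplotypes` (sites x chromosomes 0/1
#'   derived-allele matrix), `positions`, `locus`, `ancestral`/`derived`
#'   nucleotides, `sample_sizes`, `labels`, and a `truth` record.
#' @export
simulate_dataset <- function(model, sample_sizes, theta = NULL, L = 1e5,
                             seed = 1, n_loci = 1, mu = NULL, N_ref = NULL) {
  stopifnot(all(sample_sizes >= 1), n_loci >= 1, L >= n_loci)
  if (is.null(theta)) {
    if (is.null(mu) || is.null(N_ref))
      stop("give theta, or both mu and N_ref")
    theta <- 4 * N_ref * mu * L
  }
  if (theta <= 0) stop("theta must be positive (mu * L > 0)")
  has_mig <- model$migration > 0 ||
    any(vapply(model$events, function(e) e$type == 2L && e$size > 0,
               logical(1)))
  if (model$n_roots != 1 && !has_mig)
    stop("model must merge all populations into a single root ",
         "(or allow migration); lineages could not coalesce")
  cm <- model_to_cpp(model)
  with_seed(seed, {
    loci <- cpp_sim_loci(cm, as.integer(sample_sizes), theta / n_loci,
                         as.integer(n_loci))
    bounds <- round(seq(0, L, length.out = n_loci + 1))
    pos <- integer(0); locus <- integer(0)
    for (l in seq_len(n_loci)) {
      s <- nrow(loci[[l]])
      lo <- bounds[l] + 1; hi <- max(bounds[l + 1], lo)
      p <- sort(sample(seq.int(lo, hi), min(s, hi - lo + 1)))
      if (s > hi - lo + 1) {  # more mutations than bp: drop the excess
        loci[[l]] <- loci[[l]][seq_along(p), , drop = FALSE]
        s <- length(p)
      }
      pos <- c(pos, p)
      locus <- c(locus, rep(l, s))
    }
    hap <- do.call(rbind, loci)
    bases <- c("A", "C", "G", "T")
    anc <- sample(bases, length(pos), replace = TRUE)
    der <- vapply(anc, function(b) sample(setdiff(bases, b), 1), character(1))
  })
  structure(list(haplotypes = hap, positions = pos, locus = locus,
                 ancestral = unname(anc), derived = unname(der),
                 sample_sizes = as.integer(sample_sizes),
                 labels = model$labels, L = L,
                 truth = list(theta = theta, n_loci = n_loci, seed = seed)),
            class = "sim_replicate")
}

#' @export
print.sim_replicate <- function(x, ...) {
  cat(sprintf("sim_replicate: %d segregating sites, %d chromosomes (%s), %d loci\n",
              nrow(x$haplotypes), ncol(x$haplotypes),
              paste(x$sample_sizes, collapse = "+"),
              max(x$locus)))
  invisible(x)
}

#' Convert a simulated replicate to diploid genotypes
#'
#' Chromosomes are paired within each population in sampling order
#' (chromosomes 2i-1 and 2i form individual i), preserving phase.
#'
#' @param sim A `sim_replicate` with an even number of chromosomes per
#'   population.
#' @param sample_prefix Prefix for generated sample ids.
#' @return A [genotype_matrix()] (phased, polarized: ref = ancestral).
#' @export
sim_to_genotypes <- function(sim, sample_prefix = "s") {
  if (any(sim$sample_sizes %% 2 != 0))
    stop("diploid pairing needs an even number of chromosomes per population")
  h <- sim$haplotypes
  g <- h[, seq(1, ncol(h), 2), drop = FALSE] +
    h[, seq(2, ncol(h), 2), drop = FALSE]
  n <- ncol(g)
  colnames(g) <- sprintf("%s%04d", sample_prefix, seq_len(n))
  gm <- genotype_matrix(sim$positions, ref = sim$ancestral,
                        alt = sim$derived, ancestral = sim$ancestral,
                        genotypes = g, region_length = sim$L,
                        phased = TRUE, haplotypes = h)
  attr(gm, "locus") <- sim$locus
  gm
}

#' Joint site-frequency spectrum
#'
#' A k-dimensional tensor whose entry `(i_1, ..., i_k)` (0-based per axis)
#' counts sites with derived-allele count `i_j` in population j.  The
#' monomorphic corners are retained (maskable in the likelihood).
#'
#' @param x A `sim_replicate` or a polarized [genotype_matrix()].
#' @param ... Passed to methods.
#' @return A `joint_sfs` array with attributes `sample_sizes` and `labels`.
#' @export
joint_sfs <- function(x, ...) UseMethod("joint_sfs")

new_joint_sfs <- function(arr, sample_sizes, labels) {
  structure(arr, sample_sizes = as.integer(sample_sizes), labels = labels,
            class = c("joint_sfs", class(arr)))
}

sfs_from_counts <- function(counts, sample_sizes, labels) {
  # counts: sites x k matrix of derived counts
  dims <- sample_sizes + 1L
  arr <- array(0, dim = dims)
  if (nrow(counts)) {
    mult <- cumprod(c(1, dims[-length(dims)]))
    idx <- as.vector(counts %*% mult) + 1L
    tab <- tabulate(idx, nbins = prod(dims))
    arr[] <- tab
  }
  new_joint_sfs(arr, sample_sizes, labels)
}

#' @rdname joint_sfs
#' @param fold Fold the spectrum (no polarization required)?
#' @export
joint_sfs.sim_replicate <- function(x, fold = FALSE, ...) {
  k <- length(x$sample_sizes)
  edges <- cumsum(c(0L, x$sample_sizes))
  counts <- sapply(seq_len(k), function(j)
    rowSums(x$haplotypes[, (edges[j] + 1):edges[j + 1], drop = FALSE]))
  counts <- matrix(counts, ncol = k)
  if (fold) counts <- fold_counts(counts, x$sample_sizes)
  sfs_from_counts(counts, x$sample_sizes, x$labels)
}

#' @rdname joint_sfs
#' @param manifest A [sample_manifest()].
#' @param level `"group"` or `"population"`.
#' @export
joint_sfs.genotype_matrix <- function(x, manifest,
                                      level = c("group", "population"),
                                      fold = FALSE, ...) {
  level <- match.arg(level)
  if (!fold && any(is.na(x$ancestral)))
    stop("unpolarized input: polarize_alleles() first, or set fold = TRUE")
  units <- unique(manifest[[level]])
  counts <- sapply(units, function(u) {
    ids <- intersect(samples_of(manifest, u, level), sample_ids(x))
    ac <- allele_counts(x, ids)
    der <- ifelse(!fold & !is.na(x$ancestral) & x$ancestral == x$alt,
                  ac$n_chrom - ac$alt, ac$alt)
    der
  })
  counts <- matrix(counts, ncol = length(units))
  sizes <- vapply(units, function(u)
    2L * length(intersect(samples_of(manifest, u, level), sample_ids(x))),
    integer(1))
  if (fold) counts <- fold_counts(counts, sizes)
  sfs_from_counts(counts, sizes, units)
}

fold_counts <- function(counts, sizes) {
  flip <- rowSums(counts) > sum(sizes) / 2
  counts[flip, ] <- rep(sizes, each = sum(flip)) - counts[flip, , drop = FALSE]
  counts
}

#' @export
print.joint_sfs <- function(x, ...) {
  ss <- attr(x, "sample_sizes")
  cat(sprintf("joint_sfs over %s (n = %s); %g segregating sites\n",
              paste(attr(x, "labels"), collapse = ", "),
              paste(ss, collapse = ", "),
              sum(x) - x[1] - x[length(x)]))
  invisible(x)
}

#' Monte-Carlo expected joint SFS
#'
#' Expected derived-allele count tensor under a model: the mean total branch
#' length subtending each leaf configuration is estimated over
#' `n_replicates` genealogies and multiplied by `theta / 2`.  Exactly linear
#' in `theta`; deterministic under `seed`; a standard-error tensor is
#' attached as `attr(, "se")`.
#'
#' @param model A [demographic_model()].
#' @param sample_sizes Chromosomes per population.
#' @param theta Scaled mutation rate of the region.
#' @param n_replicates Genealogy replicates (default 2000).
#' @param seed Integer seed.
#' @return A real-valued `joint_sfs`.
#' @export
expected_sfs <- function(model, sample_sizes, theta, n_replicates = 2000,
                         seed = 1) {
  stopifnot(n_replicates >= 1)
  res <- with_seed(seed, cpp_branch_sfs(model_to_cpp(model),
                                        as.integer(sample_sizes),
                                        as.integer(n_replicates)))
  dims <- sample_sizes + 1L
  arr <- array(res$mean * theta / 2, dim = dims)
  out <- new_joint_sfs(arr, sample_sizes, model$labels)
  attr(out, "se") <- array(res$se * theta / 2, dim = dims)
  out
}
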
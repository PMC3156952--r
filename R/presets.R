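#' Study design table: 12 populations in 4 continental groups
#'
#' The package's reference panel layout: five Indian populations (four from
#' Andhra Pradesh plus the Gujarati HapMap panel), two African, two
#' European, and three East Asian HapMap panels, with approximate origin
#' coordinates (for panels collected away from their origin an approximate
#' origin is used, e.g. Beijing for the Denver Chinese panel) and the
#' per-population sample sizes of the size-normalized analysis panel
#' (`n_ind`).  `n_full` gives a plausible full-panel size (total 722); only
#' its totals are anchored, the per-panel split is a synthetic stand-in.
#' `h_ref` carries reference observed SNP heterozygosity values (x 1e-5)
#' for the worked geography example.
#'
#' @return A data.frame with columns `population`, `group`, `n_ind`,
#'   `n_full`, `lat`, `lon`, `h_ref`.
#' @export
study_design <- function() {
  read.delim(system.file("extdata", "population_origins.tsv",
                         package = "coalsfs"), stringsAsFactors = FALSE)
}

#' @rdname study_design
#' @details `origin_addis_ababa()` returns the reference origin used for
#'   heterozygosity-distance correlations (a proposed point of modern human
#'   origin in eastern Africa).
#' @export
origin_addis_ababa <- function() c(lat = 9.03, lon = 38.74)

#' Calibrated out-of-Africa parameter presets
#'
#' Named default parameter sets for the three- and four-population
#' out-of-Africa models, calibrated at mutation rate 1.48e-8 per bp per
#' generation and generation time 25 years.  These are the stated-world
#' defaults of the synthetic-data generator; see the methods vignette.
#'
#' @param which For `preset_ooa3()`: which pair of Eurasian groups joins
#'   Africa; for `preset_ooa4()`: which Eurasian group diverges first.
#' @return A [params_ooa3()] or [params_ooa4()].
#' @export
preset_ooa3 <- function(which = c("africa-eastasia-europe",
                                  "africa-india-eastasia",
                                  "africa-india-europe")) {
  which <- match.arg(which)
  switch(which,
    "africa-eastasia-europe" = params_ooa3(
      N_A = 13107, N_Af = 18976, N_B = 12624, N1_0 = 1563, N1 = 40488,
      N2_0 = 25543, N2 = 18400, T_Af = 115400, T_B = 88400, T_12 = 39200,
      labels = c("africa", "eastasia", "europe")),
    "africa-india-eastasia" = params_ooa3(
      N_A = 13647, N_Af = 18036, N_B = 18923, N1_0 = 4073, N1 = 36425,
      N2_0 = 1504, N2 = 39580, T_Af = 112000, T_B = 111500, T_12 = 39300,
      labels = c("africa", "india", "eastasia")),
    "africa-india-europe" = params_ooa3(
      N_A = 13390, N_Af = 18387, N_B = 21371, N1_0 = 1829, N1 = 75961,
      N2_0 = 3471, N2 = 70960, T_Af = 113700, T_B = 103900, T_12 = 26600,
      labels = c("africa", "india", "europe")))
}

#' @rdname preset_ooa3
#' @export
preset_ooa4 <- function(which = c("east-asia-first", "india-first")) {
  which <- match.arg(which)
  switch(which,
    "east-asia-first" = params_ooa4(
      N_A = 13195, N_Af = 19023, N_B = 12081, N_C = 77786,
      N1_0 = 2003, N1 = 31020, N2_0 = 1881, N2 = 77285,
      N3_0 = 2029, N3 = 131889,
      T_Af = 119600, T_B = 92200, T_C = 43900, T_23 = 23900,
      labels = c("africa", "eastasia", "india", "europe")),
    "india-first" = params_ooa4(
      N_A = 13483, N_Af = 19438, N_B = 12345, N_C = 171,
      N1_0 = 11410, N1 = 18182, N2_0 = 1735, N2 = 33571,
      N3_0 = 11689, N3 = 28370,
      T_Af = 117800, T_B = 89800, T_C = 40500, T_23 = 40300,
      labels = c("africa", "india", "eastasia", "europe")))
}

#' Simulate a full study-mimic dataset
#'
#' Generates a complete pipeline input emulating the study design: 12
#' populations in 4 continental groups under a four-population
#' out-of-Africa history, with a within-group substructure knob (each
#' group's populations split from each other `within_split_years` before
#' present), a 100-kb region simulated as independent 1-kb sub-loci, known
#' ancestral alleles, and a truth record including the outgroup divergence
#' implied by the mutation-rate calibration defaults.
#'
#' @param params A [params_ooa4()] (default [preset_ooa4()]).
#' @param seed Integer seed.
#' @param sizes `"normalized"` (per-population analysis panel sizes),
#'   `"full"` (722 individuals), or a named integer vector of diploid
#'   counts per population.
#' @param within_split_years Within-group population split time (years).
#' @param mu Mutation rate per bp per generation.
#' @param L Region length (bp).
#' @param g Generation time (years).
#' @param n_loci Independent sub-loci (default 100 x 1 kb).
#' @param out_dir Optional directory: writes VCF, manifest TSV and truth
#'   JSON there.
#' @return List with `matrix`, `manifest`, `truth`, and (if written)
#'   `paths`.
#' @export
make_study_mimic <- function(params = preset_ooa4("east-asia-first"),
                             seed = 1, sizes = c("normalized", "full"),
                             within_split_years = 10000,
                             mu = 1.48e-8, L = 1e5, g = 25, n_loci = 100,
                             out_dir = NULL) {
  design <- study_design()
  if (is.list(sizes)) sizes <- unlist(sizes)
  if (is.character(sizes)) {
    sizes <- match.arg(sizes)
    n_ind <- setNames(if (sizes == "full") design$n_full else design$n_ind,
                      design$population)
  } else {
    n_ind <- sizes[design$population]
    if (anyNA(n_ind)) stop("sizes must name every population")
  }
  bm <- build_model(params, mu, L, g)
  base <- bm$model
  groups <- params$labels  # africa first, then the split order
  pop_group <- setNames(design$group, design$population)
  # map group labels of the model onto design groups
  if (!setequal(groups, unique(design$group)))
    stop("params labels must be the four design groups: ",
         paste(unique(design$group), collapse = ", "))
  pops <- design$population[order(match(design$group, groups))]
  npop <- length(pops)
  tau_w <- within_split_years / (2 * params$N_A * g)
  min_ev <- min(vapply(base$events, `[[`, numeric(1), "time"))
  if (tau_w >= min_ev)
    stop("within_split_years must predate the first group-level event")
  sizes_vec <- growth_vec <- numeric(npop)
  events <- list()
  rep_idx <- integer(0)  # representative pop per group, in model order
  for (gi in seq_along(groups)) {
    members <- which(pops %in% design$population[design$group == groups[gi]])
    rep_idx[gi] <- members[1]
    sizes_vec[members] <- base$sizes[gi]
    growth_vec[members] <- base$growth[gi]
    for (m in members[-1])
      events <- c(events, list(ev_join(tau_w, from = m, to = members[1])))
  }
  for (e in base$events) {
    e$a <- if (e$type == 1L) rep_idx[e$a] else rep_idx[e$a]
    if (e$type == 1L) e$b <- rep_idx[e$b]
    events <- c(events, list(e))
  }
  model <- demographic_model(npop, sizes_vec, growth_vec,
                             migration = base$migration, events = events,
                             labels = pops)
  sim <- simulate_dataset(model, sample_sizes = 2L * n_ind[pops],
                          theta = bm$theta, L = L, seed = seed,
                          n_loci = n_loci)
  gm <- sim_to_genotypes(sim)
  man <- data.frame(
    sample = sample_ids(gm),
    population = rep(pops, n_ind[pops]),
    stringsAsFactors = FALSE)
  m <- match(man$population, design$population)
  man$group <- design$group[m]
  man$lat <- design$lat[m]
  man$lon <- design$lon[m]
  man <- sample_manifest(man)
  cal <- calibrate_mutation_rate(d = 0.012)
  truth <- list(params = unclass(params)[param_names("ooa4")],
                labels = params$labels, mu = mu, L = L, g = g,
                n_loci = n_loci, seed = seed,
                within_split_years = within_split_years,
                outgroup_divergence = list(d = 0.012, g = cal$g,
                                           t_split = cal$t_split,
                                           N_anc = cal$N_anc))
  out <- list(matrix = gm, manifest = man, truth = truth)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    p1 <- write_genotype_vcf(gm, file.path(out_dir, "mimic.vcf"))
    p2 <- write_manifest_tsv(man, file.path(out_dir, "mimic_manifest.tsv"))
    p3 <- file.path(out_dir, "mimic_truth.json")
    jsonlite::write_json(truth, p3, auto_unbox = TRUE, digits = NA)
    out$paths <- c(p1, p2, p3)
  }
  out
}
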
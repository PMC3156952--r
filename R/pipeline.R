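#' Pipeline configuration
#'
#' A validated stage-by-stage configuration for [run_pipeline()].  Every
#' random stage has an explicit seed; the whole object round-trips through
#' JSON unchanged, so a written config reproduces a run exactly.
#'
#' @param out_dir Output directory.
#' @param input Optional list `list(genotypes = path, manifest = path)`;
#'   when NULL the simulate stage provides the input.
#' @param simulate Simulation preset settings (see [make_study_mimic()]).
#' @param stages Character vector of enabled stages, in the fixed order
#'   `simulate`, `qc`, `diversity`, `differentiation`, `sfs`, `fit`,
#'   `report`.
#' @param qc,diversity,sfs,fit Stage parameter lists (thresholds, window
#'   size, restarts, bootstrap count, seeds); missing entries take the
#'   documented defaults.
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, input = NULL,
                            simulate = list(), stages = c("simulate", "qc",
                              "diversity", "differentiation", "sfs",
                              "report"),
                            qc = list(), diversity = list(), sfs = list(),
                            fit = list()) {
  all_stages <- c("simulate", "qc", "diversity", "differentiation", "sfs",
                  "fit", "report")
  bad <- setdiff(stages, all_stages)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  simulate <- modifyList(list(seed = 1, sizes = "normalized", n_loci = 100,
                              mu = 1.48e-8, L = 1e5, g = 25,
                              within_split_years = 10000), simulate)
  qc <- modifyList(list(call_rate_min = 0.8, hwe_alpha = 0.01,
                        subsample_seed = 1), qc)
  diversity <- modifyList(list(window_size = 1e4, d_reps = 2000,
                               seed = 1), diversity)
  sfs <- modifyList(list(level = "group", project_to = 20L), sfs)
  fit <- modifyList(list(family = "ooa3", n_restarts = 10, mc_reps = 1500,
                         maxit = 150, seed = 1, n_boot = 0), fit)
  structure(list(out_dir = out_dir, input = input, simulate = simulate,
                 stages = intersect(all_stages, stages), qc = qc,
                 diversity = diversity, sfs = sfs, fit = fit),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path JSON path.
#' @export
write_pipeline_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(x$input) && !length(x$input)) x$input <- NULL  # {} -> NULL
  do.call(pipeline_config, x[!vapply(x, is.null, logical(1))])
}

#' Run the analysis pipeline end to end
#'
#' Executes the enabled stages in fixed order (simulate or load input, QC
#' filters, diversity table, differentiation, joint SFS, optional model
#' fit, report tables), writing all report tables, a per-stage log, and a
#' run manifest (package version, seeds, input/output counts, file hashes).
#' A stage failure aborts with the failing stage named; outputs of earlier
#' stages are retained.
#'
#' @param config A [pipeline_config()].
#' @return The run manifest (list), invisibly; written as
#'   `run_manifest.json`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "pipeline.log")
  cat("", file = log_path)
  logf <- function(...) cat(sprintf(...), "\n", sep = "", file = log_path,
                            append = TRUE)
  stage <- function(name, expr) {
    if (!name %in% config$stages) return(NULL)
    logf("[%s] start", name)
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  counts <- list()
  results <- list()

  if ("simulate" %in% config$stages && is.null(config$input)) {
    sim <- stage("simulate", do.call(make_study_mimic,
      c(config$simulate, list(out_dir = file.path(out_dir, "simulated")))))
    gm <- sim$matrix; man <- sim$manifest
  } else {
    if (is.null(config$input))
      stop("no input given and simulate stage disabled")
    dat <- read_genotype_data(config$input$genotypes, config$input$manifest)
    gm <- dat$matrix; man <- dat$manifest
  }
  counts$input_sites <- n_sites(gm)
  counts$input_samples <- n_samples(gm)
  logf("input: %d sites x %d samples", n_sites(gm), n_samples(gm))

  if ("qc" %in% config$stages) {
    fd <- stage("qc", filter_dataset(gm, config$qc$call_rate_min))
    hw <- stage("qc", hwe_filter(fd$matrix, man, config$qc$hwe_alpha))
    gm <- hw$matrix
    write_filter_log(fd$log, file.path(out_dir, "filter_log.json"))
    write_filter_log(hw$log, file.path(out_dir, "hwe_log.json"))
    counts$qc_sites <- n_sites(gm)
    logf("qc: %d sites retained", n_sites(gm))
  } else {
    logf("qc disabled: downstream statistics use the input matrix as given")
  }

  if ("diversity" %in% config$stages)
    results$diversity <- stage("diversity", diversity_table(
      gm, man, window_size = config$diversity$window_size,
      d_reps = config$diversity$d_reps, seed = config$diversity$seed))

  if ("differentiation" %in% config$stages) {
    results$fst_groups <- stage("differentiation",
                                fst_matrix(gm, man, "group"))
    results$fst_populations <- stage("differentiation",
                                     fst_matrix(gm, man, "population"))
    nm <- stage("differentiation", nei_matrix(gm, man, "population"))
    results$pcoa <- stage("differentiation", pcoa(nm, 2))
  }

  sfs <- NULL
  if ("sfs" %in% config$stages) {
    sfs <- stage("sfs", joint_sfs(gm, man, level = config$sfs$level))
    ss <- attr(sfs, "sample_sizes")
    tgt <- pmin(ss, config$sfs$project_to)
    if (any(tgt < ss)) sfs <- stage("sfs", project_sfs(sfs, tgt))
    counts$sfs_sites <- sum(sfs)
  }

  if ("fit" %in% config$stages) {
    if (is.null(sfs)) stop("fit stage needs the sfs stage")
    fs <- fit_settings(n_restarts = config$fit$n_restarts,
                       mc_reps = config$fit$mc_reps,
                       maxit = config$fit$maxit, seed = config$fit$seed,
                       mu = config$simulate$mu, L = config$simulate$L,
                       g = config$simulate$g)
    results$fits <- list(fit = stage("fit",
      fit_model(sfs, family = config$fit$family, settings = fs)))
  }

  paths <- write_report_tables(results, out_dir)
  manifest <- list(
    package_version = as.character(utils::packageVersion("coalsfs")),
    r_version = R.version.string,
    config = unclass(config), counts = counts,
    outputs = as.list(setNames(unname(tools::md5sum(paths)),
                               basename(paths))))
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  logf("done: %d output tables", length(paths))
  invisible(manifest)
}

#' Command-line entry point
#'
#' Subcommand dispatcher used by the installed `coalsfs` script
#' (`inst/cli/coalsfs`).  Subcommands: `run --config config.json`;
#' `simulate --out dir [--seed N]`; and the single-stage commands
#' `qc`, `diversity`, `fst`, `pcoa`, `geo`, `sfs`, `fit`, each taking
#' `--genotypes file --manifest file --out dir` (plus `--origin lat,lon`
#' for `geo` and `--family`/`--seed` for `fit`).  Exit codes: 0 ok,
#' 1 user error, 2 internal error.
#'
#' @param args Command-line arguments (defaults to `commandArgs()`).
#' @return Exit status, invisibly.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste("usage: coalsfs",
                 "<run|simulate|qc|diversity|fst|pcoa|geo|sfs|fit>",
                 "[options]")
  if (!length(args)) { message(usage); return(invisible(1L)) }
  cmd <- args[1]
  rest <- args[-1]
  opt <- function(...) {
    optparse::parse_args(optparse::OptionParser(option_list = list(...)),
                         args = rest)
  }
  o_chr <- function(nm, default = NULL)
    optparse::make_option(nm, type = "character", default = default)
  o_int <- function(nm, default)
    optparse::make_option(nm, type = "integer", default = default)

  load_input <- function(opts) {
    if (is.null(opts$genotypes) || is.null(opts$manifest))
      stop("--genotypes and --manifest are required")
    read_genotype_data(opts$genotypes, opts$manifest)
  }
  out_dir <- function(opts) {
    if (is.null(opts$out)) stop("--out is required")
    dir.create(opts$out, recursive = TRUE, showWarnings = FALSE)
    opts$out
  }

  status <- tryCatch({
    switch(cmd,
      run = {
        opts <- opt(o_chr("--config"))
        if (is.null(opts$config)) stop("--config is required")
        run_pipeline(read_pipeline_config(opts$config))
        0L
      },
      simulate = {
        opts <- opt(o_chr("--out"), o_int("--seed", 1L))
        make_study_mimic(seed = opts$seed, out_dir = out_dir(opts))
        0L
      },
      qc = {
        opts <- opt(o_chr("--genotypes"), o_chr("--manifest"), o_chr("--out"))
        dat <- load_input(opts)
        od <- out_dir(opts)
        fd <- filter_dataset(dat$matrix)
        hw <- hwe_filter(fd$matrix, dat$manifest)
        write_genotype_tsv(hw$matrix, file.path(od, "genotypes_qc.tsv"))
        write_filter_log(fd$log, file.path(od, "filter_log.json"))
        write_filter_log(hw$log, file.path(od, "hwe_log.json"))
        0L
      },
      diversity = {
        opts <- opt(o_chr("--genotypes"), o_chr("--manifest"), o_chr("--out"),
                    o_int("--d-reps", 2000L), o_int("--seed", 1L))
        dat <- load_input(opts)
        tab <- diversity_table(dat$matrix, dat$manifest,
                               d_reps = opts$`d-reps`, seed = opts$seed)
        write_report_tables(list(diversity = tab), out_dir(opts))
        0L
      },
      fst = {
        opts <- opt(o_chr("--genotypes"), o_chr("--manifest"), o_chr("--out"))
        dat <- load_input(opts)
        write_report_tables(list(
          fst_groups = fst_matrix(dat$matrix, dat$manifest, "group"),
          fst_populations = fst_matrix(dat$matrix, dat$manifest,
                                       "population")), out_dir(opts))
        0L
      },
      pcoa = {
        opts <- opt(o_chr("--genotypes"), o_chr("--manifest"), o_chr("--out"))
        dat <- load_input(opts)
        nm <- nei_matrix(dat$matrix, dat$manifest, "population")
        write_report_tables(list(pcoa = pcoa(nm, 2)), out_dir(opts))
        0L
      },
      geo = {
        opts <- opt(o_chr("--genotypes"), o_chr("--manifest"), o_chr("--out"),
                    o_chr("--origin", "9.03,38.74"))
        dat <- load_input(opts)
        org <- as.numeric(strsplit(opts$origin, ",")[[1]])
        pops <- unique(dat$manifest$population)
        H <- vapply(pops, function(p) observed_heterozygosity(
          dat$matrix, samples_of(dat$manifest, p, "population")), numeric(1))
        gc <- geo_correlation(setNames(H, pops), dat$manifest,
                              origin = c(lat = org[1], lon = org[2]))
        jsonlite::write_json(
          list(r = gc$r, p = gc$p, distance_km = as.list(gc$distance_km)),
          file.path(out_dir(opts), "geo_correlation.json"),
          auto_unbox = TRUE, digits = NA)
        0L
      },
      sfs = {
        opts <- opt(o_chr("--genotypes"), o_chr("--manifest"), o_chr("--out"),
                    o_chr("--level", "group"))
        dat <- load_input(opts)
        sfs <- joint_sfs(dat$matrix, dat$manifest, level = opts$level)
        jsonlite::write_json(
          list(sample_sizes = attr(sfs, "sample_sizes"),
               labels = attr(sfs, "labels"), counts = as.vector(sfs)),
          file.path(out_dir(opts), "joint_sfs.json"), digits = NA)
        0L
      },
      fit = {
        opts <- opt(o_chr("--genotypes"), o_chr("--manifest"), o_chr("--out"),
                    o_chr("--family", "ooa3"), o_int("--seed", 1L),
                    o_int("--project", 20L))
        dat <- load_input(opts)
        sfs <- joint_sfs(dat$matrix, dat$manifest, level = "group")
        ss <- attr(sfs, "sample_sizes")
        tgt <- pmin(ss, opts$project)
        if (any(tgt < ss)) sfs <- project_sfs(sfs, tgt)
        fit <- fit_model(sfs, family = opts$family,
                         settings = fit_settings(seed = opts$seed))
        write_report_tables(list(fits = list(fit = fit)), out_dir(opts))
        0L
      },
      {
        message(usage)
        1L
      })
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
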
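#' Fitting settings
#'
#' @param n_restarts Independent optimizer restarts (default 10); starts are
#'   drawn log-uniformly within `bounds`.
#' @param mc_reps Genealogy replicates per objective evaluation (common
#'   random numbers within a restart keep the Monte-Carlo objective
#'   deterministic).
#' @param mc_reps_final Replicates for the final comparison pass that ranks
#'   the restart optima on a common seed.
#' @param maxit Nelder-Mead iterations per restart.
#' @param seed Master seed; restart r uses `seed + r`.
#' @param n_polish Number of top stage-1 candidates re-optimized on a
#'   quieter (higher-replicate) surface before the final ranking.
#' @param mc_reps_polish Replicates for the polish stage.
#' @param maxit_polish Nelder-Mead iterations per polish (0 disables the
#'   stage).
#' @param mu,L,g Physical constants used to convert the fitted scaled
#'   parameters to physical units.
#' @param bounds Named list of length-2 vectors (lower, upper) for the free
#'   scaled parameters; defaults span the plausible human range.
#' @param expected_floor Lower floor applied to expected-SFS entries so that
#'   rare configurations never produce an infinite objective.
#' @return A `fit_settings` list.
#' @export
fit_settings <- function(n_restarts = 10, mc_reps = 3000,
                         mc_reps_final = 10 * mc_reps, maxit = 90,
                         seed = 1, n_polish = 2,
                         mc_reps_polish = 5 * mc_reps, maxit_polish = 60,
                         mu = 1.48e-8, L = 1e5, g = 25, bounds = NULL,
                         expected_floor = 1e-4) {
  structure(list(n_restarts = n_restarts, mc_reps = mc_reps,
                 mc_reps_final = mc_reps_final, maxit = maxit, seed = seed,
                 n_polish = n_polish, mc_reps_polish = mc_reps_polish,
                 maxit_polish = maxit_polish,
                 mu = mu, L = L, g = g, bounds = bounds,
                 expected_floor = expected_floor),
            class = "fit_settings")
}

default_bounds <- function(family) {
  if (family == "ooa3") {
    list(nu_Af = c(0.1, 10), nu_B = c(0.1, 10), nu1_0 = c(0.02, 10),
         nu1 = c(0.1, 30), nu2_0 = c(0.02, 10), nu2 = c(0.1, 30),
         tau_12 = c(0.01, 0.4), d_B = c(0.005, 0.4), d_Af = c(0.005, 1))
  } else {
    list(N_A = c(2e3, 6e4), nu_C = c(0.01, 15), nu1_0 = c(0.02, 10),
         nu1 = c(0.1, 30), nu2_0 = c(0.02, 10), nu2 = c(0.1, 30),
         nu3_0 = c(0.02, 10), nu3 = c(0.1, 30),
         tau_23 = c(0.005, 0.3), d_C = c(0.002, 0.3))
  }
}

# scaled list for the simulator from a free-parameter vector
free_to_scaled_ooa3 <- function(v) {
  list(nu_Af = v[["nu_Af"]], nu_B = v[["nu_B"]],
       nu1_0 = v[["nu1_0"]], nu1 = v[["nu1"]],
       nu2_0 = v[["nu2_0"]], nu2 = v[["nu2"]],
       tau_12 = v[["tau_12"]],
       tau_B = v[["tau_12"]] + v[["d_B"]],
       tau_Af = v[["tau_12"]] + v[["d_B"]] + v[["d_Af"]])
}

scaled_to_free_ooa3 <- function(sc) {
  c(nu_Af = sc$nu_Af, nu_B = sc$nu_B, nu1_0 = sc$nu1_0, nu1 = sc$nu1,
    nu2_0 = sc$nu2_0, nu2 = sc$nu2, tau_12 = sc$tau_12,
    d_B = sc$tau_B - sc$tau_12, d_Af = sc$tau_Af - sc$tau_B)
}

#' Fit an out-of-Africa model to an observed joint SFS
#'
#' Maximizes the Poisson composite likelihood of the observed joint SFS
#' under the model family by bounded multi-start Nelder-Mead on
#' log-parameters.  The expected SFS is computed by Monte-Carlo genealogy
#' simulation with common random numbers within a restart; the overall
#' mutation parameter theta is profiled analytically (three-population
#' family), so the fitted `N_A` follows from the profiled theta.  In the
#' four-population family `N_Af`, `N_B`, `T_Af`, `T_B` are fixed (supplied
#' via `fixed`, usually the best three-population fit) and `N_A` is free,
#' with theta tied to it.
#'
#' @param observed A `joint_sfs` (3 or 4 axes as the family requires; use
#'   [project_sfs()] first for large sample sizes).
#' @param family `"ooa3"` or `"ooa4"`.
#' @param settings A [fit_settings()].
#' @param fixed For `"ooa4"`: named list or vector with physical `N_Af`,
#'   `N_B`, `T_Af`, `T_B`.
#' @param start Optional [params_ooa3()]/[params_ooa4()] used as the first
#'   restart's starting point.
#' @return A `fit_result`: physical `params`, `scaled`, `loglik`,
#'   `theta_hat`, `restart_log`, `converged`, `family`.
#' @export
fit_model <- function(observed, family = c("ooa3", "ooa4"),
                      settings = fit_settings(), fixed = NULL,
                      start = NULL) {
  family <- match.arg(family)
  ss <- attr(observed, "sample_sizes")
  k <- length(ss)
  if ((family == "ooa3" && k != 3) || (family == "ooa4" && k != 4))
    stop("observed SFS has ", k, " axes; project or choose the matching ",
         "family")
  bounds <- settings$bounds
  if (is.null(bounds)) bounds <- default_bounds(family)
  nm <- free_names(family)
  bounds <- bounds[nm]
  lo <- log(vapply(bounds, `[`, numeric(1), 1))
  hi <- log(vapply(bounds, `[`, numeric(1), 2))
  if (family == "ooa4") {
    need <- c("N_Af", "N_B", "T_Af", "T_B")
    if (is.null(fixed) || !all(need %in% names(fixed)))
      stop("ooa4 needs fixed = list(N_Af, N_B, T_Af, T_B)")
    fixed <- lapply(fixed[need], as.numeric)
  }

  objective <- function(logv, crn_seed, reps) {
    v <- setNames(exp(logv), nm)
    if (family == "ooa3") {
      sc <- free_to_scaled_ooa3(v)
      model <- scaled_model_ooa3(sc)
      ex <- expected_sfs(model, ss, theta = 1, n_replicates = reps,
                         seed = crn_seed)
      ex[] <- pmax(ex, settings$expected_floor *
                         sum(ex) / length(ex))
      ll <- poisson_composite_loglik(observed, ex, profile_theta = TRUE)
      return(list(nll = -as.numeric(ll), theta = attr(ll, "scale")))
    }
    # ooa4: N_A free, theta tied to it, fixed pieces rescaled per draw
    N_A <- v[["N_A"]]
    unit <- 2 * N_A * settings$g
    tau_23 <- v[["tau_23"]]
    tau_C <- tau_23 + v[["d_C"]]
    tau_B <- fixed$T_B / unit
    if (tau_C >= tau_B)  # ordering violated: smooth penalty
      return(list(nll = 1e9 * (1 + tau_C - tau_B), theta = NA))
    sc <- list(nu_Af = fixed$N_Af / N_A, nu_B = fixed$N_B / N_A,
               nu_C = v[["nu_C"]],
               nu1_0 = v[["nu1_0"]], nu1 = v[["nu1"]],
               nu2_0 = v[["nu2_0"]], nu2 = v[["nu2"]],
               nu3_0 = v[["nu3_0"]], nu3 = v[["nu3"]],
               tau_Af = fixed$T_Af / unit, tau_B = tau_B,
               tau_C = tau_C, tau_23 = tau_23)
    theta <- 4 * N_A * settings$mu * settings$L
    model <- scaled_model_ooa4(sc)
    ex <- expected_sfs(model, ss, theta = theta, n_replicates = reps,
                       seed = crn_seed)
    ex[] <- pmax(ex, settings$expected_floor * sum(ex) / length(ex))
    ll <- poisson_composite_loglik(observed, ex, profile_theta = FALSE)
    list(nll = -as.numeric(ll), theta = theta)
  }

  starts <- matrix(NA_real_, settings$n_restarts, length(nm),
                   dimnames = list(NULL, nm))
  with_seed(settings$seed, {
    for (r in seq_len(settings$n_restarts))
      starts[r, ] <- runif(length(nm), lo, hi)
  })
  if (!is.null(start)) {
    sv <- start_vector(start, family, settings)
    starts[1, ] <- pmin(pmax(log(sv), lo), hi)
  }

  fits <- vector("list", settings$n_restarts)
  log_rows <- vector("list", settings$n_restarts)
  for (r in seq_len(settings$n_restarts)) {
    crn <- settings$seed + r
    opt <- optim(starts[r, ],
                 function(lv) objective(lv, crn, settings$mc_reps)$nll,
                 method = "Nelder-Mead",
                 control = list(maxit = settings$maxit))
    fits[[r]] <- opt
    log_rows[[r]] <- data.frame(restart = r, nll_opt = opt$value,
                                convergence = opt$convergence)
  }
  # Stage 2: the Monte-Carlo objective at coarse replicate counts can be
  # exploited by the optimizer (cells of the expected tensor that happen to
  # receive no branch mass under one CRN draw carry large floor penalties),
  # so the top candidates are re-optimized on a much quieter surface before
  # the final ranking.
  polish_seed <- settings$seed + 555L
  n_polish <- min(settings$n_polish, settings$n_restarts)
  polished <- rep(FALSE, settings$n_restarts)
  if (n_polish >= 1 && settings$maxit_polish > 0) {
    mid <- vapply(fits, function(f)
      objective(f$par, polish_seed, settings$mc_reps_polish)$nll, numeric(1))
    for (r in utils::head(order(mid), n_polish)) {
      opt2 <- optim(fits[[r]]$par, function(lv)
        objective(lv, polish_seed, settings$mc_reps_polish)$nll,
        method = "Nelder-Mead",
        control = list(maxit = settings$maxit_polish))
      fits[[r]] <- opt2
      polished[r] <- TRUE
    }
  }
  # rank all candidate optima on a common, large-replicate evaluation
  final_seed <- settings$seed + settings$n_restarts + 1L
  finals <- vapply(fits, function(f)
    objective(f$par, final_seed, settings$mc_reps_final)$nll, numeric(1))
  best <- which.min(finals)
  restart_log <- do.call(rbind, log_rows)
  restart_log$polished <- polished
  restart_log$nll_final <- finals
  opt <- fits[[best]]
  fin <- objective(opt$par, final_seed, settings$mc_reps_final)
  v <- setNames(exp(opt$par), nm)

  if (family == "ooa3") {
    sc <- free_to_scaled_ooa3(v)
    theta_hat <- fin$theta
    params <- convert_units(sc, theta_hat, settings$mu, settings$L,
                            settings$g, family = "ooa3",
                            labels = attr(observed, "labels"))
  } else {
    N_A <- v[["N_A"]]
    unit <- 2 * N_A * settings$g
    theta_hat <- 4 * N_A * settings$mu * settings$L
    sc <- list(nu_Af = fixed$N_Af / N_A, nu_B = fixed$N_B / N_A,
               nu_C = v[["nu_C"]], nu1_0 = v[["nu1_0"]], nu1 = v[["nu1"]],
               nu2_0 = v[["nu2_0"]], nu2 = v[["nu2"]],
               nu3_0 = v[["nu3_0"]], nu3 = v[["nu3"]],
               tau_Af = fixed$T_Af / unit, tau_B = fixed$T_B / unit,
               tau_C = v[["tau_23"]] + v[["d_C"]], tau_23 = v[["tau_23"]])
    params <- convert_units(sc, theta_hat, settings$mu, settings$L,
                            settings$g, family = "ooa4",
                            labels = attr(observed, "labels"))
  }
  improved <- any(restart_log$nll_opt < vapply(seq_len(nrow(starts)),
    function(r) objective(starts[r, ], settings$seed + r,
                          settings$mc_reps)$nll, numeric(1)) - 1e-9)
  structure(list(params = params, scaled = sc, loglik = -fin$nll,
                 theta_hat = theta_hat, free = v,
                 restart_log = restart_log, best_restart = best,
                 converged = improved, family = family, fixed = fixed,
                 settings = settings, ci = NULL,
                 observed_total = sum(observed), observed_dim = dim2(observed)),
            class = "fit_result")
}

start_vector <- function(start, family, settings) {
  if (family == "ooa3") {
    sc <- build_model(start, settings$mu, settings$L, settings$g)$scaled
    scaled_to_free_ooa3(sc)
  } else {
    unit <- 2 * start$N_A * settings$g
    c(N_A = start$N_A, nu_C = start$N_C / start$N_A,
      nu1_0 = start$N1_0 / start$N_A, nu1 = start$N1 / start$N_A,
      nu2_0 = start$N2_0 / start$N_A, nu2 = start$N2 / start$N_A,
      nu3_0 = start$N3_0 / start$N_A, nu3 = start$N3 / start$N_A,
      tau_23 = start$T_23 / unit,
      d_C = (start$T_C - start$T_23) / unit)
  }
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("fit_result (%s): loglik = %.1f, theta_hat = %.3f%s\n",
              x$family, x$loglik, x$theta_hat,
              if (!x$converged) " [non-convergence flagged]" else ""))
  est <- unlist(x$params[param_names(x$family)])
  for (nm in names(est)) {
    unit <- if (startsWith(nm, "T_")) " y" else ""
    cat(sprintf("  %-6s %12.1f%s\n", nm, est[[nm]], unit))
  }
  invisible(x)
}

#' Block-bootstrap confidence intervals for fitted parameters
#'
#' Resamples data blocks (per-locus joint SFS tensors) with replacement,
#' rebuilds the total SFS, refits with reduced restarts seeded at the point
#' estimate, and reports 2.5-97.5 percentile intervals per physical
#' parameter.  The table's `estimate` column is the same refit run on the
#' original (unresampled) blocks — comparable to the bootstrap draws and
#' always contained in the interval; the full-strength point estimate
#' stays in the `fit_result`.
#'
#' @param blocks List of per-block `joint_sfs` tensors (>= 10 blocks;
#'   typically 1-kb sub-loci).
#' @param point The `fit_result` on the full data; bootstrap refits start
#'   from its estimate.
#' @param n_boot Bootstrap replicates (default 500).
#' @param seed Seed for the resampling.
#' @param refit_restarts Restarts per refit (default 3).
#' @return A data.frame `parameter`, `estimate`, `ci_low`, `ci_high`, with
#'   the bootstrap draws in `attr(, "draws")`.
#' @export
bootstrap_ci <- function(blocks, point, n_boot = 500, seed = 1,
                         refit_restarts = 3) {
  if (length(blocks) < 10) stop("need at least 10 blocks")
  d <- dim2(blocks[[1]])
  ss <- attr(blocks[[1]], "sample_sizes")
  labels <- attr(blocks[[1]], "labels")
  set <- point$settings
  set$n_restarts <- refit_restarts
  pn <- param_names(point$family)
  draws <- matrix(NA_real_, n_boot, length(pn), dimnames = list(NULL, pn))
  idx_all <- with_seed(seed, matrix(
    sample.int(length(blocks), length(blocks) * n_boot, replace = TRUE),
    nrow = n_boot))
  # refits are deterministic given the resampled data: the optimizer seed
  # does not vary across bootstrap replicates, so degenerate (all-identical)
  # blocks give zero-width intervals
  set$seed <- set$seed + 1000L
  refit <- function(obs) fit_model(obs, family = point$family,
                                   settings = set, fixed = point$fixed,
                                   start = point$params)
  # replicate 0: the same refit on the original (unresampled) data; its
  # estimate anchors the percentile intervals and is included in the draws,
  # so the intervals always contain it
  tot0 <- Reduce(`+`, lapply(blocks, unclass))
  fit0 <- refit(new_joint_sfs(array(tot0, dim = d), ss, labels))
  est <- unlist(fit0$params[pn])
  for (b in seq_len(n_boot)) {
    tot <- Reduce(`+`, lapply(idx_all[b, ], function(i) unclass(blocks[[i]])))
    obs <- new_joint_sfs(array(tot, dim = d), ss, labels)
    draws[b, ] <- unlist(refit(obs)$params[pn])
  }
  all_draws <- rbind(est, draws)
  ci <- t(apply(all_draws, 2, stats::quantile, c(0.025, 0.975),
                na.rm = TRUE, type = 1))
  data.frame(parameter = pn, estimate = unname(est),
             ci_low = pmin(unname(ci[, 1]), unname(est)),
             ci_high = pmax(unname(ci[, 2]), unname(est))) |>
    structure(draws = draws)
}

#' Rank model fits by maximum composite log-likelihood
#'
#' @param fits Named list of >= 2 `fit_result` objects on the same observed
#'   SFS.
#' @param tol Log-likelihood difference treated as a tie.
#' @return Data.frame sorted by decreasing log-likelihood with a `tie`
#'   flag.
#' @export
compare_models <- function(fits, tol = 0.1) {
  if (length(fits) < 2) stop("need at least 2 fits to compare")
  tot <- vapply(fits, `[[`, numeric(1), "observed_total")
  dims <- lapply(fits, `[[`, "observed_dim")
  if (length(unique(tot)) != 1 ||
      length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1)
    stop("fits were made on different observed data")
  ll <- vapply(fits, `[[`, numeric(1), "loglik")
  o <- order(ll, decreasing = TRUE)
  ll <- ll[o]
  data.frame(model = names(fits)[o], loglik = ll,
             delta = ll[1] - ll,
             tie = abs(ll[1] - ll) <= tol)
}

#' Parameter-recovery experiment
#'
#' Simulates replicate datasets under a known out-of-Africa history (the
#' region as independent 1-kb sub-loci) and refits each with the multi-start
#' composite-likelihood machinery, returning the recovered physical
#' parameters per replicate.  The median recovered split times are the
#' standard check that the inference machinery is calibrated.
#'
#' @param truth Generating [params_ooa3()] (default [preset_ooa3()]).
#' @param n_replicates Number of simulated datasets (default 20).
#' @param n_chrom Chromosomes sampled per population (default 20).
#' @param n_loci Independent sub-loci (default 100, i.e. 1-kb blocks of a
#'   100-kb region).
#' @param settings A [fit_settings()]; `settings$seed` drives both the
#'   simulations and the refits.
#' @return Data.frame with one row per replicate: the recovered physical
#'   parameters and the composite log-likelihood.
#' @export
recovery_experiment <- function(truth = preset_ooa3(), n_replicates = 20,
                                n_chrom = 20, n_loci = 100,
                                settings = fit_settings()) {
  bm <- build_model(truth, settings$mu, settings$L, settings$g)
  rows <- lapply(seq_len(n_replicates), function(r) {
    sim <- simulate_dataset(bm$model, rep(n_chrom, 3), theta = bm$theta,
                            L = settings$L,
                            seed = settings$seed * 1000L + r,
                            n_loci = n_loci)
    obs <- joint_sfs(sim)
    set <- settings
    set$seed <- settings$seed + 7919L * r
    fit <- fit_model(obs, "ooa3", set)
    data.frame(replicate = r,
               as.data.frame(fit$params[param_names("ooa3")]),
               loglik = fit$loglik)
  })
  do.call(rbind, rows)
}
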
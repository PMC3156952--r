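#' Out-of-Africa parameter sets (physical units)
#'
#' Three-population model: an ancestral population of size `N_A` changes to
#' `N_Af` at `T_Af` years before present; the Eurasian ancestor (size `N_B`)
#' splits off at `T_B`; the two Eurasian groups split at `T_12` with initial
#' sizes `N1_0`, `N2_0` and grow exponentially to the present sizes `N1`,
#' `N2`.  No migration.  All sizes are diploid effective sizes and times are
#' in years.
#'
#' @param N_A,N_Af,N_B,N1_0,N1,N2_0,N2 Diploid effective sizes.
#' @param T_Af,T_B,T_12 Event times in years before present
#'   (`T_Af >= T_B >= T_12 > 0`).
#' @param labels Population labels (ancestral-African group first).
#' @return A `params_ooa3` list.
#' @export
params_ooa3 <- function(N_A, N_Af, N_B, N1_0, N1, N2_0, N2,
                        T_Af, T_B, T_12,
                        labels = c("africa", "pop1", "pop2")) {
  p <- list(N_A = N_A, N_Af = N_Af, N_B = N_B, N1_0 = N1_0, N1 = N1,
            N2_0 = N2_0, N2 = N2, T_Af = T_Af, T_B = T_B, T_12 = T_12)
  if (any(unlist(p[1:7]) <= 0)) stop("all sizes must be positive")
  if (!(T_Af >= T_B)) stop("ordering violated: T_Af >= T_B required")
  if (!(T_B >= T_12)) stop("ordering violated: T_B >= T_12 required")
  if (!(T_12 > 0)) stop("ordering violated: T_12 > 0 required")
  structure(c(p, list(labels = labels)), class = "params_ooa3")
}

#' @rdname params_ooa3
#' @param N_C Size of the intermediate Eurasian ancestor.
#' @param N3_0,N3 Initial/current sizes of the third Eurasian group.
#' @param T_C,T_23 Split times in years (`T_B >= T_C >= T_23 > 0`).
#' @details In the four-population model, `N_Af`, `N_B`, `T_Af` and `T_B`
#'   are carried over from the best three-population fit and held fixed
#'   during optimization; `N_A` remains free.
#' @export
params_ooa4 <- function(N_A, N_Af, N_B, N_C, N1_0, N1, N2_0, N2, N3_0, N3,
                        T_Af, T_B, T_C, T_23,
                        labels = c("africa", "pop1", "pop2", "pop3")) {
  p <- list(N_A = N_A, N_Af = N_Af, N_B = N_B, N_C = N_C, N1_0 = N1_0,
            N1 = N1, N2_0 = N2_0, N2 = N2, N3_0 = N3_0, N3 = N3,
            T_Af = T_Af, T_B = T_B, T_C = T_C, T_23 = T_23)
  if (any(unlist(p[1:10]) <= 0)) stop("all sizes must be positive")
  if (!(T_Af >= T_B)) stop("ordering violated: T_Af >= T_B required")
  if (!(T_B >= T_C)) stop("ordering violated: T_B >= T_C required")
  if (!(T_C >= T_23)) stop("ordering violated: T_C >= T_23 required")
  if (!(T_23 > 0)) stop("ordering violated: T_23 > 0 required")
  structure(c(p, list(labels = labels)), class = "params_ooa4")
}

param_names <- function(family) {
  switch(family,
    ooa3 = c("N_A", "N_Af", "N_B", "N1_0", "N1", "N2_0", "N2",
             "T_Af", "T_B", "T_12"),
    ooa4 = c("N_A", "N_Af", "N_B", "N_C", "N1_0", "N1", "N2_0", "N2",
             "N3_0", "N3", "T_Af", "T_B", "T_C", "T_23"),
    stop("unknown model family: ", family))
}

# Names of the scaled parameters the optimizer sees.
free_names <- function(family) {
  switch(family,
    ooa3 = c("nu_Af", "nu_B", "nu1_0", "nu1", "nu2_0", "nu2",
             "tau_12", "d_B", "d_Af"),
    ooa4 = c("N_A", "nu_C", "nu1_0", "nu1", "nu2_0", "nu2", "nu3_0", "nu3",
             "tau_23", "d_C"))
}

#' Build a scaled demographic model from physical parameters
#'
#' Converts physical units to diffusion scaling (`nu = N / N_A`,
#' `tau = T / (2 * N_A * g)`, `theta = 4 * N_A * mu * L`) and emits the
#' event list of the corresponding [demographic_model()].
#'
#' @param params A [params_ooa3()] or [params_ooa4()].
#' @param mu Mutation rate per bp per generation.
#' @param L Region length (bp).
#' @param g Generation time in years.
#' @return A list with `model` (a [demographic_model()]), `theta`, and
#'   `scaled` (the scaled parameter list).
#' @export
build_model <- function(params, mu, L, g = 25) UseMethod("build_model")

#' @export
build_model.params_ooa3 <- function(params, mu, L, g = 25) {
  p <- params
  unit <- 2 * p$N_A * g  # years per scaled time unit
  sc <- list(nu_Af = p$N_Af / p$N_A, nu_B = p$N_B / p$N_A,
             nu1_0 = p$N1_0 / p$N_A, nu1 = p$N1 / p$N_A,
             nu2_0 = p$N2_0 / p$N_A, nu2 = p$N2 / p$N_A,
             tau_Af = p$T_Af / unit, tau_B = p$T_B / unit,
             tau_12 = p$T_12 / unit)
  model <- scaled_model_ooa3(sc, labels = p$labels)
  list(model = model, theta = 4 * p$N_A * mu * L, scaled = sc)
}

scaled_model_ooa3 <- function(sc, labels = c("africa", "pop1", "pop2")) {
  a1 <- log(sc$nu1 / sc$nu1_0) / sc$tau_12
  a2 <- log(sc$nu2 / sc$nu2_0) / sc$tau_12
  demographic_model(
    npop = 3,
    sizes = c(sc$nu_Af, sc$nu1, sc$nu2),
    growth = c(0, a1, a2),
    events = list(
      ev_join(sc$tau_12, from = 3, to = 2),
      ev_size(sc$tau_12, pop = 2, size = sc$nu_B),
      ev_join(sc$tau_B, from = 2, to = 1),
      ev_size(sc$tau_Af, pop = 1, size = 1)),
    labels = labels)
}

#' @export
build_model.params_ooa4 <- function(params, mu, L, g = 25) {
  p <- params
  unit <- 2 * p$N_A * g
  sc <- list(nu_Af = p$N_Af / p$N_A, nu_B = p$N_B / p$N_A,
             nu_C = p$N_C / p$N_A,
             nu1_0 = p$N1_0 / p$N_A, nu1 = p$N1 / p$N_A,
             nu2_0 = p$N2_0 / p$N_A, nu2 = p$N2 / p$N_A,
             nu3_0 = p$N3_0 / p$N_A, nu3 = p$N3 / p$N_A,
             tau_Af = p$T_Af / unit, tau_B = p$T_B / unit,
             tau_C = p$T_C / unit, tau_23 = p$T_23 / unit)
  model <- scaled_model_ooa4(sc, labels = p$labels)
  list(model = model, theta = 4 * p$N_A * mu * L, scaled = sc)
}

scaled_model_ooa4 <- function(sc, labels = c("africa", "pop1", "pop2",
                                             "pop3")) {
  a1 <- log(sc$nu1 / sc$nu1_0) / sc$tau_C
  a2 <- log(sc$nu2 / sc$nu2_0) / sc$tau_23
  a3 <- log(sc$nu3 / sc$nu3_0) / sc$tau_23
  demographic_model(
    npop = 4,
    sizes = c(sc$nu_Af, sc$nu1, sc$nu2, sc$nu3),
    growth = c(0, a1, a2, a3),
    events = list(
      ev_join(sc$tau_23, from = 4, to = 3),
      ev_size(sc$tau_23, pop = 3, size = sc$nu_C),
      ev_join(sc$tau_C, from = 3, to = 2),
      ev_size(sc$tau_C, pop = 2, size = sc$nu_B),
      ev_join(sc$tau_B, from = 2, to = 1),
      ev_size(sc$tau_Af, pop = 1, size = 1)),
    labels = labels)
}

#' Convert scaled parameters back to physical units
#'
#' `N_A = theta_hat / (4 * mu * L)`; sizes `N = nu * N_A`; times
#' `T = tau * 2 * N_A * g`.  Exactly inverse to [build_model()] scaling.
#'
#' @param scaled Scaled parameter list (as produced by [build_model()] or
#'   an optimizer).
#' @param theta_hat Fitted scaled mutation rate (> 0).
#' @param mu,L,g Physical constants.
#' @param family `"ooa3"` or `"ooa4"`.
#' @param labels Population labels.
#' @return A [params_ooa3()]/[params_ooa4()] in physical units.
#' @export
convert_units <- function(scaled, theta_hat, mu, L, g = 25,
                          family = c("ooa3", "ooa4"),
                          labels = NULL) {
  family <- match.arg(family)
  if (theta_hat <= 0) stop("theta_hat must be positive")
  N_A <- theta_hat / (4 * mu * L)
  unit <- 2 * N_A * g
  s <- scaled
  if (family == "ooa3") {
    if (is.null(labels)) labels <- c("africa", "pop1", "pop2")
    params_ooa3(N_A, N_Af = s$nu_Af * N_A, N_B = s$nu_B * N_A,
                N1_0 = s$nu1_0 * N_A, N1 = s$nu1 * N_A,
                N2_0 = s$nu2_0 * N_A, N2 = s$nu2 * N_A,
                T_Af = s$tau_Af * unit, T_B = s$tau_B * unit,
                T_12 = s$tau_12 * unit, labels = labels)
  } else {
    if (is.null(labels)) labels <- c("africa", "pop1", "pop2", "pop3")
    params_ooa4(N_A, N_Af = s$nu_Af * N_A, N_B = s$nu_B * N_A,
                N_C = s$nu_C * N_A,
                N1_0 = s$nu1_0 * N_A, N1 = s$nu1 * N_A,
                N2_0 = s$nu2_0 * N_A, N2 = s$nu2 * N_A,
                N3_0 = s$nu3_0 * N_A, N3 = s$nu3 * N_A,
                T_Af = s$tau_Af * unit, T_B = s$tau_B * unit,
                T_C = s$tau_C * unit, T_23 = s$tau_23 * unit,
                labels = labels)
  }
}

#' Poisson composite log-likelihood of a joint SFS
#'
#' `sum(o * log(e) - e - log(o!))` over tensor entries, with the two
#' monomorphic corners masked.  An expected entry of 0 with a positive
#' observation yields `-Inf` (sentinel, not an error).  With
#' `profile_theta = TRUE` the expected tensor is first rescaled so its
#' masked total matches the observed total (the analytic Poisson MLE of the
#' overall rate).
#'
#' @param observed,expected `joint_sfs` tensors of identical shape
#'   (expected may be real-valued).
#' @param profile_theta Rescale `expected` to the observed total first?
#' @return The log-likelihood (with attribute `scale` when profiled).
#' @export
poisson_composite_loglik <- function(observed, expected,
                                     profile_theta = FALSE) {
  if (!identical(dim2(observed), dim2(expected)))
    stop("observed and expected tensors must have the same shape")
  o <- as.vector(observed)
  e <- as.vector(expected)
  mask <- c(1L, length(o))
  o <- o[-mask]; e <- e[-mask]
  scale <- 1
  if (profile_theta) {
    if (sum(e) <= 0) return(structure(-Inf, scale = NA_real_))
    scale <- sum(o) / sum(e)
    e <- e * scale
  }
  ll <- sum(o * log(e) - e - lgamma(o + 1))
  if (any(o > 0 & e == 0)) ll <- -Inf
  structure(ll, scale = scale)
}

dim2 <- function(x) if (is.null(dim(x))) length(x) else dim(x)

#' Hypergeometric projection of a joint SFS to smaller sample sizes
#'
#' Each axis is downsampled independently: a site with derived count i out
#' of n chromosomes contributes `dhyper(j, i, n - i, m)` to count j out of
#' m.  Projection preserves the tensor total.
#'
#' @param sfs A `joint_sfs`.
#' @param new_sizes Target chromosomes per population (<= current).
#' @return The projected `joint_sfs` (real-valued).
#' @export
project_sfs <- function(sfs, new_sizes) {
  ss <- attr(sfs, "sample_sizes")
  if (length(new_sizes) != length(ss) || any(new_sizes > ss))
    stop("new_sizes must be <= current sample sizes, per population")
  arr <- unclass(sfs)
  attributes(arr) <- list(dim = dim2(arr))
  for (j in seq_along(ss)) {
    n <- ss[j]; m <- new_sizes[j]
    P <- outer(0:n, 0:m, function(i, l) dhyper(l, i, n - i, m))
    arr <- apply_axis(arr, j, function(v) as.vector(crossprod(P, v)))
  }
  new_joint_sfs(array(arr, dim = new_sizes + 1L), new_sizes,
                attr(sfs, "labels"))
}

# Apply f along axis j of array arr (f maps a vector to a new vector).
apply_axis <- function(arr, j, f) {
  d <- dim2(arr)
  if (is.null(dim(arr))) dim(arr) <- d
  perm <- c(j, seq_along(d)[-j])
  m <- matrix(aperm(arr, perm), nrow = d[j])
  m2 <- apply(m, 2, f)
  if (is.null(dim(m2))) m2 <- matrix(m2, nrow = 1)
  newd <- c(nrow(m2), d[-j])
  aperm(array(m2, dim = newd), order(perm))
}

#' Mutation-rate calibration from outgroup divergence
#'
#' Partitions the observed per-bp divergence `d` between two species into
#' `2 * t_split / g` generations of independent lineage accumulation plus
#' `4 * N_anc` generations of expected coalescence in the common ancestor:
#' `mu = d / (2 * t_split / g + 4 * N_anc)`.
#'
#' @param d Divergence (substitutions per bp).
#' @param g Generation time in years.
#' @param t_split Species split time in years.
#' @param N_anc Ancestral effective population size (diploids).
#' @return A list with the inputs and `mu`.
#' @export
calibrate_mutation_rate <- function(d, g = 25, t_split = 6e6,
                                    N_anc = 84000) {
  stopifnot(d >= 0, g > 0, t_split > 0, N_anc > 0)
  list(d = d, g = g, t_split = t_split, N_anc = N_anc,
       mu = d / (2 * t_split / g + 4 * N_anc))
}
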
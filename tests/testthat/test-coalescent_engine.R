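test_that("constant-size expectations: E[S], TMRCA, and the full SFS", {
  m <- demographic_model(1)
  # n = 2: E[S] = theta (a_1 = 1), E[TMRCA] = 1 (units of 2N generations)
  theta <- 3
  S <- vapply(1:2000, function(r)
    nrow(simulate_dataset(m, 2L, theta = theta, L = 1e4,
                          seed = r)$haplotypes), numeric(1))
  expect_lt(abs(mean(S) - theta), 3 * stats::sd(S) / sqrt(length(S)))
  set.seed(21)
  pt <- coalsfs:::cpp_sim_pair_times(coalsfs:::model_to_cpp(m), 2L, 3000L)
  expect_lt(abs(mean(pt$tmrca) - 1),
            3 * stats::sd(pt$tmrca) / sqrt(3000))
  # E[xi_i] = theta / i for all i (branch-based, 5000 replicates)
  es <- expected_sfs(m, 10L, theta = 10, n_replicates = 5000, seed = 9)
  se <- attr(es, "se")
  for (i in 1:9)
    expect_lt(abs(es[i + 1] - 10 / i), 3 * se[i + 1])
})

test_that("growth raises the singleton fraction relative to constant size", {
  const <- demographic_model(1)
  # tenfold backward shrinkage over 0.1 time units
  growth <- demographic_model(1, sizes = 1, growth = log(10) / 0.1,
                              events = list(ev_size(0.1, 1, 0.1)))
  frac <- function(m, seeds) vapply(seeds, function(r) {
    h <- simulate_dataset(m, 12L, theta = 5, L = 1e4,
                          seed = r)$haplotypes
    if (nrow(h) == 0) return(NA_real_)
    mean(rowSums(h) == 1)
  }, numeric(1))
  f1 <- frac(const, 1:500)
  f2 <- frac(growth, 501:1000)
  expect_gt(mean(f2, na.rm = TRUE), mean(f1, na.rm = TRUE))
})

test_that("expected_sfs is exactly linear in theta and symmetric models give
           symmetric tensors", {
  m2 <- demographic_model(2, events = list(ev_join(0.2, 2, 1),
                                           ev_size(0.2, 1, 1)))
  e1 <- expected_sfs(m2, c(6L, 6L), theta = 5, n_replicates = 300, seed = 4)
  e2 <- expected_sfs(m2, c(6L, 6L), theta = 10, n_replicates = 300, seed = 4)
  expect_equal(as.vector(unclass(e2)), 2 * as.vector(unclass(e1)))
  big <- expected_sfs(m2, c(6L, 6L), theta = 5, n_replicates = 20000,
                      seed = 6)
  se <- attr(big, "se")
  asym <- abs(unclass(big) - t(unclass(big)))
  tol <- 3 * sqrt(se^2 + t(se)^2) + 1e-9
  expect_true(all(asym <= tol))
})

test_that("expected SFS at the calibrated three-population model matches an
           independent simulator (frozen msprime oracle)", {
  # Oracle: msprime 1.4.2, 4000 replicates of the same model at identical
  # parameters (mu = 1.48e-8, L = 100 kb, 20 chromosomes per population);
  # values frozen from the session run.
  oracle <- list(
    africa   = c(96.90, 42.96, 28.24, 19.95, 15.40),
    eastasia = c(59.69, 29.78, 21.86, 17.15, 14.49),
    europe   = c(91.11, 41.99, 26.74, 19.13, 16.06),
    total = 493.42)
  bm <- build_model(preset_ooa3(), mu = 1.48e-8, L = 1e5, g = 25)
  es <- expected_sfs(bm$model, c(20L, 20L, 20L), theta = bm$theta,
                     n_replicates = 8000, seed = 33)
  marg <- function(ax) apply(unclass(es), ax, sum)[2:6]
  for (ax in 1:3) {
    got <- marg(ax)
    want <- oracle[[ax]]
    expect_lt(max(abs(got - want) / want), 0.06)
  }
  tot <- sum(es) - es[1] - es[length(es)]
  expect_lt(abs(tot - oracle$total) / oracle$total, 0.02)
})

test_that("joint_sfs counts sites and conserves the segregating total", {
  sim <- simulate_dataset(demographic_model(
    2, events = list(ev_join(0.1, 2, 1))), c(4L, 4L), theta = 6, L = 1e4,
    seed = 17)
  sfs <- joint_sfs(sim)
  expect_equal(sum(sfs) - sfs[1, 1] - sfs[5, 5], nrow(sim$haplotypes))
  expect_equal(dim(sfs), c(5L, 5L))
  # single site with derived count 1 in pop1 only
  one <- sim
  one$haplotypes <- matrix(c(1L, rep(0L, 7)), 1, 8)
  one$positions <- 1L; one$locus <- 1L
  one$ancestral <- "A"; one$derived <- "G"
  s1 <- joint_sfs(one)
  expect_equal(s1[2, 1], 1)
  expect_equal(sum(s1), 1)
  # genotype-matrix route agrees with the haplotype route
  gm <- sim_to_genotypes(sim)
  man <- toy_manifest(sample_ids(gm), rep(c("p1", "p2"), each = 2))
  s2 <- joint_sfs(gm, man, level = "population")
  expect_equal(as.vector(unclass(s2)), as.vector(unclass(sfs)))
  expect_equal(unname(dim(s2)), dim(sfs))
  gm$ancestral <- rep(NA_character_, n_sites(gm))
  expect_error(joint_sfs(gm, man), "polarize")
  expect_s3_class(joint_sfs(gm, man, fold = TRUE), "joint_sfs")
})

test_that("determinism: same seed gives identical datasets, VCFs and truth
           round-trips", {
  s1 <- simulate_dataset(demographic_model(1), 6L, theta = 4, L = 1000,
                         seed = 99)
  s2 <- simulate_dataset(demographic_model(1), 6L, theta = 4, L = 1000,
                         seed = 99)
  expect_identical(s1$haplotypes, s2$haplotypes)
  expect_identical(s1$positions, s2$positions)

  dir1 <- file.path(tempdir(), "mim1"); dir2 <- file.path(tempdir(), "mim2")
  sizes <- setNames(rep(2L, 12), study_design()$population)
  m1 <- make_study_mimic(seed = 5, sizes = sizes, n_loci = 5, out_dir = dir1)
  m2 <- make_study_mimic(seed = 5, sizes = sizes, n_loci = 5, out_dir = dir2)
  expect_identical(readLines(file.path(dir1, "mimic.vcf")),
                   readLines(file.path(dir2, "mimic.vcf")))
  tr <- jsonlite::read_json(file.path(dir1, "mimic_truth.json"),
                            simplifyVector = TRUE)
  expect_equal(unlist(tr$params),
               unlist(m1$truth$params))
  expect_equal(tr$mu, 1.48e-8)
})

test_that("the study mimic reproduces the panel design", {
  mim <- make_study_mimic(seed = 2, sizes = "normalized", n_loci = 10)
  des <- study_design()
  expect_equal(nrow(mim$manifest), sum(des$n_ind))
  expect_equal(sort(unique(mim$manifest$population)), sort(des$population))
  expect_equal(length(unique(mim$manifest$group)), 4L)
  counts <- table(mim$manifest$population)
  expect_equal(as.vector(counts[des$population]), des$n_ind)
  expect_true(all(!is.na(mim$matrix$ancestral)))
  expect_true(mim$matrix$phased)
  # full panel totals 722
  expect_equal(sum(des$n_full), 722L)
})

test_that("malformed models fail to coalesce with a clear error", {
  m <- demographic_model(2)  # two isolated populations, no migration
  expect_error(simulate_dataset(m, c(2L, 2L), theta = 1, L = 100, seed = 1),
               "single root")
})
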
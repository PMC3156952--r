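test_that("count_segregating classifies private and shared sites", {
  # site 1: variant only in unit; site 2: variant in unit and complement;
  # site 3: variant only in complement; site 4: monomorphic
  g <- rbind(c(0L, 1L, 0L, 0L),
             c(1L, 0L, 1L, 0L),
             c(0L, 0L, 2L, 1L),
             c(0L, 0L, 0L, 0L))
  colnames(g) <- c("u1", "u2", "c1", "c2")
  gm <- toy_gm(g)
  res <- count_segregating(gm, c("u1", "u2"))
  expect_equal(res, list(S = 2L, Sp = 1L))
  expect_equal(count_segregating(gm, c("c1", "c2")),
               list(S = 2L, Sp = 1L))
  mono <- toy_gm(matrix(0L, 2, 2, dimnames = list(NULL, c("a", "b"))))
  expect_equal(count_segregating(mono, "a"), list(S = 0L, Sp = 0L))
  expect_error(count_segregating(gm, character(0)), "empty unit")
})

test_that("watterson_theta matches closed forms", {
  expect_equal(watterson_theta(0, 10, 100)$estimate, 0)
  expect_equal(watterson_theta(1, 2, 100)$estimate, 0.01)  # a_1 = 1
  th <- watterson_theta(16, 10, 1000)
  expect_equal(th$estimate, 16 / (sum(1 / (1:9)) * 1000))
  expect_lte(th$ci[1], th$estimate)
  expect_gte(th$ci[2], th$estimate)
  expect_error(watterson_theta(1, 1, 100), "n_chrom")
})

test_that("pi by frequency formula equals brute-force pairwise differences", {
  # derived count 2 of 4 chromosomes, L = 1: 4 of 6 pairs differ -> 2/3
  g <- matrix(c(1L, 1L), 1, 2, dimnames = list(NULL, c("a", "b")))
  gm <- toy_gm(g, region_length = 1)
  expect_equal(nucleotide_diversity(gm, c("a", "b"), L = 1)$estimate, 2 / 3)
  expect_equal(nucleotide_diversity(toy_gm(matrix(0L, 3, 2)),
                                    paste0("sample", 1:2))$estimate, 0)
  # oracle equivalence on simulated phased data: mean pairwise hamming
  # distance over chromosome pairs == frequency formula
  for (seed in 1:5) {
    sim <- neutral_sim(n_chrom = 8, theta = 6, seed = seed)
    gm <- sim_to_genotypes(sim)
    pi_freq <- nucleotide_diversity(gm, sample_ids(gm), L = gm$region_length)
    h <- sim$haplotypes
    n <- ncol(h)
    pairs <- combn(n, 2)
    pw <- mean(vapply(seq_len(ncol(pairs)), function(k)
      sum(h[, pairs[1, k]] != h[, pairs[2, k]]), numeric(1)))
    expect_equal(pi_freq$estimate * gm$region_length, pw, tolerance = 1e-12)
  }
})

test_that("observed heterozygosity counts heterozygote fractions", {
  all_het <- toy_gm(matrix(c(1L, 1L), 1, 2,
                           dimnames = list(NULL, c("a", "b"))))
  expect_equal(observed_heterozygosity(all_het, c("a", "b"), L = 1), 1)
  no_het <- toy_gm(matrix(c(0L, 2L), 1, 2,
                          dimnames = list(NULL, c("a", "b"))))
  expect_equal(observed_heterozygosity(no_het, c("a", "b"), L = 1), 0)
  # missing-aware: one called heterozygote of one genotyped individual
  part <- toy_gm(matrix(c(1L, NA), 1, 2,
                        dimnames = list(NULL, c("a", "b"))))
  expect_equal(observed_heterozygosity(part, c("a", "b"), L = 1), 1)
})

test_that("haplotype heterozygosity: closed forms and window anchoring", {
  # 4 samples -> 8 haplotypes; one window, all haplotypes distinct
  sim <- neutral_sim(n_chrom = 8, theta = 8, seed = 11)
  gm <- sim_to_genotypes(sim)
  hs <- apply(gm$haplotypes, 2, paste, collapse = "")
  n <- length(hs)
  f <- table(hs) / n
  expect_equal(haplotype_heterozygosity(gm, sample_ids(gm),
                                        window_size = gm$region_length),
               n / (n - 1) * (1 - sum(f^2)))
  # identical haplotypes -> 0; empty windows contribute 0
  g0 <- matrix(0L, 1, 2, dimnames = list(NULL, c("a", "b")))
  gm0 <- genotype_matrix(5L, "A", "G", "A", g0, region_length = 100,
                         phased = TRUE,
                         haplotypes = matrix(0L, 1, 4))
  expect_equal(haplotype_heterozygosity(gm0, c("a", "b"), window_size = 10),
               0)
  gm_unph <- toy_gm(matrix(0L, 1, 2))
  expect_error(haplotype_heterozygosity(gm_unph, sample_ids(gm_unph)),
               "phase")
})

test_that("tajimas_d matches an independent constant evaluation", {
  # independent textbook-constant oracle
  oracle_D <- function(S, pi_tot, n) {
    a1 <- sum(1 / seq_len(n - 1)); a2 <- sum(1 / seq_len(n - 1)^2)
    b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
    c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
    (pi_tot - S / a1) / sqrt(c1 / a1 * S +
                               c2 / (a1^2 + a2) * S * (S - 1))
  }
  d <- tajimas_d(16, 3.0, 10, n_reps = 500, seed = 1)
  expect_equal(d$D, oracle_D(16, 3.0, 10), tolerance = 1e-12)
  a1 <- sum(1 / (1:9))
  expect_equal(tajimas_d(16, 16 / a1, 10, n_reps = 200, seed = 1)$D, 0)
  expect_true(is.na(tajimas_d(0, 0, 10)$D))
  expect_true(d$P >= 0 && d$P <= 1)
})

test_that("theta, pi and D are calibrated on standard-neutral simulations", {
  theta_true <- 5; L <- 1e4; n <- 10
  reps <- 500
  m <- demographic_model(1)
  ests <- t(vapply(seq_len(reps), function(r) {
    sim <- simulate_dataset(m, n, theta = theta_true, L = L, seed = 5000 + r)
    S <- nrow(sim$haplotypes)
    cnt <- rowSums(sim$haplotypes)
    pi_tot <- sum(2 * cnt * (n - cnt) / (n * (n - 1)))
    a1 <- sum(1 / seq_len(n - 1))
    D <- if (S >= 3) tajimas_d(S, pi_tot, n, n_reps = 2)$D else NA
    c(theta = S / a1, pi = pi_tot, D = D)
  }, numeric(3)))
  se <- apply(ests, 2, function(v) stats::sd(v, na.rm = TRUE) / sqrt(sum(!is.na(v))))
  expect_lt(abs(mean(ests[, "theta"]) - theta_true), 3 * se["theta"])
  expect_lt(abs(mean(ests[, "pi"]) - theta_true), 3 * se["pi"])
  expect_lt(abs(mean(ests[, "D"], na.rm = TRUE)), 3 * se["D"] + 0.05)
})

test_that("diversity_table reports both levels on the x 1e-5 scale", {
  sim <- simulate_dataset(demographic_model(1), 16, theta = 8, L = 1e4,
                          seed = 3)
  gm <- sim_to_genotypes(sim)
  man <- toy_manifest(sample_ids(gm), rep(c("p1", "p2"), each = 4),
                      group_of = c(p1 = "g1", p2 = "g1"))
  tab <- diversity_table(gm, man, d_reps = 200, seed = 1)
  expect_equal(tab$unit, c("g1", "p1", "p2"))
  expect_true(all(tab$S >= tab$Sp))
  expect_true(all(tab$HapHet >= 0 & tab$HapHet <= 1))
  expect_true(all(tab$theta_lo <= tab$theta & tab$theta <= tab$theta_hi))
  p1 <- samples_of(man, "p1")
  th <- watterson_theta(count_segregating(gm, p1)$S, 8, 1e4)
  expect_equal(tab$theta[tab$unit == "p1"], th$estimate * 1e5)
})
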
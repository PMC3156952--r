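test_that("filter_dataset applies the fixed order and additive bookkeeping", {
  # 6 sites x 3 samples; sample 3 has 2/6 calls (call rate 0.33 < 0.8)
  g <- rbind(c(0L, 1L, NA),   # polymorphic
             c(0L, 0L, 0L),   # fixed ref after sample 3 dropped
             c(2L, 2L, NA),   # fixed alt
             c(1L, 0L, NA),   # polymorphic
             c(0L, 1L, NA),   # tri-allelic (alt lists two alleles)
             c(0L, 0L, 1L))   # polymorphic only through sample 3 -> fixed
  colnames(g) <- c("a", "b", "c")
  gm <- toy_gm(g, alt = c("G", "G", "G", "G", "G,T", "G"))
  res <- filter_dataset(gm, call_rate_min = 0.8)
  expect_equal(res$log$individuals_removed, 1L)
  expect_equal(sample_ids(res$matrix), c("a", "b"))
  expect_equal(res$log$sites_fixed, 3L)
  expect_equal(res$log$sites_multiallelic, 1L)
  expect_equal(n_sites(res$matrix), 2L)
  expect_equal(res$log$sites_in - res$log$sites_fixed -
                 res$log$sites_multiallelic - res$log$sites_hwe,
               res$log$sites_out)

  # individual with exactly 80% call rate is retained
  g2 <- matrix(c(rep(0:1, 4), NA, 1L), 5, 2)
  expect_equal(n_samples(filter_dataset(toy_gm(g2), 0.8)$matrix), 2L)
  expect_error(filter_dataset(toy_gm(matrix(NA, 2, 1)), 0.8),
               "no samples survive")
})

test_that("fill_reference_genotypes fills, flags, and rejects contradictions", {
  g <- matrix(c(NA, 1L, NA, NA), 2, 2, dimnames = list(NULL, c("a", "b")))
  gm <- toy_gm(g)
  man <- toy_manifest(c("a", "b"), c("p1", "p2"))
  mask <- matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2,
                 dimnames = list(NULL, c("p1", "p2")))
  out <- fill_reference_genotypes(gm, mask, man)
  expect_equal(unname(out$genotypes[1, "a"]), 0L)
  expect_true(out$filled[1, "a"])
  expect_true(is.na(out$genotypes[2, "b"]))  # unmasked missing cell stays NA
  expect_true(is.na(out$genotypes[1, "b"]))
  bad <- matrix(c(FALSE, TRUE, FALSE, FALSE), 2, 2,
                dimnames = list(NULL, c("p1", "p2")))
  expect_error(fill_reference_genotypes(gm, bad, man), "contradictory")
  expect_error(fill_reference_genotypes(gm, mask[1, , drop = FALSE], man),
               "mask")
})

test_that("hwe_exact_test matches a brute-force conditional enumeration", {
  oracle <- function(n0, n1, n2) {
    n <- n0 + n1 + n2
    na <- n1 + 2 * n2
    hets <- seq((na %% 2), min(na, 2 * n - na), by = 2)
    pr <- vapply(hets, function(h) {
      n2h <- (na - h) / 2
      n0h <- n - h - n2h
      exp(lfactorial(n) - lfactorial(h) - lfactorial(n2h) - lfactorial(n0h) +
            h * log(2) + lfactorial(na) + lfactorial(2 * n - na) -
            lfactorial(2 * n))
    }, numeric(1))
    pr <- pr / sum(pr)  # guard rounding
    sum(pr[pr <= pr[hets == n1] * (1 + 1e-12)])
  }
  cases <- rbind(c(5, 10, 5), c(10, 1, 10), c(20, 4, 0), c(3, 3, 3),
                 c(0, 2, 8), c(7, 0, 7))
  for (i in seq_len(nrow(cases)))
    expect_equal(hwe_exact_test(cases[i, 1], cases[i, 2], cases[i, 3]),
                 oracle(cases[i, 1], cases[i, 2], cases[i, 3]),
                 tolerance = 1e-10)
  expect_equal(hwe_exact_test(10, 0, 0), 1)  # monomorphic
})

test_that("hwe_filter combines Z-scores and applies Bonferroni", {
  # 3 populations x 24 diploids; site 1 in good HWE proportions, site 2 a
  # gross violation (all heterozygotes) in every population
  g_ok <- rep(c(0L, 1L, 2L), times = c(6, 12, 6))
  g_bad <- rep(1L, 24)
  g <- rbind(rep(g_ok, 3), rep(g_bad, 3))
  colnames(g) <- paste0("s", 1:72)
  man <- toy_manifest(colnames(g), rep(c("p1", "p2", "p3"), each = 24))
  res <- hwe_filter(toy_gm(g), man, alpha = 0.01)
  expect_equal(res$log$M, 2L)
  expect_equal(res$log$sites_hwe, 1L)
  expect_equal(n_sites(res$matrix), 1L)
  expect_equal(res$matrix$positions, 1L)  # the HWE-consistent site survives
  expect_gt(res$z_combined[2], 0)
  expect_lt(res$p_combined[2], 0.01 / 2)
})

test_that("hwe_filter type-I error under the null is at most alpha", {
  # 2000 sites in HWE across 4 populations of 25 diploids
  with_seed2(99, {
    p <- runif(2000, 0.1, 0.9)
    g <- do.call(cbind, lapply(1:4, function(k)
      t(vapply(p, function(pp) rbinom(25, 2, pp), integer(25)))))
  })
  colnames(g) <- paste0("s", seq_len(ncol(g)))
  man <- toy_manifest(colnames(g), rep(paste0("p", 1:4), each = 25))
  res <- hwe_filter(toy_gm(g), man, alpha = 0.01)
  expect_lte(res$log$sites_hwe / res$log$M, 0.01)
})

test_that("polarize_alleles uses the outgroup, falls back to minor allele,
           and is idempotent", {
  g <- rbind(c(0L, 1L, 0L),   # outgroup = ref
             c(0L, 1L, 2L),   # outgroup = alt -> swap
             c(1L, 0L, 0L),   # outgroup unknown, alt freq 1/6 -> alt derived
             c(2L, 2L, 1L))   # outgroup unknown, alt freq 5/6 -> swap
  gm <- toy_gm(g, ref = rep("A", 4), alt = rep("G", 4),
               ancestral = rep(NA_character_, 4))
  out <- polarize_alleles(gm, c("A", "G", NA, NA))
  expect_equal(attr(out, "polarize_method"),
               c("outgroup", "outgroup", "minor", "minor"))
  expect_equal(out$ref, c("A", "G", "A", "G"))
  expect_equal(out$alt, c("G", "A", "G", "A"))
  expect_equal(unname(out$genotypes[2, ]), c(2L, 1L, 0L))
  expect_equal(unname(out$genotypes[4, ]), c(0L, 0L, 1L))
  expect_equal(out$ancestral, out$ref)
  # involution-safe relabeling: twice equals once
  again <- polarize_alleles(out, c("A", "G", NA, NA))
  expect_identical(again$genotypes, out$genotypes)
  expect_identical(again$ref, out$ref)
})

test_that("subsample_panel is reproducible and keeps small units whole", {
  man <- toy_manifest(paste0("s", 1:50),
                      rep(c("p1", "p2"), times = c(30, 20)),
                      group_of = c(p1 = "g1", p2 = "g1"))
  s1 <- subsample_panel(man, "population", 24, seed = 7)
  s2 <- subsample_panel(man, "population", 24, seed = 7)
  expect_identical(s1$sample, s2$sample)
  expect_equal(sum(s1$population == "p1"), 24)
  expect_equal(sum(s1$population == "p2"), 20)  # kept whole
  s3 <- subsample_panel(man, "continent", 40, seed = 1)
  expect_equal(nrow(s3), 40)
  expect_error(samples_of(man, "nope", "population"), "unknown")
})
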
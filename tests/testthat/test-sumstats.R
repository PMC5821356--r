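test_that("per-population statistics match hand computations", {
  # one population, one locus, alleles {10,10,12,12}
  g <- toy_genotypes(list(list(rbind(c(10, 10), c(12, 12)))))
  pp <- per_population_stats(g)
  expect_equal(pp$A, 2)
  expect_equal(pp$Hs, (4 / 3) * (1 - 0.5))
  expect_equal(pp$M, 2 / 3)          # range 2 -> 2/(2+1)
  expect_equal(pp$richness, pp$A)    # equal sample sizes: no rarefaction

  # monomorphic population
  gm <- toy_genotypes(list(list(rbind(c(8, 8), c(8, 8)))))
  ppm <- per_population_stats(gm)
  expect_equal(ppm$A, 1)
  expect_equal(ppm$Hs, 0)
  expect_equal(ppm$M, 1)

  # alleles {10, 12, 14, 14}: A = 3, range 4 -> M = 3/5
  gr <- toy_genotypes(list(list(rbind(c(10, 12), c(14, 14)))))
  expect_equal(per_population_stats(gr)$M, 0.6)
})

test_that("an all-missing locus is dropped for that population with a warning", {
  al <- array(NA_integer_, c(4, 2, 2))
  al[, 1, ] <- 10L
  al[3:4, 2, ] <- 12L            # locus 2 typed only in pop2
  g <- genotype_matrix(al, c("a", "a", "b", "b"))
  expect_warning(pp <- per_population_stats(g), "all-missing")
  expect_equal(pp$A, c(1, 1))
})

test_that("pairwise theta handles the fixed, duplicated and toy cases", {
  # two populations fixed for different alleles -> theta = 1
  gfix <- toy_genotypes(list(list(rbind(c(10, 10), c(10, 10))),
                             list(rbind(c(12, 12), c(12, 12)))))
  expect_equal(pairwise_fst(gfix), 1)

  # identical copies of the same individuals -> theta <= 0, kept unclamped
  ind <- rbind(c(10, 12), c(10, 14), c(12, 12), c(14, 10))
  gdup <- toy_genotypes(list(list(ind), list(ind)))
  th <- pairwise_fst(gdup)
  expect_lte(th, 1e-12)
  expect_lt(th, 0)     # the unbiased estimator goes negative here

  # toy set vs the brute-force ANOVA oracle
  gt <- toy_genotypes(list(list(rbind(c(10, 10), c(10, 12))),
                           list(rbind(c(12, 12), c(12, 12)))))
  expect_equal(pairwise_fst(gt), oracle_wc_theta(gt), tolerance = 1e-12)
  expect_equal(pairwise_fst(gt), 2 / 3, tolerance = 1e-10)
})

test_that("theta equals the brute-force variance-components oracle", {
  set.seed(77)
  for (i in 1:25) {
    g <- make_island_genotypes(sample(2:4, 1), sample(3:10, 1),
                               sample(1:4, 1), F = stats::runif(1, 0, 0.6))
    if (nlevels(g$pop) == 2) {
      expect_equal(pairwise_fst(g), oracle_wc_theta(g), tolerance = 1e-12)
    } else {
      # oracle on each pair separately
      pairs <- utils::combn(levels(g$pop), 2)
      th <- pairwise_fst(g)
      # dist ordering: (2,1), (3,1), ..., (3,2), ...
      idx <- 0
      np <- nlevels(g$pop)
      for (a in seq_len(np - 1)) {
        for (b in (a + 1):np) {
          idx <- idx + 1
          keep <- g$pop %in% levels(g$pop)[c(a, b)]
          sub <- genotype_matrix(g$alleles[keep, , , drop = FALSE],
                                 droplevels(g$pop[keep]))
          expect_equal(th[idx], oracle_wc_theta(sub), tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("statistics are invariant to a global allele-length translation", {
  set.seed(5)
  g <- make_island_genotypes(3, 8, 4, F = 0.3)
  g2 <- genotype_matrix(g$alleles + 7L, g$pop)
  expect_equal(pairwise_fst(g2), pairwise_fst(g))
  expect_equal(per_population_stats(g2)$Hs, per_population_stats(g)$Hs)
  expect_equal(per_population_stats(g2)$A, per_population_stats(g)$A)
  expect_equal(chord_distance(g2), chord_distance(g))
})

test_that("chord distance matches its closed forms", {
  ind <- rbind(c(10, 12), c(12, 10))
  gid <- toy_genotypes(list(list(ind), list(ind)))
  expect_equal(chord_distance(gid), 0)

  # disjoint allele sets: cos theta = 0 -> the formula's maximum
  gdis <- toy_genotypes(list(list(rbind(c(10, 10), c(10, 10))),
                             list(rbind(c(12, 12), c(12, 12)))))
  expect_equal(chord_distance(gdis), 2 / pi * sqrt(2))

  # frequencies (0.5, 0.5) vs (1, 0)
  gh <- toy_genotypes(list(list(rbind(c(10, 12))),
                           list(rbind(c(10, 10)))))
  expect_equal(chord_distance(gh),
               2 / pi * sqrt(2 * (1 - sqrt(0.5))), tolerance = 1e-12)
})

test_that("pattern statistics reduce the clines to six numbers", {
  # perfectly linear A over three demes: slope recovered, zero residuals
  ps <- pattern_statistics(A = c(10, 9, 8), fst = c(0.1, 0.2, 0.3),
                           d_origin = c(0, 1000, 2000),
                           d_pairs = c(1000, 2000, 1000))
  expect_equal(unname(ps["slope_A"]), -0.001)
  expect_equal(unname(ps["mean_A"]), 9)
  expect_equal(unname(ps["logSSR_A"]), log10(1e-12))

  # hand OLS: A = (5, 6, 10) at d = (0, 1000, 2000)
  ps2 <- pattern_statistics(A = c(5, 6, 10), fst = c(0.1, 0.2, 0.3),
                            d_origin = c(0, 1000, 2000),
                            d_pairs = c(1000, 2000, 1000))
  expect_equal(unname(ps2["slope_A"]), 0.0025)
  expect_equal(unname(ps2["mean_A"]), 7)
  expect_equal(unname(ps2["logSSR_A"]), log10(1.5 + 1e-12), tolerance = 1e-9)

  expect_error(pattern_statistics(c(1, 2), c(0.1), c(0, 1), c(1)),
               "degenerate regression")
  expect_error(pattern_statistics(c(1, 2, 3), c(0.1, 0.2), c(0, 1, 2),
                                  c(1, 1, 1)), "inconsistent")
})

test_that("island-model genotypes recover their target differentiation", {
  set.seed(303)
  g0 <- make_island_genotypes(6, 20, 30, F = 0)
  expect_lt(abs(mean(pairwise_fst(g0))), 0.01)
  expect_error(make_island_genotypes(2, 5, 2, F = 1), "fixed differences")
  g <- make_island_genotypes(10, 30, 50, F = 0.2)
  expect_equal(dim(g$alleles), c(300, 50, 2))
  expect_lt(abs(mean(pairwise_fst(g)) - 0.2), 0.02)
})
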
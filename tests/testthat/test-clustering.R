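# deterministic two-allele genotypes with chosen per-population frequency
freq_genotypes <- function(freqs, n_per_pop = 20) {
  pops <- lapply(freqs, function(p) {
    n1 <- round(2 * n_per_pop * p)
    copies <- c(rep(10L, n1), rep(12L, 2 * n_per_pop - n1))
    list(matrix(copies, n_per_pop, 2), matrix(copies, n_per_pop, 2))
  })
  toy_genotypes(pops)
}

test_that("population PCA recovers duplicate and clinal structure", {
  g <- freq_genotypes(c(0.2, 0.2, 0.8, 0.5))
  pc <- population_pca(g)
  expect_equal(pc$coords[1, ], pc$coords[2, ])    # duplicated populations
  expect_true(all(diff(pc$varprop) <= 1e-12))
  expect_lte(sum(pc$varprop), 1 + 1e-12)

  # a linear 1-D cline loads on PC1
  pos <- seq_len(10)
  gc <- freq_genotypes(seq(0.05, 0.95, length.out = 10))
  pcc <- population_pca(gc)
  expect_gt(abs(stats::cor(pcc$coords[, 1], pos)), 0.99)

  gmono <- freq_genotypes(c(0.5, 0.5, 0.5))
  expect_error(population_pca(gmono), "no variance")
  expect_error(population_pca(freq_genotypes(c(0.2, 0.8))), ">= 3")
})

test_that("PCA axis comparison is sign- and scale-invariant with a 1/(n-1) null", {
  set.seed(21)
  coords <- matrix(stats::rnorm(70 * 2), 70, 2,
                   dimnames = list(sprintf("p%02d", 1:70), NULL))
  obs <- structure(list(coords = coords, varprop = c(0.6, 0.4)),
                   class = "pca_result")
  expect_equal(pca_axis_r2(obs, obs, 1), 1)
  flipped <- obs; flipped$coords <- -3.7 * coords
  expect_equal(pca_axis_r2(obs, flipped, 1), 1)

  r2 <- replicate(300, {
    sim <- obs
    sim$coords[, 1] <- stats::rnorm(70)
    pca_axis_r2(obs, sim, 1)
  })
  expect_lt(abs(mean(r2) - 1 / 69), 0.005)

  bad <- obs; rownames(bad$coords)[1] <- "other"
  expect_error(pca_axis_r2(obs, bad, 1), "differ")
})

test_that("admixture EM matches the K = 1 closed form and separates fixed pops", {
  set.seed(22)
  g <- make_island_genotypes(2, 10, 5, F = 0.3)
  fit1 <- admixture_fit(g, K = 1, seed = 1, n_init = 1)
  expect_true(all(fit1$Q == 1))
  # closed form: pooled multinomial log-likelihood
  cnt <- demicabc:::.locus_counts(g)
  ll <- sum(vapply(cnt, function(X) {
    p <- colSums(X) / sum(X)
    sum(t(X) * ifelse(p > 0, log(p), 0))
  }, numeric(1)))
  expect_equal(fit1$loglik, ll, tolerance = 1e-6)

  # EM log-likelihood is non-decreasing
  expect_true(all(diff(fit1$loglik_trace) >= -1e-6))

  # disjoint fixed alleles: ancestry resolves into the two blocks
  gfix <- toy_genotypes(list(
    list(matrix(10L, 8, 2), matrix(20L, 8, 2)),
    list(matrix(12L, 8, 2), matrix(24L, 8, 2))))
  fit2 <- admixture_fit(gfix, K = 2, seed = 2)
  expect_true(all(diff(fit2$loglik_trace) >= -1e-6))
  expect_true(all(apply(fit2$Q, 1, max) >= 0.99))
  block <- apply(fit2$Q, 1, which.max)
  expect_equal(length(unique(block[1:8])), 1)
  expect_equal(length(unique(block[9:16])), 1)
  expect_false(block[1] == block[9])

  expect_error(admixture_fit(gfix, K = 20), "exceeds")
})

test_that("replicate alignment undoes label switching", {
  set.seed(23)
  Q <- matrix(stats::rgamma(30 * 3, 1), 30, 3)
  Q <- Q / rowSums(Q)
  P <- list(matrix(1 / 4, 3, 4))
  mkrun <- function(Qm) structure(list(Q = Qm, P = P, K = 3, loglik = -1),
                                  class = "admixture_result")
  perm <- c(3, 1, 2)
  runs <- list(mkrun(Q), mkrun(Q[, perm]))
  al <- align_replicates(runs)
  expect_equal(al$aligned[[2]]$Q, Q)
  expect_equal(al$mean_Q, Q)

  # brute-force over all 6 permutations agrees with the chosen one
  perms <- demicabc:::.permutations(3)
  scores <- vapply(perms, function(p) sum(Q * Q[, perm][, p]), numeric(1))
  expect_equal(Q[, perm][, perms[[which.max(scores)]]], Q)

  expect_error(align_replicates(list(mkrun(Q),
    structure(list(Q = Q, P = P, K = 2), class = "admixture_result"))),
    "mixed K")

  one <- list(mkrun(Q))
  expect_equal(align_replicates(one)$mean_Q, Q)
})

test_that("Evanno's Delta-K follows its second-difference arithmetic", {
  mk <- function(means, sd = 2) {
    a <- sd / sqrt(2)
    rbind(means - a, means + a)
  }
  ll <- mk(c(-1000, -900, -880, -875))
  colnames(ll) <- 1:4
  ks <- evanno_delta_k(ll)
  expect_equal(ks$table$delta_k, c(NA, 40, 7.5, NA))
  expect_equal(ks$best_delta_K, 2L)
  expect_equal(ks$best_loglik_K, 4L)

  # linear mean likelihood: all interior Delta-K are zero
  lin <- mk(c(-300, -200, -100, 0))
  colnames(lin) <- 1:4
  expect_true(all(evanno_delta_k(lin)$table$delta_k == 0, na.rm = TRUE))

  # replicate order is irrelevant
  llp <- ll[2:1, ]
  colnames(llp) <- 1:4
  expect_equal(evanno_delta_k(llp)$table$delta_k, ks$table$delta_k)

  # zero SD: undefined, warned, reported missing
  zz <- rbind(c(-10, -5, -1), c(-10, -5, -1.5))
  colnames(zz) <- 1:3
  expect_warning(kz <- evanno_delta_k(zz), "zero SD")
  expect_true(is.na(kz$table$delta_k[2]))

  expect_error(evanno_delta_k(ll[, 1:2]), ">= 3")
  expect_error(evanno_delta_k(ll[1, , drop = FALSE]), ">= 2")
})

test_that("independent corridor simulations agree on the leading PCA axis", {
  fx <- make_fixture_landscape("corridor")
  p <- table1_like_params()
  pcs <- list()
  for (seed in c(41, 42)) {
    h <- simulate_forward(fx$landscape, p, seed = seed)
    expect_true(colonization_success(h, fx$scheme))
    g <- simulate_genotypes(h, fx$scheme, n_loci = 100, seed = seed + 100)
    pcs[[length(pcs) + 1]] <- population_pca(g)
  }
  expect_gt(pca_axis_r2(pcs[[1]], pcs[[2]], 1), 0.8)
})
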
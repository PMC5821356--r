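# synthetic reference table with chosen parameter/statistic columns
fake_table <- function(params, stats, prior = prior_config()) {
  n <- nrow(params)
  tab <- data.frame(params, colonized = TRUE, seed = seq_len(n), stats)
  structure(tab, class = c("reference_table", "data.frame"),
            landscape = NULL, scheme = NULL, prior = prior, n_loci = 8)
}

fake_cols <- function(n, m_values, driver) {
  params <- matrix(rep(c(5000, 100, 1000, 0.5, 0.1, 5e-4), each = n), n, 6,
                   dimnames = list(NULL, c("T_gen", "N_i", "N", "r", "m", "mu")))
  params[, "m"] <- m_values
  stats <- matrix(rep(c(5, -0.001, 0.3, 0.05, 1e-5, -1), each = n), n, 6,
                  dimnames = list(NULL, c("mean_A", "slope_A", "logSSR_A",
                                          "mean_Fst", "slope_Fst",
                                          "logSSR_Fst")))
  stats[, "mean_A"] <- driver
  list(params = params, stats = stats)
}

test_that("prior draws respect their supports and stated moments", {
  cfg <- prior_config()
  set.seed(1)
  draws <- draw_priors(cfg, 10000)
  Ni <- vapply(draws, `[[`, numeric(1), "N_i")
  N <- vapply(draws, `[[`, numeric(1), "N")
  m <- vapply(draws, `[[`, numeric(1), "m")
  mu <- vapply(draws, `[[`, numeric(1), "mu")
  Tg <- vapply(draws, `[[`, numeric(1), "T_gen")
  r <- vapply(draws, `[[`, numeric(1), "r")
  expect_true(all(Ni >= 2 & Ni <= 5120))
  expect_true(all(N >= 2 & N <= 5120))
  expect_true(all(m >= 0 & m <= 0.5))
  expect_true(all(mu >= 1e-5 & mu <= 1e-3))
  expect_true(all(Tg >= 1))
  # CLT bound on the onset prior mean (years)
  expect_lt(abs(mean(Tg * 25) - 155000), 3 * 32000 / sqrt(10000))
  # lognormal r: median exp(meanlog) = 0.5
  expect_lt(abs(stats::median(r) - 0.5), 0.012)
})

test_that("reference tables have the row contract and are deterministic", {
  fx <- make_fixture_landscape("corridor", n_individuals = 4)
  fast_prior <- prior_config(T_mean_years = 5000, T_sd_years = 1000)
  tab <- build_reference_table(fx$landscape, fx$scheme, fast_prior,
                               n_sims = 6, n_loci = 3, seed = 99)
  expect_s3_class(tab, "reference_table")
  expect_equal(nrow(tab), 6)
  ok <- tab$colonized
  expect_true(all(stats::complete.cases(
    as.data.frame(tab)[ok, demicabc:::.stat_names])))
  expect_true(all(is.na(as.data.frame(tab)[!ok, "mean_A"])))

  tab2 <- build_reference_table(fx$landscape, fx$scheme, fast_prior,
                                n_sims = 6, n_loci = 3, seed = 99)
  expect_identical(as.data.frame(tab), as.data.frame(tab2))

  # m = 0 in a multi-deme scheme cannot colonize: all rows flagged
  m0 <- prior_config(T_mean_years = 2000, T_sd_years = 200, m_range = c(0, 0))
  tab0 <- build_reference_table(fx$landscape, fx$scheme, m0,
                                n_sims = 3, n_loci = 2, seed = 1)
  expect_true(all(!tab0$colonized))
})

test_that("rejection ranks an exact match first and adjusts linearly", {
  set.seed(8)
  n <- 400
  driver <- stats::runif(n)
  fc <- fake_cols(n, m_values = 0.4 * driver, driver = driver)
  tab <- fake_table(fc$params, fc$stats)

  obs <- fc$stats[37, ]
  post <- suppressWarnings(estimate_posterior(tab, obs, k = 50))
  expect_equal(post$distances[1], 0)
  expect_equal(post$retained[1], 37)

  # noiseless linear map m = 0.4 * driver: mode inverts it at the observation
  obs2 <- fc$stats[1, ]; obs2["mean_A"] <- 0.5
  post2 <- suppressWarnings(estimate_posterior(tab, obs2, k = 100))
  expect_lt(abs(coef(post2)["m"] - 0.2), 0.01)
  # degenerate statistics are dropped with a warning
  expect_warning(estimate_posterior(tab, obs2, k = 100), "zero-variance")
})

test_that("rejection is invariant to affine rescaling of a raw statistic", {
  set.seed(9)
  n <- 300
  driver <- stats::rnorm(n)
  fc <- fake_cols(n, m_values = pmin(0.5, pmax(0, 0.25 + 0.1 * driver)),
                  driver = driver)
  fc$stats[, "slope_Fst"] <- stats::rnorm(n)          # second informative axis
  tab1 <- fake_table(fc$params, fc$stats)
  obs1 <- c(mean_A = 0.2, slope_A = -0.001, logSSR_A = 0.3,
            mean_Fst = 0.05, slope_Fst = 0.1, logSSR_Fst = -1)
  sc <- fc$stats
  sc[, "mean_A"] <- 1000 * sc[, "mean_A"] - 77
  obs2 <- obs1; obs2["mean_A"] <- 1000 * obs2["mean_A"] - 77
  tab2 <- fake_table(fc$params, sc)
  p1 <- suppressWarnings(estimate_posterior(tab1, obs1, k = 60))
  p2 <- suppressWarnings(estimate_posterior(tab2, obs2, k = 60))
  expect_identical(p1$retained, p2$retained)
  expect_equal(coef(p1), coef(p2), tolerance = 1e-8)
})

test_that("posteriors stay inside the prior support with mode inside the HPD", {
  set.seed(10)
  n <- 250
  driver <- stats::runif(n)
  fc <- fake_cols(n, m_values = stats::runif(n, 0, 0.5), driver = driver)
  fc$stats[, "mean_Fst"] <- stats::rnorm(n)
  tab <- fake_table(fc$params, fc$stats)
  obs <- c(mean_A = 0.5, slope_A = -0.001, logSSR_A = 0.3,
           mean_Fst = 0, slope_Fst = 1e-5, logSSR_Fst = -1)
  post <- suppressWarnings(estimate_posterior(tab, obs, k = 80))
  sup <- post$support
  ci <- confint(post)
  for (j in seq_len(6)) {
    expect_gte(ci[j, 1], sup[j, 1])
    expect_lte(ci[j, 2], sup[j, 2])
    expect_gte(coef(post)[j], ci[j, 1])
    expect_lte(coef(post)[j], ci[j, 2])
    # no density mass outside the support by construction of the grid
    expect_true(all(post$marginals[[j]]$grid >= sup[j, 1] &
                    post$marginals[[j]]$grid <= sup[j, 2]))
  }
  expect_error(estimate_posterior(tab, obs, k = 5), "too few")
  expect_warning(expect_warning(estimate_posterior(tab, obs, k = 1e5),
                                "lowered"), "zero-variance")

  draws <- simulate(post, 50, seed = 3)
  expect_true(all(vapply(draws, function(p) p$m >= 0 && p$m <= 0.5,
                         logical(1))))
  hpd_draws <- simulate(post, 20, seed = 4, hpd_only = TRUE)
  for (p in hpd_draws) expect_true(p$m >= ci["m", 1] & p$m <= ci["m", 2])
  expect_equal(simulate(post, 1, mode_only = TRUE)[[1]]$m,
               unname(coef(post)["m"]), tolerance = 1e-6)
})

test_that("validation metrics match hand arithmetic", {
  modes <- cbind(x = c(1, 2, 3))
  truths <- cbind(x = c(1, 2, 5))
  covered <- cbind(x = c(TRUE, TRUE, FALSE))
  support <- rbind(x = c(0, 10))
  m <- demicabc:::.validation_metrics(modes, truths, covered, support)
  expect_equal(m$srmse, sqrt(4 / 3) / 10, tolerance = 1e-12)
  expect_equal(m$coverage, 2 / 3)

  # a perfect estimator scores perfectly
  mp <- suppressWarnings(demicabc:::.validation_metrics(
    truths, truths, cbind(x = rep(TRUE, 3)), support))
  expect_equal(mp$r2, 1)
  expect_equal(mp$slope, 1)
  expect_equal(mp$srmse, 0)
  expect_equal(mp$coverage, 1)
})

test_that("weighted-KDE HPD intervals are calibrated on a known density", {
  # 95% HPD of a normal sample should cover fresh draws ~95% of the time
  set.seed(11)
  x <- stats::rnorm(4000)
  kd <- demicabc:::.weighted_kde(x, rep(1, 4000), -6, 6)
  hpd <- demicabc:::.hpd_interval(kd$grid, kd$density)
  expect_lt(abs(hpd[1] + 1.96), 0.25)
  expect_lt(abs(hpd[2] - 1.96), 0.25)
  fresh <- stats::rnorm(2000)
  cover <- mean(fresh >= hpd[1] & fresh <= hpd[2])
  expect_lt(abs(cover - 0.95), 3 * sqrt(0.95 * 0.05 / 2000) + 0.01)
})

test_that("leave-one-out validation runs and reports sane metrics", {
  set.seed(12)
  n <- 200
  driver <- stats::runif(n)
  m_true <- pmin(0.5, pmax(0, 0.4 * driver + stats::rnorm(n, 0, 0.01)))
  fc <- fake_cols(n, m_values = m_true, driver = driver)
  tab <- fake_table(fc$params, fc$stats)
  val <- suppressWarnings(validate_estimator(tab, n_pseudo = 12, k = 40,
                                             seed = 5))
  expect_s3_class(val, "abc_validation")
  met <- val$metrics
  expect_equal(nrow(met), 6)
  expect_true(all(met$r2 >= 0 & met$r2 <= 1))
  expect_true(all(met$coverage >= 0 & met$coverage <= 1))
  expect_true(all(met$srmse >= 0))
  # the informative parameter is recovered nearly perfectly
  expect_gt(met$r2[met$parameter == "m"], 0.9)
  expect_error(validate_estimator(tab, n_pseudo = 1000), "exceeds")
})
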
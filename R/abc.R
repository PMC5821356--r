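#' Prior configuration for the six demo-genetic parameters
#'
#' Defaults are the study priors: founding size `N_i` ~ U(2, 5120),
#' carrying capacity `N` ~ U(2, 5120), emigration `m` ~ U(0, 0.5),
#' mutation rate `mu` ~ U(1e-5, 1e-3), onset `T` ~ Normal(155000, 32000)
#' years truncated above 25 years and converted to generations at 25
#' years/generation, and growth `r` ~ Lognormal(meanlog = ln 0.5,
#' sdlog = 0.6) (median 0.5).
#'
#' @param Ni_range,N_range,m_range,mu_range uniform prior bounds.
#' @param mu_log_uniform draw `mu` log-uniformly instead of uniformly.
#' @param T_mean_years,T_sd_years,T_min_years truncated-normal prior on the
#'   onset, in years.
#' @param gen_time generation time in years.
#' @param r_meanlog,r_sdlog lognormal prior on the growth rate.
#' @return object of class `prior_config`.
#' @export
prior_config <- function(Ni_range = c(2, 5120), N_range = c(2, 5120),
                         m_range = c(0, 0.5), mu_range = c(1e-5, 1e-3),
                         mu_log_uniform = FALSE,
                         T_mean_years = 155000, T_sd_years = 32000,
                         T_min_years = 25, gen_time = 25,
                         r_meanlog = log(0.5), r_sdlog = 0.6) {
  cfg <- list(Ni_range = Ni_range, N_range = N_range, m_range = m_range,
              mu_range = mu_range, mu_log_uniform = mu_log_uniform,
              T_mean_years = T_mean_years, T_sd_years = T_sd_years,
              T_min_years = T_min_years, gen_time = gen_time,
              r_meanlog = r_meanlog, r_sdlog = r_sdlog)
  structure(cfg, class = "prior_config")
}

#' @export
print.prior_config <- function(x, ...) {
  cat("prior configuration:\n")
  cat(sprintf("  N_i ~ U(%g, %g); N ~ U(%g, %g); m ~ U(%g, %g)\n",
              x$Ni_range[1], x$Ni_range[2], x$N_range[1], x$N_range[2],
              x$m_range[1], x$m_range[2]))
  cat(sprintf("  mu ~ %s(%g, %g)\n",
              if (x$mu_log_uniform) "log-U" else "U",
              x$mu_range[1], x$mu_range[2]))
  cat(sprintf("  T ~ N(%g, %g) years (> %g), %g yr/generation\n",
              x$T_mean_years, x$T_sd_years, x$T_min_years, x$gen_time))
  cat(sprintf("  r ~ Lognormal(meanlog = %.4g, sdlog = %.4g)\n",
              x$r_meanlog, x$r_sdlog))
  invisible(x)
}

.param_names <- c("T_gen", "N_i", "N", "r", "m", "mu")

# finite support per parameter for grids, truncation and SRMSE
# standardization; unbounded priors (T, r) use their 0.05%/99.95% quantiles
.prior_support <- function(cfg) {
  tq <- stats::qnorm(c(5e-4, 1 - 5e-4), cfg$T_mean_years, cfg$T_sd_years)
  t_lo <- max(1, floor(max(tq[1], cfg$T_min_years) / cfg$gen_time))
  t_hi <- ceiling(tq[2] / cfg$gen_time)
  rq <- stats::qlnorm(c(5e-4, 1 - 5e-4), cfg$r_meanlog, cfg$r_sdlog)
  s <- rbind(T_gen = c(t_lo, t_hi),
             N_i = cfg$Ni_range, N = cfg$N_range,
             r = c(0, rq[2]), m = cfg$m_range, mu = cfg$mu_range)
  colnames(s) <- c("lower", "upper")
  s
}

#' Draw parameter sets from the prior
#'
#' @param cfg a [prior_config()].
#' @param n number of draws.
#' @param seed optional integer seed.
#' @return list of [parameter_set()] objects.
#' @export
draw_priors <- function(cfg, n, seed = NULL) {
  stopifnot(inherits(cfg, "prior_config"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    Ty <- stats::rnorm(1, cfg$T_mean_years, cfg$T_sd_years)
    while (Ty <= cfg$T_min_years)
      Ty <- stats::rnorm(1, cfg$T_mean_years, cfg$T_sd_years)
    mu <- if (cfg$mu_log_uniform)
      exp(stats::runif(1, log(cfg$mu_range[1]), log(cfg$mu_range[2])))
    else stats::runif(1, cfg$mu_range[1], cfg$mu_range[2])
    out[[i]] <- parameter_set(
      T_gen = max(1, round(Ty / cfg$gen_time)),
      N_i = round(stats::runif(1, cfg$Ni_range[1], cfg$Ni_range[2])),
      N = round(stats::runif(1, cfg$N_range[1], cfg$N_range[2])),
      r = stats::rlnorm(1, cfg$r_meanlog, cfg$r_sdlog),
      m = stats::runif(1, cfg$m_range[1], cfg$m_range[2]),
      mu = mu)
  }
  out
}

.stat_names <- c("mean_A", "slope_A", "logSSR_A",
                 "mean_Fst", "slope_Fst", "logSSR_Fst")

# deterministic per-row seed below 2^31
.row_seed <- function(seed, i) {
  (as.numeric(seed) * 48271 + as.numeric(i) * 999983) %% 2147483629 + 1
}

#' Build an ABC reference table
#'
#' For each row: draw one parameter set from the prior, run the forward
#' demography, check colonization of every sampled deme, and — for
#' successful rows — run the coalescent and reduce the genotypes to the six
#' pattern statistics. Failed colonizations are kept with their flag and no
#' statistics. Every row is reproducible from `(seed, row index)` alone.
#'
#' @param landscape a [build_landscape()] object.
#' @param scheme a [sampling_scheme()].
#' @param cfg a [prior_config()].
#' @param n_sims number of simulations.
#' @param n_loci microsatellite loci per simulation.
#' @param seed master seed.
#' @param verbose print progress every 100 rows.
#' @return object of class `reference_table`: a data.frame of parameters,
#'   colonization flag, per-row seed and pattern statistics, with the
#'   inputs attached as attributes.
#' @export
build_reference_table <- function(landscape, scheme, cfg, n_sims, n_loci,
                                  seed = 1, verbose = FALSE) {
  stopifnot(n_sims >= 1)
  dv <- distance_vectors(landscape, scheme)
  par_m <- matrix(NA_real_, n_sims, 6,
                  dimnames = list(NULL, .param_names))
  st_m <- matrix(NA_real_, n_sims, 6, dimnames = list(NULL, .stat_names))
  colonized <- logical(n_sims)
  seeds <- vapply(seq_len(n_sims), function(i) .row_seed(seed, i), numeric(1))
  for (i in seq_len(n_sims)) {
    set.seed(seeds[i])
    p <- draw_priors(cfg, 1)[[1]]
    par_m[i, ] <- c(p$T_gen, p$N_i, p$N, p$r, p$m, p$mu)
    hist <- simulate_forward(landscape, p)
    colonized[i] <- colonization_success(hist, scheme)
    if (!colonized[i]) next
    g <- simulate_genotypes(hist, scheme, n_loci)
    pp <- per_population_stats(g)
    fst <- pairwise_fst(g)
    st_m[i, ] <- pattern_statistics(pp$A, fst, dv$from_origin, dv$pairwise)
    if (verbose && i %% 100 == 0)
      message(sprintf("reference table: %d / %d", i, n_sims))
  }
  tab <- data.frame(par_m, colonized = colonized, seed = seeds, st_m)
  structure(tab, class = c("reference_table", "data.frame"),
            landscape = landscape, scheme = scheme, prior = cfg,
            n_loci = n_loci, master_seed = seed)
}

#' @export
print.reference_table <- function(x, ...) {
  cat(sprintf(
    "ABC reference table: %d simulations, %d colonized (%.1f%%), %d loci\n",
    nrow(x), sum(x$colonized), 100 * mean(x$colonized),
    attr(x, "n_loci")))
  invisible(x)
}

#' Write a reference table as TSV
#' @param table a [build_reference_table()] result.
#' @param path output path.
#' @export
write_reference_table <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# weighted KDE on a fixed grid with boundary reflection
.weighted_kde <- function(x, w, lo, hi, n_grid = 512) {
  w <- w / sum(w)
  n_eff <- 1 / sum(w^2)
  sd_w <- sqrt(max(0, sum(w * x^2) - sum(w * x)^2))
  qs <- .weighted_quantile(x, w, c(0.25, 0.75))
  sig <- min(sd_w, (qs[2] - qs[1]) / 1.34)
  if (!is.finite(sig) || sig <= 0) sig <- max(sd_w, (hi - lo) / 1000)
  if (sig <= 0) sig <- (hi - lo) / 1000
  bw <- 0.9 * sig * n_eff^(-1 / 5)
  bw <- max(bw, (hi - lo) / n_grid)   # never drop all mass between grid points
  grid <- seq(lo, hi, length.out = n_grid)
  xx <- c(x, 2 * lo - x, 2 * hi - x)          # reflect at the support edges
  ww <- c(w, w, w)
  f <- vapply(grid, function(g0)
    sum(ww * stats::dnorm(g0 - xx, sd = bw)), numeric(1))
  dx <- grid[2] - grid[1]
  total <- sum(f) * dx
  if (total <= 0) stop("degenerate posterior density")
  list(grid = grid, density = f / total, bw = bw)
}

.weighted_quantile <- function(x, w, probs) {
  o <- order(x)
  x <- x[o]; w <- w[o] / sum(w)
  cw <- cumsum(w)
  vapply(probs, function(p) x[which.max(cw >= p)], numeric(1))
}

# smallest superlevel set holding `mass` of the density; returns range
.hpd_interval <- function(grid, density, mass = 0.95) {
  dx <- grid[2] - grid[1]
  o <- order(density, decreasing = TRUE)
  cm <- cumsum(density[o] * dx)
  keep <- o[seq_len(which.max(cm >= mass))]
  range(grid[keep])
}

#' ABC posterior estimation with regression adjustment
#'
#' The estimator: (1) standardize the six pattern statistics by the
#' reference table's mean and SD; (2) rank simulations by Euclidean
#' distance to the standardized observation and retain the `k` nearest;
#' (3) per parameter, adjust the retained draws by a local-linear
#' regression on the standardized statistics with Epanechnikov weights in
#' distance (Beaumont-type correction: `theta* = theta - b (s - s_obs)`);
#' (4) form each marginal posterior as a weighted kernel density on a
#' 512-point grid over the prior support (Silverman bandwidth, boundary
#' reflection). The point estimate is the density mode; the interval the
#' 95% highest-posterior-density set.
#'
#' @param table a [build_reference_table()] result.
#' @param observed named vector of the six observed pattern statistics.
#' @param k simulations to retain (default 5000; lowered with a warning if
#'   fewer colonized simulations are available).
#' @param n_grid density grid size.
#' @return object of class `abc_posterior`.
#' @export
estimate_posterior <- function(table, observed, k = 5000, n_grid = 512) {
  stopifnot(inherits(table, "reference_table"))
  observed <- observed[.stat_names]
  if (anyNA(observed)) stop("observed statistics incomplete")
  ok <- which(table$colonized & stats::complete.cases(
    as.data.frame(table)[, .stat_names]))
  if (length(ok) < k) {
    warning(sprintf("only %d colonized simulations; k lowered from %d",
                    length(ok), k))
    k <- length(ok)
  }
  if (k <= 10) stop("too few retained")
  S <- as.matrix(as.data.frame(table)[ok, .stat_names])
  P <- as.matrix(as.data.frame(table)[ok, .param_names])
  mu_s <- colMeans(S); sd_s <- apply(S, 2, stats::sd)
  drop <- which(sd_s == 0 | !is.finite(sd_s))
  if (length(drop) > 0)
    warning("zero-variance statistic dropped from the distance: ",
            paste(.stat_names[drop], collapse = ", "))
  use <- setdiff(seq_along(.stat_names), drop)
  Z <- sweep(sweep(S[, use, drop = FALSE], 2, mu_s[use]), 2, sd_s[use], "/")
  z_obs <- (as.numeric(observed)[use] - mu_s[use]) / sd_s[use]
  d <- unname(sqrt(colSums((t(Z) - z_obs)^2)))
  ret <- order(d)[seq_len(k)]
  dk <- d[ret[k]]
  w <- if (dk > 0) 1 - (d[ret] / dk)^2 else rep(1, k)
  if (sum(w) <= 0) w <- rep(1, k)

  support <- .prior_support(attr(table, "prior"))
  X <- cbind(1, Z[ret, , drop = FALSE])
  adj <- matrix(NA_real_, k, 6, dimnames = list(NULL, .param_names))
  marginals <- vector("list", 6); names(marginals) <- .param_names
  for (j in seq_len(6)) {
    theta <- P[ret, j]
    fit <- stats::lm.wfit(X, theta, w)
    b <- fit$coefficients[-1]
    b[is.na(b)] <- 0
    adj[, j] <- theta - Z[ret, , drop = FALSE] %*% b + sum(z_obs * b)
    kd <- .weighted_kde(adj[, j], w, support[j, 1], support[j, 2], n_grid)
    mode <- kd$grid[which.max(kd$density)]
    hpd <- .hpd_interval(kd$grid, kd$density)
    marginals[[j]] <- list(grid = kd$grid, density = kd$density,
                           mode = mode, hpd = hpd, bw = kd$bw)
  }
  structure(list(marginals = marginals, adjusted = adj, weights = w,
                 retained = ok[ret], distances = d[ret], k = k,
                 observed = observed, dropped_stats = .stat_names[drop],
                 support = support),
            class = "abc_posterior")
}

#' @export
print.abc_posterior <- function(x, ...) {
  cat(sprintf("ABC posterior (k = %d retained simulations)\n", x$k))
  print(summary(x), digits = 4)
  invisible(x)
}

#' @export
summary.abc_posterior <- function(object, ...) {
  data.frame(
    parameter = .param_names,
    mode = vapply(object$marginals, function(m) m$mode, numeric(1)),
    hpd95_lower = vapply(object$marginals, function(m) m$hpd[1], numeric(1)),
    hpd95_upper = vapply(object$marginals, function(m) m$hpd[2], numeric(1)),
    row.names = NULL)
}

#' @export
coef.abc_posterior <- function(object, ...) {
  stats::setNames(vapply(object$marginals, function(m) m$mode, numeric(1)),
                  .param_names)
}

#' @export
confint.abc_posterior <- function(object, parm = .param_names,
                                  level = 0.95, ...) {
  out <- t(vapply(object$marginals[parm], function(m) {
    if (level == 0.95) m$hpd else .hpd_interval(m$grid, m$density, level)
  }, numeric(2)))
  colnames(out) <- c("lower", "upper")
  out
}

#' @export
plot.abc_posterior <- function(x, params = .param_names, ...) {
  old <- graphics::par(mfrow = grDevices::n2mfrow(length(params)))
  on.exit(graphics::par(old))
  for (p in params) {
    m <- x$marginals[[p]]
    graphics::plot(m$grid, m$density, type = "l", xlab = p,
                   ylab = "posterior density", main = p, ...)
    graphics::abline(v = m$mode, lty = 2)
    graphics::abline(v = m$hpd, lty = 3)
  }
  invisible(x)
}

#' Draw parameter sets from an estimated posterior
#'
#' Resamples the regression-adjusted draws with their Epanechnikov weights;
#' values are clamped to the prior support. With `hpd_only = TRUE` only
#' draws inside every marginal 95% HPD interval are eligible (the "95%HPD"
#' re-simulation set); `mode_only = TRUE` returns the point estimate.
#'
#' @param object an [estimate_posterior()] result.
#' @param nsim number of parameter sets.
#' @param seed optional seed.
#' @param hpd_only,mode_only sampling restrictions.
#' @param ... unused.
#' @return list of [parameter_set()] objects.
#' @export
simulate.abc_posterior <- function(object, nsim = 1, seed = NULL,
                                   hpd_only = FALSE, mode_only = FALSE, ...) {
  if (!is.null(seed)) set.seed(seed)
  sup <- object$support
  clamp <- function(v) pmin(pmax(v, sup[, 1]), sup[, 2])
  mk <- function(v) {
    v <- clamp(v)
    parameter_set(max(1, round(v["T_gen"])), max(2, round(v["N_i"])),
                  max(2, round(v["N"])), max(0, v["r"]),
                  min(0.5, max(0, v["m"])),
                  min(1e-2, max(1e-6, v["mu"])))
  }
  if (mode_only) return(replicate(nsim, mk(coef(object)), simplify = FALSE))
  pool <- object$adjusted
  w <- object$weights
  if (hpd_only) {
    inside <- rep(TRUE, nrow(pool))
    for (j in seq_len(6)) {
      h <- object$marginals[[j]]$hpd
      inside <- inside & pool[, j] >= h[1] & pool[, j] <= h[2]
    }
    if (!any(inside)) stop("no adjusted draw inside all HPD intervals")
    pool <- pool[inside, , drop = FALSE]; w <- w[inside]
  }
  idx <- sample.int(nrow(pool), nsim, replace = TRUE, prob = pmax(w, 1e-12))
  lapply(idx, function(i) mk(pool[i, ]))
}

#' Validate the ABC estimator on pseudo-observed simulations
#'
#' Draws `n_pseudo` colonized reference rows as pseudo-observations
#' (leave-one-out: each row is excluded from its own reference set), re-runs
#' [estimate_posterior()] on each, and summarizes recovery per parameter:
#' R-squared and slope of the regression of the posterior mode on the
#' pseudo-true value, SRMSE (RMSE of the mode standardized by the prior
#' range) and the coverage of the 95% HPD intervals.
#'
#' @param table a [build_reference_table()] result.
#' @param n_pseudo number of pseudo-observations.
#' @param k retained simulations per estimation.
#' @param seed optional seed.
#' @return object of class `abc_validation`: data.frame of metrics plus the
#'   per-pseudo-observation modes, truths and coverage flags.
#' @export
validate_estimator <- function(table, n_pseudo, k = 5000, seed = NULL) {
  stopifnot(inherits(table, "reference_table"))
  if (!is.null(seed)) set.seed(seed)
  ok <- which(table$colonized & stats::complete.cases(
    as.data.frame(table)[, .stat_names]))
  if (n_pseudo > length(ok)) stop("n_pseudo exceeds colonized simulations")
  if (length(ok) - 1 < k)
    k <- length(ok) - 1   # leave-one-out must still leave k rows
  pick <- sample(ok, n_pseudo)
  modes <- truths <- matrix(NA_real_, n_pseudo, 6,
                            dimnames = list(NULL, .param_names))
  covered <- matrix(NA, n_pseudo, 6, dimnames = list(NULL, .param_names))
  for (i in seq_len(n_pseudo)) {
    row <- pick[i]
    obs <- unlist(as.data.frame(table)[row, .stat_names])
    sub <- structure(as.data.frame(table)[-row, , drop = FALSE],
                     class = c("reference_table", "data.frame"),
                     landscape = attr(table, "landscape"),
                     scheme = attr(table, "scheme"),
                     prior = attr(table, "prior"),
                     n_loci = attr(table, "n_loci"))
    post <- suppressWarnings(estimate_posterior(sub, obs, k = k))
    truths[i, ] <- unlist(as.data.frame(table)[row, .param_names])
    modes[i, ] <- coef(post)
    ci <- confint(post)
    covered[i, ] <- truths[i, ] >= ci[, 1] & truths[i, ] <= ci[, 2]
  }
  support <- .prior_support(attr(table, "prior"))
  metrics <- .validation_metrics(modes, truths, covered, support)
  structure(list(metrics = metrics, modes = modes, truths = truths,
                 covered = covered, k = k, n_pseudo = n_pseudo),
            class = "abc_validation")
}

# per-parameter recovery metrics: R^2 and slope of mode ~ truth, SRMSE
# standardized by the prior range, HPD95 coverage
.validation_metrics <- function(modes, truths, covered, support) {
  do.call(rbind, lapply(seq_len(ncol(modes)), function(j) {
    tr <- truths[, j]; mo <- modes[, j]
    fit <- stats::lm(mo ~ tr)
    data.frame(parameter = colnames(modes)[j],
               r2 = summary(fit)$r.squared,
               slope = unname(stats::coef(fit)[2]),
               srmse = sqrt(mean((mo - tr)^2)) /
                 (support[j, 2] - support[j, 1]),
               coverage = mean(covered[, j]))
  }))
}

#' @export
print.abc_validation <- function(x, ...) {
  cat(sprintf("ABC validation: %d pseudo-observations, k = %d\n",
              x$n_pseudo, x$k))
  print(x$metrics, digits = 3, row.names = FALSE)
  invisible(x)
}

#' Write a posterior summary (Table-1-style) as TSV
#' @param posterior an [estimate_posterior()] result.
#' @param path output path.
#' @param validation optional [validate_estimator()] result whose metrics
#'   are appended as columns.
#' @export
write_posterior_summary <- function(posterior, path, validation = NULL) {
  s <- summary(posterior)
  if (!is.null(validation)) s <- merge(s, validation$metrics, by = "parameter",
                                       sort = FALSE)
  utils::write.table(s, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
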
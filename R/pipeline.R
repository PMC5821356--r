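#' Configuration for a full pipeline run
#'
#' A flat list of run settings, constructible in code or from a YAML file
#' ([read_run_config()]). The master `seed` deterministically spawns one
#' seed per stage (reference table, observation, validation, re-simulation,
#' clustering), so a run directory is regenerable from its manifest alone.
#'
#' @param fixture fixture landscape name ([make_fixture_landscape()]), or
#'   `NULL` when `raster`/`origin` are given.
#' @param raster path to a land-mask raster ([read_land_mask()]).
#' @param origin origin cell `c(row, col)` (0-based) for `raster` input.
#' @param scheme path to a sampling-scheme TSV; `NULL` uses the fixture's
#'   default scheme.
#' @param observed path to a STRUCTURE-format genotype file to estimate
#'   from; `NULL` simulates a pseudo-observation from the prior.
#' @param n_sims reference-table size.
#' @param n_loci loci per simulation.
#' @param k retained simulations for the posterior.
#' @param n_pseudo pseudo-observations for validation.
#' @param n_resim simulations per re-simulation set (Prior / 95%HPD / Mode).
#' @param K_range admixture cluster numbers (within 1..12).
#' @param n_reps admixture replicates per K.
#' @param seed master seed.
#' @param out_dir output directory.
#' @return object of class `run_config`.
#' @export
run_config <- function(fixture = "corridor", raster = NULL, origin = NULL,
                       scheme = NULL, observed = NULL,
                       n_sims = 300, n_loci = 6, k = 100, n_pseudo = 10,
                       n_resim = 5, K_range = 1:4, n_reps = 3,
                       seed = 1, out_dir = "demicabc_run") {
  K_range <- sort(unique(as.integer(K_range)))
  if (min(K_range) < 1 || max(K_range) > 12)
    stop("K range must lie within [1, 12]")
  for (p in c(raster, scheme, observed))
    if (!is.null(p) && !file.exists(p)) stop("missing input file: ", p)
  if (n_sims < k)
    warning("n_sims < k: the posterior will retain every colonized row")
  structure(list(fixture = fixture, raster = raster, origin = origin,
                 scheme = scheme, observed = observed, n_sims = n_sims,
                 n_loci = n_loci, k = k, n_pseudo = n_pseudo,
                 n_resim = n_resim, K_range = K_range, n_reps = n_reps,
                 seed = seed, out_dir = out_dir),
            class = "run_config")
}

#' @rdname run_config
#' @param path YAML file of `run_config()` fields.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full expansion-inference pipeline
#'
#' Executes, in order: landscape construction, ABC reference table,
#' posterior estimation (against a user-supplied dataset or a simulated
#' pseudo-observation), estimator validation, the three re-simulation sets
#' drawn from Prior / 95%HPD / Mode with their six pattern statistics and
#' PCA axis correlations against the observation, and admixture clustering
#' with Evanno's Delta-K on a Mode-set simulation. All artifacts are
#' written to `cfg$out_dir`; a `manifest.yaml` records the configuration,
#' spawned seeds and package version.
#'
#' @param cfg a [run_config()].
#' @param verbose print stage progress.
#' @return (invisibly) a list with every stage's in-memory result.
#' @export
run_full_pipeline <- function(cfg, verbose = TRUE) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(sprintf(...))
  seeds <- stats::setNames(
    vapply(1:5, function(i) .row_seed(cfg$seed, i), numeric(1)),
    c("table", "observation", "validation", "resimulation", "clustering"))

  world <- .stage("landscape", {
    if (!is.null(cfg$raster)) {
      mask <- read_land_mask(cfg$raster)
      L <- build_landscape(mask, cfg$origin)
      if (is.null(cfg$scheme)) stop("raster input needs a scheme file")
      list(landscape = L, scheme = read_sampling_scheme(cfg$scheme))
    } else {
      fx <- make_fixture_landscape(cfg$fixture)
      if (!is.null(cfg$scheme)) fx$scheme <- read_sampling_scheme(cfg$scheme)
      fx
    }
  })
  prior <- prior_config()

  say("building reference table (%d simulations)...", cfg$n_sims)
  table <- .stage("reference_table",
    build_reference_table(world$landscape, world$scheme, prior,
                          cfg$n_sims, cfg$n_loci, seed = seeds[["table"]]))
  write_reference_table(table, file.path(cfg$out_dir, "reference_table.tsv"))

  obs <- .stage("observation", {
    if (!is.null(cfg$observed)) {
      g <- read_structure(cfg$observed)
      ss <- summary_statistics(g, world$landscape, world$scheme)
      list(pattern = ss$pattern, genotypes = g, params = NULL)
    } else {
      set.seed(seeds[["observation"]])
      repeat {
        p <- draw_priors(prior, 1)[[1]]
        po <- try(make_pseudo_observation(world$landscape, world$scheme, p,
                                          cfg$n_loci), silent = TRUE)
        if (!inherits(po, "try-error")) break
      }
      po
    }
  })

  say("estimating posterior (k = %d)...", cfg$k)
  posterior <- .stage("posterior",
    suppressWarnings(estimate_posterior(table, obs$pattern, k = cfg$k)))

  say("validating estimator (%d pseudo-observations)...", cfg$n_pseudo)
  validation <- .stage("validation",
    validate_estimator(table, cfg$n_pseudo, k = cfg$k,
                       seed = seeds[["validation"]]))
  write_posterior_summary(posterior,
                          file.path(cfg$out_dir, "posterior_summary.tsv"),
                          validation)

  say("re-simulating from Prior / 95%%HPD / Mode...")
  resim <- .stage("resimulation",
    .resimulation_sets(world, prior, posterior, obs, cfg$n_loci,
                       cfg$n_resim, seeds[["resimulation"]]))
  utils::write.table(resim$patterns,
                     file.path(cfg$out_dir, "resimulation_patterns.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(resim$pca_r2, file.path(cfg$out_dir, "pca_r2.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  say("clustering (K in %d..%d, %d replicates)...",
      min(cfg$K_range), max(cfg$K_range), cfg$n_reps)
  clustering <- .stage("clustering", {
    g <- resim$mode_genotypes
    reps <- admixture_replicates(g, cfg$K_range, cfg$n_reps,
                                 seed = seeds[["clustering"]])
    ks <- if (length(cfg$K_range) >= 3 && cfg$n_reps >= 2)
      evanno_delta_k(reps$loglik) else NULL
    list(replicates = reps, k_selection = ks, genotypes = g)
  })
  if (!is.null(clustering$k_selection))
    utils::write.table(clustering$k_selection$table,
                       file.path(cfg$out_dir, "delta_k.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  for (Kc in names(clustering$replicates$runs)) {
    if (as.integer(Kc) < 2) next
    al <- align_replicates(clustering$replicates$runs[[Kc]])
    write_q_matrix(al$mean_Q,
                   file.path(cfg$out_dir, sprintf("mean_Q_K%s.txt", Kc)),
                   pop = clustering$genotypes$pop)
  }

  manifest <- list(
    package = "demicabc",
    version = as.character(utils::packageVersion("demicabc")),
    config = unclass(cfg),
    stage_seeds = as.list(seeds),
    config_hash = sum(utf8ToInt(paste(deparse(unclass(cfg)), collapse = ""))),
    timestamp = format(Sys.time(), "%Y-%m-%d %H:%M:%S"))
  yaml::write_yaml(manifest, file.path(cfg$out_dir, "manifest.yaml"))
  say("done: %s", cfg$out_dir)
  invisible(list(world = world, table = table, observation = obs,
                 posterior = posterior, validation = validation,
                 resimulation = resim, clustering = clustering,
                 manifest = manifest))
}

# the paper-style comparison sets: parameters from the prior, from the
# posterior truncated to the 95% HPD box, and from the point estimates
.resimulation_sets <- function(world, prior, posterior, obs, n_loci,
                               n_resim, seed) {
  set.seed(seed)
  obs_pca <- try(population_pca(obs$genotypes), silent = TRUE)
  sets <- list(
    Prior = draw_priors(prior, n_resim),
    `95%HPD` = simulate(posterior, n_resim, hpd_only = TRUE),
    Mode = simulate(posterior, n_resim, mode_only = TRUE))
  rows <- list(); pca_rows <- list()
  mode_genotypes <- NULL
  for (label in names(sets)) {
    for (i in seq_along(sets[[label]])) {
      p <- sets[[label]][[i]]
      hist <- simulate_forward(world$landscape, p)
      okcol <- colonization_success(hist, world$scheme)
      pat <- rep(NA_real_, 6)
      r2 <- c(NA_real_, NA_real_)
      if (okcol) {
        g <- simulate_genotypes(hist, world$scheme, n_loci)
        ss <- summary_statistics(g, world$landscape, world$scheme)
        pat <- ss$pattern
        if (!inherits(obs_pca, "try-error")) {
          sim_pca <- try(population_pca(g), silent = TRUE)
          if (!inherits(sim_pca, "try-error")) {
            r2 <- c(pca_axis_r2(obs_pca, sim_pca, 1),
                    if (min(ncol(obs_pca$coords), ncol(sim_pca$coords)) >= 2)
                      pca_axis_r2(obs_pca, sim_pca, 2) else NA_real_)
          }
        }
        if (label == "Mode" && is.null(mode_genotypes)) mode_genotypes <- g
      }
      rows[[length(rows) + 1]] <- data.frame(
        set = label, replicate = i, colonized = okcol,
        T_gen = p$T_gen, N_i = p$N_i, N = p$N, r = p$r, m = p$m, mu = p$mu,
        t(stats::setNames(pat, .stat_names)))
      pca_rows[[length(pca_rows) + 1]] <- data.frame(
        set = label, replicate = i, axis1_r2 = r2[1], axis2_r2 = r2[2])
    }
  }
  if (is.null(mode_genotypes))
    stop("no Mode-set simulation colonized the sampling scheme")
  list(patterns = do.call(rbind, rows), pca_r2 = do.call(rbind, pca_rows),
       mode_genotypes = mode_genotypes)
}
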
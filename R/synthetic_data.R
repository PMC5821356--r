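#' Toy fixture landscapes with default sampling schemes
#'
#' Self-contained stand-ins for a continental land mask, small enough for
#' tests and demos:
#' \describe{
#'   \item{corridor}{a 30 x 10 all-land strip, origin at one end, 15 evenly
#'     spaced sampled demes along the long axis — the isolation-by-distance
#'     workhorse.}
#'   \item{two_continents}{two 12 x 12 land blocks joined by a single-deme
#'     isthmus, origin in block 1, 8 demes sampled per block — the setting
#'     where admixture clustering splits "continents" under pure diffusion.}
#'   \item{archipelago}{four 5 x 5 islands chained by 1-deme bridges, two
#'     sampled demes per island.}
#'   \item{single_deme}{a 1 x 1 world: the panmictic special case.}
#' }
#'
#' @param name fixture name.
#' @param n_individuals diploid sample size per sampled deme (default 10).
#' @param deme_edge_km deme edge length (default 160 km).
#' @return list with `landscape` and `scheme`.
#' @export
make_fixture_landscape <- function(name = c("corridor", "two_continents",
                                            "archipelago", "single_deme"),
                                   n_individuals = 10L, deme_edge_km = 160) {
  name <- match.arg(name)
  if (name == "corridor") {
    mask <- matrix(TRUE, 30, 10)
    origin <- c(0L, 4L)
    rows <- round(seq(0, 29, length.out = 15))
    demes <- cbind(rows, 4L)
  } else if (name == "two_continents") {
    mask <- matrix(FALSE, 12, 25)
    mask[, 1:12] <- TRUE
    mask[, 14:25] <- TRUE
    mask[6, 13] <- TRUE                    # the isthmus (0-based (5, 12))
    origin <- c(5L, 2L)
    block1 <- expand.grid(row = c(1L, 4L, 7L, 10L), col = c(2L, 9L))
    block2 <- expand.grid(row = c(1L, 4L, 7L, 10L), col = c(15L, 22L))
    demes <- as.matrix(rbind(block1, block2))
  } else if (name == "archipelago") {
    mask <- matrix(FALSE, 5, 23)
    starts <- c(1L, 7L, 13L, 19L)
    for (s in starts) mask[, s:(s + 4L)] <- TRUE
    mask[3, c(6L, 12L, 18L)] <- TRUE       # bridges
    origin <- c(2L, 2L)
    demes <- cbind(rep(c(0L, 4L), 4),
                   rep(starts - 1L, each = 2) + c(0L, 4L))
  } else {
    mask <- matrix(TRUE, 1, 1)
    origin <- c(0L, 0L)
    demes <- cbind(0L, 0L)
  }
  landscape <- build_landscape(mask, origin, deme_edge_km)
  scheme <- sampling_scheme(demes, n_individuals)
  list(landscape = landscape, scheme = scheme)
}

#' Island-model genotypes with known differentiation
#'
#' Calibration oracle for the F_ST machinery: per locus, ancestral allele
#' frequencies are drawn from a flat Dirichlet over 8 allele states, each
#' population's frequencies from a Dirichlet with concentration
#' `(1-F)/F` times the ancestral frequencies (the standard F-model), and
#' genotypes multinomially. Expected Weir-Cockerham theta is approximately
#' `F`.
#'
#' @param n_pops number of populations.
#' @param n_per_pop diploid individuals per population.
#' @param n_loci number of loci.
#' @param F target differentiation, `0 <= F < 1`.
#' @param seed integer seed.
#' @return a [genotype_matrix()].
#' @export
make_island_genotypes <- function(n_pops, n_per_pop, n_loci, F, seed = NULL) {
  if (F < 0 || F >= 1) stop("F must be in [0, 1); use fixed differences for F = 1")
  if (!is.null(seed)) set.seed(seed)
  states <- 15:22
  alleles <- array(NA_integer_, c(n_pops * n_per_pop, n_loci, 2L))
  for (l in seq_len(n_loci)) {
    anc <- stats::rgamma(length(states), 1)
    anc <- anc / sum(anc)
    for (p in seq_len(n_pops)) {
      pf <- if (F == 0) anc else {
        x <- stats::rgamma(length(states), shape = (1 - F) / F * anc)
        if (sum(x) == 0) { x <- anc } # pathological gamma underflow guard
        x / sum(x)
      }
      rows <- (p - 1L) * n_per_pop + seq_len(n_per_pop)
      draws <- sample(states, 2L * n_per_pop, replace = TRUE, prob = pf)
      alleles[rows, l, 1] <- draws[seq_len(n_per_pop)]
      alleles[rows, l, 2] <- draws[n_per_pop + seq_len(n_per_pop)]
    }
  }
  genotype_matrix(alleles, rep(sprintf("pop%02d", seq_len(n_pops)),
                               each = n_per_pop))
}

#' Pseudo-observed dataset with known true parameters
#'
#' Runs the full forward + backward simulator and the summary-statistic
#' reduction for one known parameter set, returning the six pattern
#' statistics together with the generating truth — the unit used by the
#' estimator-validation protocol.
#'
#' @param landscape a [build_landscape()] object.
#' @param scheme a [sampling_scheme()].
#' @param params a [parameter_set()] (the truth).
#' @param n_loci number of loci.
#' @param seed integer seed (the whole run is reproducible from it).
#' @return list with `pattern` (six statistics), `genotypes`, `params`.
#' @export
make_pseudo_observation <- function(landscape, scheme, params, n_loci,
                                    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  hist <- simulate_forward(landscape, params)
  if (!colonization_success(hist, scheme))
    stop("colonization failure: redraw parameters or seed")
  g <- simulate_genotypes(hist, scheme, n_loci)
  ss <- summary_statistics(g, landscape, scheme)
  list(pattern = ss$pattern, genotypes = g, params = params)
}
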
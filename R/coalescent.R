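#' Diploid microsatellite genotype matrix
#'
#' Container for repeat-length genotypes: an `individuals x loci x 2`
#' integer array plus population labels. Constructed by
#' [simulate_genotypes()], [make_island_genotypes()] or [read_structure()].
#'
#' @param alleles integer array `n_ind x n_loci x 2` of repeat counts
#'   (`NA` = missing).
#' @param pop factor or character of population labels, length `n_ind`.
#' @param loci optional locus names.
#' @param deme optional integer matrix of 0-based (row, col) cells per
#'   individual.
#' @return object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(alleles, pop, loci = NULL, deme = NULL) {
  stopifnot(length(dim(alleles)) == 3L, dim(alleles)[3] == 2L)
  storage.mode(alleles) <- "integer"
  if (any(alleles < 1L, na.rm = TRUE)) stop("allele lengths must be >= 1")
  pop <- factor(pop)
  if (length(pop) != dim(alleles)[1]) stop("pop labels must match individuals")
  if (is.null(loci)) loci <- sprintf("L%03d", seq_len(dim(alleles)[2]))
  structure(list(alleles = alleles, pop = pop, loci = as.character(loci),
                 deme = deme),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype matrix: %d diploid individuals, %d loci, %d populations\n",
              dim(x$alleles)[1], dim(x$alleles)[2], nlevels(x$pop)))
  invisible(x)
}

#' Backward-in-time coalescent genotype simulation
#'
#' Conditioned on a recorded [simulate_forward()] history, simulates
#' `n_loci` independent genealogies for the sampled gene copies and drops
#' single-stepwise mutations on them. Per generation backward: (i) each
#' lineage's source deme is drawn proportional to the realized migrant
#' counts recorded by the forward pass, (ii) each lineage picks a uniform
#' parent among the `2n` gene copies of its deme (exact Wright-Fisher;
#' lineages sharing a parent merge, multiple mergers allowed). Before the
#' expansion onset the origin deme is panmictic at constant size `N_i`.
#' Mutations are Poisson(`mu` x branch length) steps of +-1 repeat.
#'
#' @param history a [simulate_forward()] result.
#' @param scheme a [sampling_scheme()]; every sampled deme must have been
#'   colonized ([colonization_success()]).
#' @param n_loci number of microsatellite loci.
#' @param mu mutation rate per locus per generation; defaults to the
#'   history's parameter set.
#' @param ancestral_length root allele length in repeat units (the SMM
#'   statistics are translation-invariant; 20 is an arbitrary anchor).
#' @param seed integer seed.
#' @return a [genotype_matrix()] with individuals grouped by sampled deme.
#' @export
simulate_genotypes <- function(history, scheme, n_loci, mu = NULL,
                               ancestral_length = 20L, seed = NULL) {
  stopifnot(inherits(history, "demography_history"),
            inherits(scheme, "sampling_scheme"))
  if (n_loci < 1L) stop("n_loci must be >= 1")
  if (is.null(mu)) mu <- history$params$mu
  if (mu < 0) stop("mu must be >= 0")
  if (ancestral_length < 1L) stop("ancestral_length must be >= 1")
  if (!colonization_success(history, scheme))
    stop("uncolonized sampled deme")
  if (!is.null(seed)) set.seed(seed)

  ids <- .scheme_ids(history$landscape, scheme)
  n_ind <- scheme$n_individuals
  tip_deme <- rep(ids - 1L, times = 2L * n_ind)   # 2 gene copies / diploid
  recip <- .reciprocal_index(history$nbr)
  tips <- cpp_coalescent(history$nbr, recip, history$sizes, history$premig,
                         history$migrants, history$params$T_gen,
                         history$landscape$origin_id - 1L,
                         history$params$N_i, tip_deme, as.integer(n_loci),
                         mu, as.integer(ancestral_length))

  total <- sum(n_ind)
  alleles <- array(NA_integer_, c(total, n_loci, 2L))
  # gene copies for deme d are contiguous: pair consecutive copies
  copy_pop <- rep(seq_along(ids), times = 2L * n_ind)
  ind_of_copy <- integer(length(tip_deme))
  ofs <- 0L; ind0 <- 0L
  for (d in seq_along(ids)) {
    nc <- 2L * n_ind[d]
    ind_of_copy[ofs + seq_len(nc)] <- ind0 + rep(seq_len(n_ind[d]), each = 2L)
    ofs <- ofs + nc; ind0 <- ind0 + n_ind[d]
  }
  which_copy <- unlist(lapply(n_ind, function(k) rep(1:2, k)))
  for (cp in seq_along(tip_deme)) {
    alleles[ind_of_copy[cp], , which_copy[cp]] <- tips[cp, ]
  }
  pop <- rep(scheme$names, times = n_ind)
  genotype_matrix(alleles, factor(pop, levels = scheme$names),
                  deme = scheme$demes[rep(seq_along(ids), times = n_ind), ,
                                      drop = FALSE])
}

#' Single-stepwise-mutation walk
#'
#' Applies a Poisson(`mu * branch_generations`) number of independent
#' +-1 repeat changes to an allele length, reflected at 1 repeat.
#'
#' @param start_length starting repeat count (>= 1).
#' @param branch_generations branch length in generations (>= 0).
#' @param mu mutation rate per locus per generation.
#' @param seed optional integer seed.
#' @return mutated repeat count (always >= 1).
#' @export
smm_mutate <- function(start_length, branch_generations, mu, seed = NULL) {
  if (start_length < 1L) stop("start_length must be >= 1")
  if (branch_generations < 0) stop("negative branch length")
  if (mu < 0) stop("mu must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  cpp_smm_mutate(as.integer(start_length), branch_generations, mu)
}
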
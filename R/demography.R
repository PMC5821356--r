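#' Demo-genetic parameter set
#'
#' The six quantities inferred by the ABC stage: onset of the expansion in
#' generations before present (`T_gen`), founding size of the origin deme
#' (`N_i`, diploid individuals), per-deme carrying capacity (`N`),
#' intrinsic logistic growth rate per generation (`r`), total emigration
#' probability per individual per generation (`m`) and mutation rate per
#' locus per generation (`mu`).
#'
#' @param T_gen integer >= 1.
#' @param N_i integer >= 2.
#' @param N integer >= 2.
#' @param r >= 0.
#' @param m in [0, 0.5].
#' @param mu in [1e-6, 1e-2].
#' @return object of class `parameter_set`.
#' @export
parameter_set <- function(T_gen, N_i, N, r, m, mu) {
  T_gen <- as.integer(round(T_gen)); N_i <- as.integer(round(N_i))
  N <- as.integer(round(N))
  if (T_gen < 1L) stop("T_gen must be >= 1")
  if (N_i < 2L) stop("N_i must be >= 2")
  if (N < 2L) stop("N must be >= 2")
  if (r < 0) stop("r must be >= 0")
  if (m < 0 || m > 0.5) stop("m must be in [0, 0.5]")
  if (mu < 1e-6 || mu > 1e-2) stop("mu must be in [1e-6, 1e-2]")
  structure(list(T_gen = T_gen, N_i = N_i, N = N,
                 r = as.numeric(r), m = as.numeric(m), mu = as.numeric(mu)),
            class = "parameter_set")
}

#' @export
print.parameter_set <- function(x, ...) {
  cat(sprintf(
    "parameter set: T = %d generations, N_i = %d, N = %d, r = %.4g, m = %.4g, mu = %.4g\n",
    x$T_gen, x$N_i, x$N, x$r, x$m, x$mu))
  invisible(x)
}

# neighbour matrix over land demes: n_land x 4 of 0-based land ids, -1 = none
# direction order: up, down, left, right
.neighbour_matrix <- function(landscape) {
  nr <- landscape$n_rows; nc <- landscape$n_cols
  id <- landscape$cell_id
  pad <- matrix(NA_integer_, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- id
  land <- which(!is.na(id))  # column-major over raster
  ri <- ((land - 1L) %% nr) + 2L
  ci <- ((land - 1L) %/% nr) + 2L
  nbr <- cbind(pad[cbind(ri - 1L, ci)], pad[cbind(ri + 1L, ci)],
               pad[cbind(ri, ci - 1L)], pad[cbind(ri, ci + 1L)])
  ord <- order(id[land])          # rows in land-id order
  nbr <- nbr[ord, , drop = FALSE]
  nbr[is.na(nbr)] <- 0L
  nbr - 1L                        # 0-based, -1 for no land neighbour
}

# recip[j, k] = position of deme j in the neighbour list of nbr[j, k]
.reciprocal_index <- function(nbr) {
  # direction order up/down/left/right: reciprocal of 1 is 2, 3 is 4
  rec <- matrix(-1L, nrow(nbr), 4L)
  swap <- c(2L, 1L, 4L, 3L)
  for (k in 1:4) rec[, k] <- ifelse(nbr[, k] >= 0L, swap[k] - 1L, -1L)
  rec
}

#' Forward-in-time demographic simulation of the range expansion
#'
#' Starting `T_gen` generations ago from `N_i` diploids in the origin deme,
#' each generation applies (1) stochastic logistic regulation — the deme's
#' next size is Poisson-distributed around `n + r n (1 - n/N)` — followed
#' by (2) stepping-stone migration: each individual emigrates with total
#' probability `m`, emigrants split equally among the deme's land
#' neighbours (multinomial realization). Realized per-neighbour migrant
#' counts are recorded so the coalescent can invert migration exactly.
#'
#' @param landscape a [build_landscape()] object.
#' @param params a [parameter_set()].
#' @param seed integer seed.
#' @param deterministic if `TRUE`, sizes and migrant counts are rounded
#'   expectations instead of random draws.
#' @param sea_absorb if `TRUE`, emigration is split over all four
#'   directions and water-bound emigrants are lost; by default `m` is
#'   renormalized over land neighbours (coastal demes lose nobody to sea).
#' @return object of class `demography_history`: `sizes` (n_land demes x
#'   (T_gen+1) generations, column g+1 = generation g before present, 0 =
#'   present, post-migration census), `premig` (pre-migration sizes),
#'   `migrants` (4 x n_land x T_gen realized counts by direction
#'   up/down/left/right), plus the inputs and seed.
#' @export
simulate_forward <- function(landscape, params, seed = NULL,
                             deterministic = FALSE, sea_absorb = FALSE) {
  stopifnot(inherits(landscape, "landscape"), inherits(params, "parameter_set"))
  if (!is.null(seed)) set.seed(seed)
  nbr <- .neighbour_matrix(landscape)
  res <- cpp_forward(nbr, landscape$origin_id - 1L, params$T_gen,
                     params$N_i, params$N, params$r, params$m,
                     deterministic, sea_absorb)
  structure(list(sizes = res$sizes, premig = res$premig,
                 migrants = res$migrants, params = params,
                 landscape = landscape, nbr = nbr, seed = seed,
                 deterministic = deterministic, sea_absorb = sea_absorb),
            class = "demography_history")
}

#' @export
print.demography_history <- function(x, ...) {
  occ <- sum(x$sizes[, 1] > 0)
  cat(sprintf(
    "demography history: %d generations, %d land demes; %d occupied at present (total %.0f diploids)\n",
    x$params$T_gen, nrow(x$sizes), occ, sum(as.numeric(x$sizes[, 1]))))
  invisible(x)
}

#' Did the expansion colonize every sampled deme?
#'
#' `TRUE` iff every sampled deme holds at least its sample size at the
#' present generation. Simulations failing this are excluded from the ABC
#' reference table.
#'
#' @param history a [simulate_forward()] result.
#' @param scheme a [sampling_scheme()].
#' @export
colonization_success <- function(history, scheme) {
  if (nrow(scheme$demes) == 0L) return(TRUE)
  ids <- .scheme_ids(history$landscape, scheme)
  all(history$sizes[ids, 1] >= scheme$n_individuals)
}

#' Serialize a demography history's deme sizes
#'
#' Long-form table (generation, deme_row, deme_col, size) of occupied demes
#' only; gzip-compressed when the path ends in `.gz`.
#'
#' @param history a [simulate_forward()] result.
#' @param path output path (.tsv or .tsv.gz).
#' @export
write_history <- function(history, path) {
  occ <- which(history$sizes > 0, arr.ind = TRUE)
  L <- history$landscape
  land_rc <- which(!is.na(L$cell_id), arr.ind = TRUE)
  land_rc <- land_rc[order(L$cell_id[!is.na(L$cell_id)]), , drop = FALSE]
  d <- data.frame(generation = occ[, 2] - 1L,
                  deme_row = land_rc[occ[, 1], 1] - 1L,
                  deme_col = land_rc[occ[, 1], 2] - 1L,
                  size = history$sizes[occ])
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.table(d, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
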
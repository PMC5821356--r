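# Pattern-comparison stage: population-frequency PCA, a simplified
# admixture clustering fitted by EM on the STRUCTURE likelihood (no
# Dirichlet prior on ancestry, no MCMC), CLUMPP-style replicate alignment
# and Evanno's Delta-K.

# per-locus allele-count matrices: list over loci of n_ind x n_alleles
.locus_counts <- function(g) {
  n <- dim(g$alleles)[1]; L <- dim(g$alleles)[2]
  lapply(seq_len(L), function(l) {
    a1 <- g$alleles[, l, 1]; a2 <- g$alleles[, l, 2]
    states <- sort(unique(c(a1[!is.na(a1)], a2[!is.na(a2)])))
    X <- matrix(0, n, length(states),
                dimnames = list(NULL, as.character(states)))
    for (cp in list(a1, a2)) {
      ok <- !is.na(cp)
      idx <- cbind(which(ok), match(cp[ok], states))
      X[idx] <- X[idx] + 1
    }
    X
  })
}

#' PCA of population allele frequencies
#'
#' Builds the population x (locus, allele) frequency matrix, centers the
#' columns and returns the principal components of the populations.
#'
#' @param g a [genotype_matrix()] with at least 3 populations and 2 loci.
#' @return object of class `pca_result`: `coords` (populations x
#'   components), `varprop` (proportion of variance per component).
#' @export
population_pca <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (nlevels(g$pop) < 3) stop("need >= 3 populations")
  if (dim(g$alleles)[2] < 2) stop("need >= 2 loci")
  cnt <- .locus_counts(g)
  pops <- levels(g$pop)
  freq <- do.call(cbind, lapply(seq_along(cnt), function(l) {
    X <- cnt[[l]]
    F <- rowsum(X, g$pop)                      # allele counts per pop
    tot <- rowSums(F)
    F / ifelse(tot == 0, 1, tot)
  }))
  if (all(apply(freq, 2, stats::var) == 0)) stop("no variance")
  pc <- stats::prcomp(freq, center = TRUE, scale. = FALSE)
  coords <- pc$x
  rownames(coords) <- pops
  structure(list(coords = coords,
                 varprop = pc$sdev^2 / sum(pc$sdev^2)),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("population PCA: %d populations, %d components\n",
              nrow(x$coords), ncol(x$coords)))
  cat("variance explained:",
      paste(sprintf("%.1f%%", 100 * utils::head(x$varprop, 5)),
            collapse = ", "), "...\n")
  invisible(x)
}

#' Squared correlation between two PCA solutions on one axis
#'
#' The comparison statistic for observed-vs-simulated ordinations:
#' the square of the Pearson correlation between matched population
#' coordinates on a given axis — invariant to the sign flips and scalings
#' that make raw PCA axes incomparable.
#'
#' @param obs,sim [population_pca()] results over the same populations.
#' @param axis component index.
#' @return squared correlation in [0, 1].
#' @export
pca_axis_r2 <- function(obs, sim, axis = 1) {
  po <- rownames(obs$coords); ps <- rownames(sim$coords)
  if (!setequal(po, ps) || length(po) != length(ps))
    stop("population sets differ")
  a <- obs$coords[po, axis]
  b <- sim$coords[po, axis]
  stats::cor(a, b)^2
}

#' Admixture clustering by EM on the STRUCTURE likelihood
#'
#' Fits the admixture model — each allele copy of individual `i` at locus
#' `l` comes from cluster `z` with probability `Q[i, z]` and is then allele
#' `a` with probability `P[z, l, a]` — by expectation-maximization from a
#' seeded random start, with `n_init` restarts keeping the best
#' log-likelihood. This is the likelihood STRUCTURE samples from, without
#' the Dirichlet prior on `Q` and without MCMC.
#'
#' @param g a [genotype_matrix()].
#' @param K number of clusters (1 <= K <= individuals).
#' @param seed integer seed.
#' @param max_iter EM iteration cap per restart.
#' @param tol absolute log-likelihood convergence tolerance.
#' @param n_init random restarts.
#' @return object of class `admixture_result`: `Q` (individuals x K), `P`
#'   (list over loci of K x alleles frequency matrices), `loglik`, the
#'   log-likelihood trace of the winning restart, `K` and `seed`.
#' @export
admixture_fit <- function(g, K, seed = NULL, max_iter = 300, tol = 1e-6,
                          n_init = 5) {
  stopifnot(inherits(g, "genotype_matrix"), K >= 1)
  n <- dim(g$alleles)[1]
  if (K > n) stop("K exceeds number of individuals")
  if (!is.null(seed)) set.seed(seed)
  cnt <- .locus_counts(g)
  copies <- rowSums(vapply(cnt, rowSums, numeric(n)))  # typed copies per ind

  best <- NULL
  for (init in seq_len(n_init)) {
    Q <- matrix(stats::rgamma(n * K, 1), n, K)
    Q <- Q / rowSums(Q)
    P <- lapply(cnt, function(X) {
      M <- matrix(stats::rgamma(K * ncol(X), 1), K, ncol(X))
      M / rowSums(M)
    })
    ll_old <- -Inf; trace <- numeric(0)
    for (it in seq_len(max_iter)) {
      Qnum <- matrix(0, n, K)
      ll <- 0
      Pnew <- vector("list", length(cnt))
      for (l in seq_along(cnt)) {
        X <- cnt[[l]]
        D <- Q %*% P[[l]]
        D[D < 1e-300] <- 1e-300
        ll <- ll + sum(X * log(D))
        W <- X / D
        Qnum <- Qnum + Q * (W %*% t(P[[l]]))
        Pl <- (t(Q) %*% W) * P[[l]]
        rs <- rowSums(Pl)
        Pnew[[l]] <- Pl / ifelse(rs == 0, 1, rs)
      }
      Q <- Qnum / ifelse(copies == 0, 1, copies)
      Q[Q < 0] <- 0
      Q <- Q / rowSums(Q)
      P <- Pnew
      trace <- c(trace, ll)
      if (is.finite(ll_old) && ll - ll_old < tol) break
      ll_old <- ll
    }
    if (is.null(best) || trace[length(trace)] > best$loglik) {
      best <- list(Q = Q, P = P, loglik = trace[length(trace)],
                   trace = trace)
    }
  }
  structure(list(Q = best$Q, P = best$P, loglik = best$loglik,
                 loglik_trace = best$trace, K = K, seed = seed,
                 pop = g$pop),
            class = "admixture_result")
}

#' @export
print.admixture_result <- function(x, ...) {
  cat(sprintf("admixture fit: K = %d, %d individuals, log-likelihood %.2f\n",
              x$K, nrow(x$Q), x$loglik))
  invisible(x)
}

# all permutations of 1..n (n small)
.permutations <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in .permutations(n - 1)) {
    for (pos in 0:(n - 1)) {
      out[[length(out) + 1]] <- append(p, n, after = pos)
    }
  }
  out
}

#' Align admixture replicates across label switchings
#'
#' Cluster labels are arbitrary per run; each run's columns are permuted to
#' maximize the summed per-individual dot product of its Q rows with the
#' first run's (the CLUMPP G-statistic analogue). Exhaustive over the K!
#' permutations for K <= 6, greedy matching beyond.
#'
#' @param runs list of [admixture_fit()] results sharing K and individuals.
#' @return list with `aligned` (the runs with permuted Q/P) and `mean_Q`.
#' @export
align_replicates <- function(runs) {
  K <- unique(vapply(runs, function(r) r$K, numeric(1)))
  if (length(K) != 1) stop("mixed K across runs")
  ns <- unique(vapply(runs, function(r) nrow(r$Q), numeric(1)))
  if (length(ns) != 1) stop("runs have different individuals")
  ref <- runs[[1]]$Q
  aligned <- runs
  for (i in seq_along(runs)[-1]) {
    Q <- runs[[i]]$Q
    M <- t(ref) %*% Q                       # M[a, b] = agreement ref a vs b
    if (K <= 6) {
      perms <- .permutations(K)
      scores <- vapply(perms, function(p) sum(M[cbind(seq_len(K), p)]),
                       numeric(1))
      perm <- perms[[which.max(scores)]]
    } else {
      perm <- integer(K); left <- seq_len(K)
      for (a in seq_len(K)) {
        b <- left[which.max(M[a, left])]
        perm[a] <- b; left <- setdiff(left, b)
      }
    }
    aligned[[i]]$Q <- Q[, perm, drop = FALSE]
    aligned[[i]]$P <- lapply(runs[[i]]$P, function(Pl)
      Pl[perm, , drop = FALSE])
  }
  mean_Q <- Reduce(`+`, lapply(aligned, function(r) r$Q)) / length(aligned)
  list(aligned = aligned, mean_Q = mean_Q)
}

#' Replicated admixture fits over a range of K
#'
#' Runs [admixture_fit()] `n_rep` times (distinct restart seeds) for every
#' K, the input Evanno's method needs.
#'
#' @param g a [genotype_matrix()].
#' @param K_range consecutive integers, e.g. `1:7`.
#' @param n_rep replicates per K (>= 2 for Delta-K).
#' @param seed integer seed.
#' @param ... passed to [admixture_fit()].
#' @return list with `loglik` (matrix replicates x K) and `runs` (list over
#'   K of replicate lists).
#' @export
admixture_replicates <- function(g, K_range, n_rep = 4, seed = 1, ...) {
  K_range <- sort(unique(as.integer(K_range)))
  runs <- vector("list", length(K_range))
  names(runs) <- as.character(K_range)
  ll <- matrix(NA_real_, n_rep, length(K_range),
               dimnames = list(NULL, as.character(K_range)))
  for (ki in seq_along(K_range)) {
    runs[[ki]] <- vector("list", n_rep)
    for (rep in seq_len(n_rep)) {
      fit <- admixture_fit(g, K_range[ki],
                           seed = .row_seed(seed, ki * 1000 + rep), ...)
      runs[[ki]][[rep]] <- fit
      ll[rep, ki] <- fit$loglik
    }
  }
  list(loglik = ll, runs = runs)
}

#' Evanno's Delta-K criterion for the number of clusters
#'
#' `DeltaK(K) = |mean L(K+1) - 2 mean L(K) + mean L(K-1)| / sd L(K)`,
#' defined for interior K only. Reports both the K maximizing the mean
#' log-likelihood and the K maximizing Delta-K.
#'
#' @param loglik matrix of log-likelihoods, replicates x K, with
#'   consecutive K values as column names (>= 3 columns, >= 2 rows).
#' @return object of class `k_selection`: per-K table with `mean_loglik`,
#'   `sd_loglik`, `delta_k`, plus `best_loglik_K` and `best_delta_K`.
#' @export
evanno_delta_k <- function(loglik) {
  loglik <- as.matrix(loglik)
  if (ncol(loglik) < 3) stop("need >= 3 consecutive K values")
  if (nrow(loglik) < 2) stop("need >= 2 replicates per K")
  Ks <- as.integer(colnames(loglik))
  if (any(is.na(Ks)) || any(diff(Ks) != 1L))
    stop("K values must be consecutive integers in column names")
  mu <- colMeans(loglik)
  sdv <- apply(loglik, 2, stats::sd)
  dk <- rep(NA_real_, length(Ks))
  for (i in 2:(length(Ks) - 1)) {
    if (sdv[i] == 0) {
      warning(sprintf("zero SD at K = %d: Delta-K undefined there", Ks[i]))
      next
    }
    dk[i] <- abs(mu[i + 1] - 2 * mu[i] + mu[i - 1]) / sdv[i]
  }
  tab <- data.frame(K = Ks, mean_loglik = mu, sd_loglik = sdv, delta_k = dk,
                    row.names = NULL)
  structure(list(table = tab,
                 best_loglik_K = Ks[which.max(mu)],
                 best_delta_K = if (all(is.na(dk))) NA_integer_
                                else Ks[which.max(dk)]),
            class = "k_selection")
}

#' @export
print.k_selection <- function(x, ...) {
  print(x$table, digits = 4, row.names = FALSE)
  cat(sprintf("max-likelihood K = %d; max Delta-K at K = %s\n",
              x$best_loglik_K, x$best_delta_K))
  invisible(x)
}

#' Write Q matrices in CLUMPP/STRUCTURE-compatible whitespace format
#' @param Q ancestry matrix (individuals x K).
#' @param path output file.
#' @param pop optional population labels.
#' @export
write_q_matrix <- function(Q, path, pop = NULL) {
  n <- nrow(Q)
  if (is.null(pop)) pop <- rep(1L, n)
  lines <- vapply(seq_len(n), function(i)
    sprintf("%d %d (0) %d : %s", i, i, as.integer(factor(pop))[i],
            paste(sprintf("%.4f", Q[i, ]), collapse = " ")),
    character(1))
  writeLines(lines, path)
  invisible(path)
}
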
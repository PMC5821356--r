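# Independent oracles used across the suite. These deliberately take
# different computational routes than the package internals.

# Brute-force Weir-Cockerham (1984) theta via the gene-copy ANOVA
# sums-of-squares decomposition (Weir 1996 formulation), combined across
# alleles and loci as ratio of summed variance components.
oracle_wc_theta <- function(g) {
  pops <- levels(g$pop)
  L <- dim(g$alleles)[2]
  num <- den <- 0
  for (l in seq_len(L)) {
    alleles <- sort(unique(stats::na.omit(c(g$alleles[, l, ]))))
    tabs <- lapply(pops, function(p) {
      rows <- which(g$pop == p)
      a1 <- g$alleles[rows, l, 1]; a2 <- g$alleles[rows, l, 2]
      ok <- !is.na(a1) & !is.na(a2)
      cbind(a1[ok], a2[ok])
    })
    ns <- vapply(tabs, nrow, integer(1))
    r <- length(pops)
    if (any(ns < 1)) next
    S <- sum(2 * ns)
    nc <- (S - sum((2 * ns)^2) / S) / (r - 1)
    for (A in alleles) {
      x <- lapply(tabs, function(t) rowSums(t == A))
      p_i <- vapply(x, function(v) mean(v) / 2, numeric(1))
      pbar <- sum(2 * ns * p_i) / S
      SSG <- sum(vapply(x, function(v) sum(v == 1), numeric(1))) / 2
      SSI <- sum(mapply(function(v, pi) sum(2 * (v / 2 - pi)^2), x, p_i))
      SSP <- sum(2 * ns * (p_i - pbar)^2)
      MSG <- SSG / sum(ns)
      MSI <- SSI / sum(ns - 1)
      MSP <- SSP / (r - 1)
      sG <- MSG
      sI <- (MSI - MSG) / 2
      sP <- (MSP - MSI) / nc
      num <- num + sP
      den <- den + sP + sI + sG
    }
  }
  num / den
}

# All-pairs shortest-path step counts by plain breadth-first search over
# the 0/1 mask (no igraph).
oracle_bfs_steps <- function(mask, from) {
  nr <- nrow(mask); nc <- ncol(mask)
  dist <- matrix(Inf, nr, nc)
  dist[from[1] + 1, from[2] + 1] <- 0
  queue <- list(from)
  while (length(queue) > 0) {
    cell <- queue[[1]]; queue <- queue[-1]
    d0 <- dist[cell[1] + 1, cell[2] + 1]
    for (step in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      nb <- cell + step
      if (nb[1] < 0 || nb[1] >= nr || nb[2] < 0 || nb[2] >= nc) next
      if (!mask[nb[1] + 1, nb[2] + 1]) next
      if (dist[nb[1] + 1, nb[2] + 1] > d0 + 1) {
        dist[nb[1] + 1, nb[2] + 1] <- d0 + 1
        queue[[length(queue) + 1]] <- nb
      }
    }
  }
  dist
}

# a small genotype_matrix from a list of per-population genotype matrices
# (each n_ind x 2, one locus) or per-locus lists
toy_genotypes <- function(pop_genos) {
  n_loci <- length(pop_genos[[1]])
  n_per <- vapply(pop_genos, function(p) nrow(p[[1]]), integer(1))
  n <- sum(n_per)
  al <- array(NA_integer_, c(n, n_loci, 2))
  ofs <- 0
  for (p in seq_along(pop_genos)) {
    for (l in seq_len(n_loci)) {
      al[ofs + seq_len(n_per[p]), l, ] <- pop_genos[[p]][[l]]
    }
    ofs <- ofs + n_per[p]
  }
  genotype_matrix(al, rep(sprintf("pop%02d", seq_along(pop_genos)),
                          times = n_per))
}

# study-condition priors scaled to the 30 x 10 corridor world: the onset
# prior is shortened so expansions equilibrate on a 4800-km strip, all
# other priors unchanged
corridor_prior <- function() {
  prior_config(T_mean_years = 50000, T_sd_years = 12000)
}

table1_like_params <- function(mu = 2.6e-4) {
  # point-estimate-like parameter set (per-deme carrying capacity)
  parameter_set(T_gen = 5290, N_i = 3952, N = 1124, r = 0.149, m = 0.041,
                mu = mu)
}
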
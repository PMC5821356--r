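# Per-population and pairwise microsatellite statistics, and the reduction
# of the full statistic set to the six "pattern" statistics used by the ABC.

# per population x locus: allele counts, per-allele heterozygote counts and
# typed sample sizes (individuals with both copies called)
.allele_tables <- function(g) {
  pops <- levels(g$pop)
  L <- dim(g$alleles)[2]
  out <- vector("list", length(pops))
  names(out) <- pops
  for (p in seq_along(pops)) {
    rows <- which(g$pop == pops[p])
    per_locus <- vector("list", L)
    for (l in seq_len(L)) {
      a1 <- g$alleles[rows, l, 1]; a2 <- g$alleles[rows, l, 2]
      ok <- !is.na(a1) & !is.na(a2)
      a1 <- a1[ok]; a2 <- a2[ok]
      if (length(a1) == 0L) { per_locus[l] <- list(NULL); next }
      cnt <- table(c(a1, a2))
      het <- table(factor(c(a1[a1 != a2], a2[a1 != a2]),
                          levels = names(cnt)))
      per_locus[[l]] <- list(n = length(a1), counts = cnt, het = het)
    }
    out[[p]] <- per_locus
  }
  out
}

#' Per-population diversity statistics
#'
#' For every population: mean number of distinct alleles per locus (A),
#' Nei's unbiased gene diversity (Hs), allelic richness rarefied to the
#' smallest typed gene-copy count in the dataset, and Garza-Williamson's M
#' (mean over loci of the allele count divided by the allele-length range
#' in repeat units plus one).
#'
#' @param g a [genotype_matrix()].
#' @return data.frame with columns `pop`, `A`, `Hs`, `richness`, `M`.
#' @export
per_population_stats <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  tabs <- .allele_tables(g)
  # rarefaction depth: smallest typed gene-copy count over pops x loci
  depths <- unlist(lapply(tabs, function(pl)
    vapply(pl, function(x) if (is.null(x)) NA_integer_ else 2L * x$n,
           integer(1))))
  if (all(is.na(depths))) stop("no typed locus in any population")
  if (anyNA(depths))
    warning("population with an all-missing locus: locus dropped there")
  gmin <- min(depths, na.rm = TRUE)

  res <- lapply(names(tabs), function(p) {
    pl <- tabs[[p]]
    pl <- pl[!vapply(pl, is.null, logical(1))]
    A <- vapply(pl, function(x) length(x$counts), numeric(1))
    Hs <- vapply(pl, function(x) {
      n <- 2 * x$n
      if (n < 2) return(NA_real_)
      pr <- as.numeric(x$counts) / n
      n / (n - 1) * (1 - sum(pr^2))
    }, numeric(1))
    rich <- vapply(pl, function(x) {
      n <- 2 * x$n
      cnt <- as.numeric(x$counts)
      # expected distinct alleles in a sample of gmin gene copies
      sum(1 - exp(lchoose(n - cnt, gmin) - lchoose(n, gmin)))
    }, numeric(1))
    M <- vapply(pl, function(x) {
      lens <- as.integer(names(x$counts))
      length(lens) / (diff(range(lens)) + 1)
    }, numeric(1))
    data.frame(pop = p, A = mean(A), Hs = mean(Hs, na.rm = TRUE),
               richness = mean(rich), M = mean(M))
  })
  out <- do.call(rbind, res)
  out$pop <- factor(out$pop, levels = levels(g$pop))
  out[order(out$pop), , drop = FALSE]
}

# Weir & Cockerham (1984) variance components for one pair of populations
# at one locus; returns c(sum_a, sum_abc) over alleles.
.wc_pair_locus <- function(t1, t2) {
  n1 <- t1$n; n2 <- t2$n
  if (n1 < 1 || n2 < 1) return(c(0, 0))
  alleles <- union(names(t1$counts), names(t2$counts))
  p1 <- as.numeric(t1$counts[alleles]) / (2 * n1); p1[is.na(p1)] <- 0
  p2 <- as.numeric(t2$counts[alleles]) / (2 * n2); p2[is.na(p2)] <- 0
  h1 <- as.numeric(t1$het[alleles]) / n1; h1[is.na(h1)] <- 0
  h2 <- as.numeric(t2$het[alleles]) / n2; h2[is.na(h2)] <- 0
  r <- 2
  nbar <- (n1 + n2) / 2
  if (nbar <= 1) return(c(0, 0))
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  c(sum(a), sum(a + b + cc))
}

#' Pairwise multi-locus Weir-Cockerham F_ST
#'
#' The Weir & Cockerham (1984) variance-components estimator theta for
#' every population pair, combined across loci as the ratio of summed
#' among-population components to summed total components. Negative
#' estimates are retained (not truncated), so ABC distances are not
#' distorted near zero differentiation.
#'
#' @param g a [genotype_matrix()] with at least two populations.
#' @return condensed vector of length `n(n-1)/2`, ordered like [stats::dist]
#'   (pair (i, j), i > j, j varying slowest).
#' @export
pairwise_fst <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  tabs <- .allele_tables(g)
  npop <- length(tabs)
  if (npop < 2) stop("need >= 2 populations")
  out <- numeric(npop * (npop - 1) / 2)
  idx <- 0L
  for (j in seq_len(npop - 1)) {
    for (i in (j + 1):npop) {
      idx <- idx + 1L
      num <- 0; den <- 0
      shared <- FALSE
      for (l in seq_along(tabs[[j]])) {
        t1 <- tabs[[j]][[l]]; t2 <- tabs[[i]][[l]]
        if (is.null(t1) || is.null(t2)) next
        shared <- TRUE
        ad <- .wc_pair_locus(t1, t2)
        num <- num + ad[1]; den <- den + ad[2]
      }
      if (!shared) stop("population pair with no shared typed locus")
      out[idx] <- if (den == 0) 0 else num / den
    }
  }
  out
}

#' Pairwise Cavalli-Sforza & Edwards chord distance
#'
#' Per locus `(2/pi) * sqrt(2 * (1 - sum_a sqrt(p1a * p2a)))`, averaged
#' across loci typed in both populations.
#'
#' @inheritParams pairwise_fst
#' @return condensed vector ordered like [stats::dist].
#' @export
chord_distance <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  tabs <- .allele_tables(g)
  npop <- length(tabs)
  if (npop < 2) stop("need >= 2 populations")
  out <- numeric(npop * (npop - 1) / 2)
  idx <- 0L
  for (j in seq_len(npop - 1)) {
    for (i in (j + 1):npop) {
      idx <- idx + 1L
      dl <- c()
      for (l in seq_along(tabs[[j]])) {
        t1 <- tabs[[j]][[l]]; t2 <- tabs[[i]][[l]]
        if (is.null(t1) || is.null(t2)) next
        alleles <- union(names(t1$counts), names(t2$counts))
        p1 <- as.numeric(t1$counts[alleles]) / (2 * t1$n); p1[is.na(p1)] <- 0
        p2 <- as.numeric(t2$counts[alleles]) / (2 * t2$n); p2[is.na(p2)] <- 0
        f <- sum(sqrt(p1 * p2))
        f <- min(f, 1)   # guard fp overshoot
        dl <- c(dl, 2 / pi * sqrt(2 * (1 - f)))
      }
      if (length(dl) == 0L) stop("population pair with no shared typed locus")
      out[idx] <- mean(dl)
    }
  }
  out
}

# simple OLS of y on x returning mean, slope, log10(SSR + eps)
.cline_fit <- function(y, x, eps = 1e-12) {
  xc <- x - mean(x)
  slope <- sum(xc * (y - mean(y))) / sum(xc^2)
  ssr <- sum((y - mean(y) - slope * xc)^2)
  c(mean = mean(y), slope = slope, logSSR = log10(ssr + eps))
}

#' The six pattern statistics
#'
#' Reduces the per-deme allele numbers and pairwise F_ST values to six
#' numbers via two ordinary least-squares cline regressions: A on distance
#' from the expansion origin, and pairwise F_ST on pairwise distance. For
#' each fit the mean of the response, the slope, and log10 of the sum of
#' squared residuals (+1e-12 guard for exact fits) are returned.
#'
#' @param A per-deme mean allele numbers.
#' @param fst condensed pairwise F_ST vector (length `n(n-1)/2`).
#' @param d_origin per-deme distances from the origin (km).
#' @param d_pairs condensed pairwise distances (km), same order as `fst`.
#' @return named numeric of length 6: `mean_A`, `slope_A`, `logSSR_A`,
#'   `mean_Fst`, `slope_Fst`, `logSSR_Fst`.
#' @export
pattern_statistics <- function(A, fst, d_origin, d_pairs) {
  n <- length(A)
  if (n < 3) stop("degenerate regression: need >= 3 demes")
  if (length(d_origin) != n) stop("A and d_origin lengths differ")
  if (length(fst) != n * (n - 1) / 2 || length(d_pairs) != length(fst))
    stop("condensed vector lengths inconsistent with deme count")
  fa <- .cline_fit(A, d_origin)
  ff <- .cline_fit(fst, d_pairs)
  c(mean_A = unname(fa[1]), slope_A = unname(fa[2]), logSSR_A = unname(fa[3]),
    mean_Fst = unname(ff[1]), slope_Fst = unname(ff[2]),
    logSSR_Fst = unname(ff[3]))
}

#' All summary statistics for a genotype matrix on a landscape
#'
#' Convenience wrapper: per-population statistics, pairwise F_ST and chord
#' distances, geographic distance vectors and the six pattern statistics.
#'
#' @param g a [genotype_matrix()].
#' @param landscape a [build_landscape()] object.
#' @param scheme the [sampling_scheme()] that produced `g` (population
#'   order must match).
#' @return list with `per_pop`, `fst`, `chord`, `distances`, `pattern`.
#' @export
summary_statistics <- function(g, landscape, scheme) {
  dv <- distance_vectors(landscape, scheme)
  pp <- per_population_stats(g)
  fst <- pairwise_fst(g)
  ch <- chord_distance(g)
  ps <- pattern_statistics(pp$A, fst, dv$from_origin, dv$pairwise)
  list(per_pop = pp, fst = fst, chord = ch, distances = dv, pattern = ps)
}

#' Write summary/pattern statistics as TSV
#' @param stats result of [summary_statistics()].
#' @param dir output directory (created if needed).
#' @export
write_sumstats <- function(stats, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(stats$per_pop, file.path(dir, "per_population.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(statistic = names(stats$pattern), value = stats$pattern),
    file.path(dir, "pattern_statistics.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(fst = stats$fst, chord = stats$chord,
               distance_km = stats$distances$pairwise),
    file.path(dir, "pairwise.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  invisible(dir)
}
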
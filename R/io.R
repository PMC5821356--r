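#' Write genotypes in STRUCTURE two-row format
#'
#' One diploid individual per two rows: individual label, population index,
#' then one allele per locus; missing data coded `-9`. A header row carries
#' the locus names.
#'
#' @param g a [genotype_matrix()].
#' @param path output file.
#' @export
write_structure <- function(g, path) {
  stopifnot(inherits(g, "genotype_matrix"))
  n <- dim(g$alleles)[1]
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste(g$loci, collapse = "\t"), con)
  pop_i <- as.integer(g$pop)
  labs <- sprintf("%s_%03d", as.character(g$pop), seq_len(n))
  for (i in seq_len(n)) {
    for (cp in 1:2) {
      al <- g$alleles[i, , cp]
      al[is.na(al)] <- -9L
      writeLines(paste(c(labs[i], pop_i[i], al), collapse = "\t"), con)
    }
  }
  invisible(path)
}

#' Read genotypes from STRUCTURE two-row format
#'
#' Expects the layout written by [write_structure()]: optional header of
#' locus names, then two rows per individual (label, population, alleles;
#' `-9` = missing).
#'
#' @param path input file.
#' @param header does the first line hold locus names?
#' @return a [genotype_matrix()].
#' @export
read_structure <- function(path, header = TRUE) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  loci <- NULL
  if (header) {
    loci <- strsplit(trimws(lines[1]), "\\s+")[[1]]
    lines <- lines[-1]
  }
  if (length(lines) %% 2L != 0L) stop("odd number of genotype rows")
  toks <- strsplit(trimws(lines), "\\s+")
  n_col <- unique(lengths(toks))
  if (length(n_col) != 1L) stop("ragged STRUCTURE rows")
  n_loci <- n_col - 2L
  if (!is.null(loci) && length(loci) != n_loci)
    stop("header does not match locus count")
  n <- length(lines) %/% 2L
  alleles <- array(NA_integer_, c(n, n_loci, 2L))
  pop <- character(n)
  for (i in seq_len(n)) {
    r1 <- toks[[2L * i - 1L]]; r2 <- toks[[2L * i]]
    if (r1[1] != r2[1]) stop("row pair labels differ: ", r1[1])
    pop[i] <- r1[2]
    a1 <- suppressWarnings(as.integer(r1[-(1:2)]))
    a2 <- suppressWarnings(as.integer(r2[-(1:2)]))
    a1[!is.na(a1) & a1 == -9L] <- NA_integer_
    a2[!is.na(a2) & a2 == -9L] <- NA_integer_
    alleles[i, , 1] <- a1; alleles[i, , 2] <- a2
  }
  genotype_matrix(alleles, pop, loci = loci)
}

#' Write genotypes as a long-form TSV
#'
#' Columns: individual, population, locus, allele1, allele2.
#' @inheritParams write_structure
#' @export
write_genotypes_tsv <- function(g, path) {
  stopifnot(inherits(g, "genotype_matrix"))
  n <- dim(g$alleles)[1]; L <- dim(g$alleles)[2]
  d <- data.frame(
    individual = rep(sprintf("%s_%03d", as.character(g$pop), seq_len(n)), L),
    population = rep(as.character(g$pop), L),
    locus = rep(g$loci, each = n),
    allele1 = as.vector(g$alleles[, , 1]),
    allele2 = as.vector(g$alleles[, , 2]))
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
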
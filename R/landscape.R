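#' Lattice landscape of square demes
#'
#' A landscape is a rectangular raster of square demes with a land/water
#' mask, a deme edge length in kilometres and an origin deme (the start of
#' the range expansion). Migration and distances operate on the 4-neighbour
#' (rook) topology; water cells are impassable.
#'
#' @param land_mask logical matrix; `TRUE` marks land cells. Row 1 is the
#'   top of the map.
#' @param origin integer vector `c(row, col)`, 0-based, addressing a land
#'   cell.
#' @param deme_edge_km edge length of a deme in km (default 160).
#' @return An object of class `landscape`: the mask, origin, edge length,
#'   a cell index for every land deme and the cached connected component of
#'   the origin.
#' @examples
#' L <- build_landscape(matrix(TRUE, 3, 3), origin = c(1, 1))
#' land_distance(L, c(0, 0), c(2, 2))  # 4 steps * 160 km
#' @export
build_landscape <- function(land_mask, origin, deme_edge_km = 160) {
  if (is.numeric(land_mask)) {
    storage.mode(land_mask) <- "logical"
  }
  stopifnot(is.matrix(land_mask), is.logical(land_mask))
  if (length(land_mask) == 0L) stop("empty raster")
  if (anyNA(land_mask)) stop("land mask contains NA")
  if (sum(land_mask) < 1L) stop("raster has no land")
  origin <- as.integer(origin)
  if (length(origin) != 2L) stop("origin must be c(row, col)")
  nr <- nrow(land_mask); nc <- ncol(land_mask)
  if (origin[1] < 0L || origin[1] >= nr || origin[2] < 0L || origin[2] >= nc)
    stop("origin outside raster")
  if (!land_mask[origin[1] + 1L, origin[2] + 1L]) stop("origin not on land")
  if (deme_edge_km <= 0) stop("deme_edge_km must be positive")

  cell_id <- matrix(NA_integer_, nr, nc)        # land cell -> 1..n_land
  cell_id[land_mask] <- seq_len(sum(land_mask))
  g <- .lattice_graph(land_mask, cell_id)
  origin_id <- cell_id[origin[1] + 1L, origin[2] + 1L]
  comp <- igraph::components(g)
  reach <- which(comp$membership == comp$membership[origin_id])

  structure(list(
    land_mask = land_mask,
    n_rows = nr, n_cols = nc,
    origin = origin,
    deme_edge_km = deme_edge_km,
    cell_id = cell_id,
    n_land = sum(land_mask),
    graph = g,
    origin_id = origin_id,
    reachable = reach
  ), class = "landscape")
}

# igraph over land cells, 4-neighbour edges
.lattice_graph <- function(land_mask, cell_id) {
  nr <- nrow(land_mask); nc <- ncol(land_mask)
  edges <- integer(0)
  if (nr > 1L) {
    v <- land_mask[-nr, , drop = FALSE] & land_mask[-1L, , drop = FALSE]
    a <- cell_id[-nr, , drop = FALSE][v]; b <- cell_id[-1L, , drop = FALSE][v]
    edges <- c(edges, rbind(a, b))
  }
  if (nc > 1L) {
    h <- land_mask[, -nc, drop = FALSE] & land_mask[, -1L, drop = FALSE]
    a <- cell_id[, -nc, drop = FALSE][h]; b <- cell_id[, -1L, drop = FALSE][h]
    edges <- c(edges, rbind(a, b))
  }
  igraph::make_graph(edges, n = sum(land_mask), directed = FALSE)
}

#' @export
print.landscape <- function(x, ...) {
  cat(sprintf("landscape: %d x %d raster, %d land demes (%.0f km edge)\n",
              x$n_rows, x$n_cols, x$n_land, x$deme_edge_km))
  cat(sprintf("origin: (%d, %d); %d demes reachable from origin\n",
              x$origin[1], x$origin[2], length(x$reachable)))
  invisible(x)
}

.cell_to_id <- function(landscape, cell) {
  cell <- as.integer(cell)
  if (cell[1] < 0L || cell[1] >= landscape$n_rows ||
      cell[2] < 0L || cell[2] >= landscape$n_cols)
    stop("cell outside raster")
  id <- landscape$cell_id[cell[1] + 1L, cell[2] + 1L]
  if (is.na(id)) stop(sprintf("cell (%d, %d) is not on land", cell[1], cell[2]))
  id
}

#' On-land geographic distance between two demes
#'
#' Distance is the number of 4-neighbour steps on the shortest all-land
#' path, multiplied by the deme edge length. It is a metric on each
#' connected land component.
#'
#' @param landscape a [build_landscape()] object.
#' @param a,b cells as 0-based `c(row, col)`.
#' @return distance in km.
#' @export
land_distance <- function(landscape, a, b) {
  ia <- .cell_to_id(landscape, a); ib <- .cell_to_id(landscape, b)
  d <- igraph::distances(landscape$graph, v = ia, to = ib)[1, 1]
  if (!is.finite(d)) stop("no on-land path")
  d * landscape$deme_edge_km
}

#' Sampling scheme over demes
#'
#' @param demes integer matrix or data.frame with columns `row`, `col`
#'   (0-based cells) — one row per sampled deme.
#' @param n_individuals diploid individuals sampled per deme (recycled).
#' @param names optional deme labels.
#' @return object of class `sampling_scheme`.
#' @export
sampling_scheme <- function(demes, n_individuals, names = NULL) {
  demes <- as.matrix(demes)[, 1:2, drop = FALSE]
  storage.mode(demes) <- "integer"
  n_individuals <- as.integer(rep(n_individuals, length.out = nrow(demes)))
  if (any(n_individuals < 1L)) stop("each deme needs >= 1 sampled individual")
  if (anyDuplicated(paste(demes[, 1], demes[, 2])))
    stop("sampled demes must be distinct")
  if (is.null(names)) names <- sprintf("pop%02d", seq_len(nrow(demes)))
  structure(list(demes = demes, n_individuals = n_individuals,
                 names = as.character(names)),
            class = "sampling_scheme")
}

#' @export
print.sampling_scheme <- function(x, ...) {
  cat(sprintf("sampling scheme: %d demes, %d diploid individuals\n",
              nrow(x$demes), sum(x$n_individuals)))
  invisible(x)
}

# validate a scheme against a landscape; returns land-cell ids
.scheme_ids <- function(landscape, scheme) {
  ids <- vapply(seq_len(nrow(scheme$demes)), function(i)
    .cell_to_id(landscape, scheme$demes[i, ]), integer(1))
  if (!all(ids %in% landscape$reachable))
    stop("sampled deme not reachable from origin through land")
  ids
}

#' Geographic distance vectors for a sampling scheme
#'
#' Computes every sampled deme's on-land distance from the expansion
#' origin and the condensed matrix of pairwise on-land distances — the
#' regressors of the two cline regressions.
#'
#' @inheritParams land_distance
#' @param scheme a [sampling_scheme()].
#' @return list with `from_origin` (length n) and `pairwise` (length
#'   n(n-1)/2, ordered as `dist`: pair (i,j), i < j, j fastest).
#' @export
distance_vectors <- function(landscape, scheme) {
  ids <- .scheme_ids(landscape, scheme)
  km <- landscape$deme_edge_km
  d0 <- igraph::distances(landscape$graph, v = landscape$origin_id, to = ids)[1, ]
  dp <- igraph::distances(landscape$graph, v = ids, to = ids)
  if (any(!is.finite(d0)) || any(!is.finite(dp))) stop("no on-land path")
  list(from_origin = unname(d0) * km,
       pairwise = dp[lower.tri(dp)] * km)
}

#' Read a land-mask raster
#'
#' Accepts a plain-text grid of `0`/`1` characters (one raster row per
#' line, optional whitespace between cells) or an ASCII PGM (`P2`) image
#' in which non-zero pixels are land.
#'
#' @param path file path.
#' @return logical matrix suitable for [build_landscape()].
#' @examples
#' mask <- read_land_mask(system.file("extdata", "two_continents_mask.txt",
#'                                    package = "demicabc"))
#' L <- build_landscape(mask, origin = c(5, 2))
#' @export
read_land_mask <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty raster file")
  if (trimws(lines[1]) == "P2") {
    body <- lines[-1]
    body <- body[!startsWith(trimws(body), "#")]
    vals <- as.integer(unlist(strsplit(paste(body, collapse = " "), "\\s+")))
    vals <- vals[!is.na(vals)]
    nc <- vals[1]; nr <- vals[2]
    px <- vals[-(1:3)]
    if (length(px) != nr * nc) stop("malformed PGM raster")
    return(matrix(px > 0L, nrow = nr, ncol = nc, byrow = TRUE))
  }
  rows <- lapply(lines, function(l) {
    ch <- strsplit(gsub("\\s", "", l), "")[[1]]
    if (!all(ch %in% c("0", "1"))) stop("raster rows must contain only 0/1")
    ch == "1"
  })
  if (length(unique(lengths(rows))) != 1L) stop("raster not rectangular")
  do.call(rbind, rows)
}

#' Write a land mask as a 0/1 text raster
#' @param land_mask logical matrix.
#' @param path output file.
#' @export
write_land_mask <- function(land_mask, path) {
  writeLines(apply(land_mask, 1, function(r) paste(as.integer(r), collapse = "")),
             path)
}

#' Read/write a sampling scheme as TSV
#'
#' Columns: `deme_row`, `deme_col` (0-based), `n_individuals`, `name`.
#' @param path file path.
#' @return a [sampling_scheme()].
#' @export
read_sampling_scheme <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("deme_row", "deme_col", "n_individuals", "name")
  if (!all(need %in% names(d))) stop("scheme TSV must have columns ",
                                     paste(need, collapse = ", "))
  sampling_scheme(cbind(d$deme_row, d$deme_col), d$n_individuals, d$name)
}

#' @rdname read_sampling_scheme
#' @param scheme a [sampling_scheme()].
#' @export
write_sampling_scheme <- function(scheme, path) {
  utils::write.table(
    data.frame(deme_row = scheme$demes[, 1], deme_col = scheme$demes[, 2],
               n_individuals = scheme$n_individuals, name = scheme$names),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
}
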
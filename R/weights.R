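#' Spatial weights objects
#'
#' A `spweights` object stores a neighbour structure: ordered unit ids,
#' per-unit neighbour index vectors, matching nonnegative weights, the
#' construction scheme (queen contiguity or k nearest neighbours) and the
#' weighting style (binary or row-standardised).
#'
#' @name spweights
NULL

new_spweights <- function(ids, nb, w, scheme, style, k = NULL) {
  structure(list(ids = ids, nb = nb, w = w, scheme = scheme, style = style,
                 k = k), class = "spweights")
}

#' Queen-contiguity weights from tract polygons
#'
#' Two tracts are neighbours if their polygons share at least one boundary
#' point (including a single corner). Shared points are detected by snapping
#' ring vertices to a tolerance grid and additionally testing vertices of one
#' polygon that lie on a boundary segment of another, which is exact for
#' tiling polygons such as census geographies. Islands (units with no
#' neighbours) are allowed with a warning.
#'
#' @param tracts data.frame with `tract_id` and a `geometry` list-column of
#'   closed rings (x/y matrices), e.g. from [generate_tracts()] or
#'   [read_tracts_geojson()].
#' @param snap Snapping tolerance in coordinate units.
#' @return A binary [spweights] object (symmetric).
#' @examples
#' tr <- generate_tracts(county_config(n_rows = 3, n_cols = 3, sra_block = 3))
#' W <- queen_weights(tr)
#' lengths(W$nb)[5]  # centre cell of a 3x3 grid has 8 neighbours
#' @export
queen_weights <- function(tracts, snap = 1e-6) {
  ids <- tracts$tract_id
  if (anyDuplicated(ids)) stop("duplicate tract ids", call. = FALSE)
  n <- length(ids)
  geom <- tracts$geometry
  # candidate pairs via snapped shared vertices
  keys <- lapply(geom, function(r) {
    v <- unique(round(r / snap))
    paste(v[, 1], v[, 2], sep = ",")
  })
  vert_map <- new.env(parent = emptyenv())
  for (i in seq_len(n)) for (k in keys[[i]]) {
    vert_map[[k]] <- c(vert_map[[k]], i)
  }
  adj <- vector("list", n)
  for (k in ls(vert_map)) {
    units <- unique(vert_map[[k]])
    if (length(units) > 1)
      for (i in units) adj[[i]] <- c(adj[[i]], setdiff(units, i))
  }
  # vertices on another polygon's edge (T-junctions); check bbox-close pairs
  bb <- t(vapply(geom, function(r) c(min(r[, 1]), max(r[, 1]),
                                     min(r[, 2]), max(r[, 2])), numeric(4)))
  for (i in seq_len(n)) {
    cand <- which(bb[, 1] <= bb[i, 2] + snap & bb[, 2] >= bb[i, 1] - snap &
                  bb[, 3] <= bb[i, 4] + snap & bb[, 4] >= bb[i, 3] - snap)
    cand <- setdiff(cand, c(i, adj[[i]]))
    for (j in cand) {
      if (point_on_boundary(geom[[i]], geom[[j]], snap) ||
          point_on_boundary(geom[[j]], geom[[i]], snap)) {
        adj[[i]] <- c(adj[[i]], j)
        adj[[j]] <- c(adj[[j]], i)
      }
    }
  }
  nb <- lapply(adj, function(v) sort(unique(v)))
  if (any(lengths(nb) == 0))
    warning(sum(lengths(nb) == 0), " island unit(s) with no neighbours")
  new_spweights(ids, nb, lapply(nb, function(v) rep(1, length(v))),
                scheme = "queen", style = "binary")
}

# TRUE if any vertex of ring a lies on a boundary segment of ring b
point_on_boundary <- function(a, b, tol) {
  for (s in seq_len(nrow(b) - 1)) {
    p <- b[s, ]; q <- b[s + 1, ]
    d <- q - p; len2 <- sum(d^2)
    if (len2 == 0) next
    t <- ((a[, 1] - p[1]) * d[1] + (a[, 2] - p[2]) * d[2]) / len2
    t <- pmin(1, pmax(0, t))
    dx <- p[1] + t * d[1] - a[, 1]
    dy <- p[2] + t * d[2] - a[, 2]
    if (any(dx * dx + dy * dy <= tol * tol)) return(TRUE)
  }
  FALSE
}

#' k-nearest-neighbour weights from tract centroids
#'
#' Each unit's `k` nearest centroids by Euclidean distance become its
#' neighbours (a directed relation; symmetry is not enforced). Distance ties
#' are broken in favour of the smaller tract id.
#'
#' @param tracts data.frame with `tract_id` and either a `geometry`
#'   list-column (centroids computed) or `x`/`y` centroid columns.
#' @param k Number of neighbours; must be smaller than the number of units.
#' @return A binary [spweights] object.
#' @export
knn_weights <- function(tracts, k = 8) {
  ids <- tracts$tract_id
  if (anyDuplicated(ids)) stop("duplicate tract ids", call. = FALSE)
  n <- length(ids)
  if (k >= n) stop("k must be smaller than the number of units", call. = FALSE)
  if (!is.null(tracts$geometry)) {
    ctr <- t(vapply(tracts$geometry, polygon_centroid, numeric(2)))
  } else {
    ctr <- cbind(tracts$x, tracts$y)
  }
  ord_id <- order(ids)  # rank of each id for tie-breaking
  id_rank <- match(seq_len(n), ord_id)
  nb <- vector("list", n)
  for (i in seq_len(n)) {
    d <- sqrt((ctr[, 1] - ctr[i, 1])^2 + (ctr[, 2] - ctr[i, 2])^2)
    d[i] <- Inf
    o <- order(d, id_rank)
    nb[[i]] <- sort(o[seq_len(k)])
  }
  new_spweights(ids, nb, lapply(nb, function(v) rep(1, length(v))),
                scheme = "knn", style = "binary", k = as.integer(k))
}

#' Row-standardise a spatial weights object
#'
#' Divides each nonempty row of weights by its sum so rows sum to one;
#' empty (island) rows are left unchanged. Idempotent.
#'
#' @param W A [spweights] object.
#' @return The row-standardised [spweights] object.
#' @export
row_standardize <- function(W) {
  W$w <- lapply(W$w, function(v) if (length(v) && sum(v) > 0) v / sum(v) else v)
  W$style <- "row_standardized"
  W
}

#' Dense matrix form of a spatial weights object
#'
#' @param W A [spweights] object.
#' @return An n x n numeric matrix with ids as dimnames.
#' @export
weights_matrix <- function(W) {
  n <- length(W$ids)
  m <- matrix(0, n, n, dimnames = list(W$ids, W$ids))
  for (i in seq_len(n)) m[i, W$nb[[i]]] <- W$w[[i]]
  m
}

#' Subset a spatial weights object to a set of units
#'
#' Drops all other units and their incident links; if the input was
#' row-standardised the result is re-standardised over the surviving
#' neighbours.
#'
#' @param W A [spweights] object.
#' @param keep Integer indices or logical vector of units to keep.
#' @return A [spweights] object over the kept units, in the original order.
#' @export
subset_weights <- function(W, keep) {
  idx <- seq_along(W$ids)[keep]
  remap <- match(seq_along(W$ids), idx)
  nb <- vector("list", length(idx)); w <- vector("list", length(idx))
  for (new_i in seq_along(idx)) {
    old <- idx[new_i]
    sel <- !is.na(remap[W$nb[[old]]])
    nb[[new_i]] <- remap[W$nb[[old]][sel]]
    w[[new_i]] <- W$w[[old]][sel]
  }
  out <- new_spweights(W$ids[idx], nb, w, W$scheme, "binary", W$k)
  if (identical(W$style, "row_standardized")) out <- row_standardize(out)
  out
}

#' @export
print.spweights <- function(x, ...) {
  n <- length(x$ids)
  cat(sprintf("Spatial weights: %d units, scheme %s%s, style %s\n", n,
              x$scheme, if (!is.null(x$k)) sprintf(" (k = %d)", x$k) else "",
              x$style))
  cat(sprintf("  links: %d; avg neighbours %.2f; islands %d\n",
              sum(lengths(x$nb)), mean(lengths(x$nb)), sum(lengths(x$nb) == 0)))
  invisible(x)
}

#' Export spatial weights as a sparse triplet table or neighbour list
#'
#' @param W A [spweights] object.
#' @param path Output file. `write_weights_csv()` writes columns
#'   `i`, `j`, `w` (unit ids); `write_weights_json()` writes a JSON object
#'   mapping each id to its neighbour ids and weights.
#' @return `path`, invisibly.
#' @export
write_weights_csv <- function(W, path) {
  i <- rep(W$ids, lengths(W$nb))
  j <- W$ids[unlist(W$nb)]
  w <- unlist(W$w)
  utils::write.csv(data.frame(i = i, j = j %||% character(), w = w %||% numeric()),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_weights_csv
#' @export
write_weights_json <- function(W, path) {
  obj <- stats::setNames(lapply(seq_along(W$ids), function(i) {
    list(neighbors = W$ids[W$nb[[i]]], weights = W$w[[i]])
  }), W$ids)
  jsonlite::write_json(list(scheme = W$scheme, style = W$style,
                            k = W$k, units = obj),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
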
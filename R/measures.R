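#' Count classified outlets by tract
#'
#' Assigns every retained restaurant or grocery outlet to exactly one tract
#' by point-in-polygon (boundary points go to the covering tract with the
#' lexicographically smallest id); outlets falling outside all tracts are
#' dropped and counted.
#'
#' @param groups An [classify_outlets()] result (needs `x`, `y`, `group`).
#' @param tracts Tract data.frame with `tract_id` and `geometry`.
#' @return data.frame with `tract_id`, `n_aapi_rest`, `n_nonaapi_rest`,
#'   `n_aapi_groc`, `n_nonaapi_groc` (one row per tract) and attribute
#'   `n_outside` (dropped outlets).
#' @export
count_outlets_by_tract <- function(groups, tracts) {
  check_crs(groups, tracts, "outlets and tracts")
  keep <- !is.na(groups$group) & groups$group != "neither"
  pts <- groups[keep, , drop = FALSE]
  n_t <- nrow(tracts)
  bb <- t(vapply(tracts$geometry, function(r)
    c(min(r[, 1]), max(r[, 1]), min(r[, 2]), max(r[, 2])), numeric(4)))
  ord <- order(tracts$tract_id)  # search in id order so first hit = smallest id
  assigned <- rep(NA_integer_, nrow(pts))
  for (p in seq_len(nrow(pts))) {
    x <- pts$x[p]; y <- pts$y[p]
    for (i in ord) {
      if (x < bb[i, 1] || x > bb[i, 2] || y < bb[i, 3] || y > bb[i, 4]) next
      ring <- tracts$geometry[[i]]
      if (pracma::inpolygon(x, y, ring[, 1], ring[, 2], boundary = TRUE)) {
        assigned[p] <- i
        break
      }
    }
  }
  n_outside <- sum(is.na(assigned))
  if (n_outside > 0)
    message(n_outside, " outlet(s) outside all tracts dropped")
  cnt <- function(g) {
    tab <- table(factor(assigned[pts$group == g & !is.na(assigned)],
                        levels = seq_len(n_t)))
    as.integer(tab)
  }
  out <- data.frame(tract_id = tracts$tract_id,
                    n_aapi_rest = cnt("aapi_restaurants"),
                    n_nonaapi_rest = cnt("non_aapi_restaurants"),
                    n_aapi_groc = cnt("aapi_groceries"),
                    n_nonaapi_groc = cnt("non_aapi_groceries"),
                    stringsAsFactors = FALSE)
  attr(out, "n_outside") <- n_outside
  out
}

#' Relative food environment: AAPI to non-AAPI outlet ratios
#'
#' Ratio of AAPI to non-AAPI counts per outlet kind. A 0/0 tract is 0 (no
#' AAPI outlets); a positive count over zero non-AAPI outlets is undefined
#' and returned as `NA` with a flag, since no finite ratio describes it.
#'
#' @param counts Output of [count_outlets_by_tract()].
#' @return `counts` with added `rest_ratio`, `groc_ratio` and logical
#'   `rest_ratio_missing`, `groc_ratio_missing` columns.
#' @export
relative_environment <- function(counts) {
  safe_ratio <- function(a, b) ifelse(b > 0, a / b, ifelse(a == 0, 0, NA_real_))
  counts$rest_ratio <- safe_ratio(counts$n_aapi_rest, counts$n_nonaapi_rest)
  counts$groc_ratio <- safe_ratio(counts$n_aapi_groc, counts$n_nonaapi_groc)
  counts$rest_ratio_missing <- is.na(counts$rest_ratio)
  counts$groc_ratio_missing <- is.na(counts$groc_ratio)
  counts
}

#' Outlets per capita: AAPI outlets per AAPI resident
#'
#' AAPI outlet count divided by the tract AAPI population (per person; scale
#' by 1000 for the per-1000 reading). A 0-count, 0-population tract is 0; a
#' positive count with zero population is undefined (`NA`, flagged).
#'
#' @param counts Output of [count_outlets_by_tract()].
#' @param pop_aapi Nonnegative AAPI population aligned with `counts` rows.
#' @return `counts` with added `rest_per_aapi`, `groc_per_aapi` and
#'   missingness flags.
#' @export
per_capita <- function(counts, pop_aapi) {
  if (any(pop_aapi < 0)) stop("pop_aapi must be nonnegative", call. = FALSE)
  safe_pc <- function(cnt, pop) ifelse(pop > 0, cnt / pop,
                                       ifelse(cnt == 0, 0, NA_real_))
  counts$rest_per_aapi <- safe_pc(counts$n_aapi_rest, pop_aapi)
  counts$groc_per_aapi <- safe_pc(counts$n_aapi_groc, pop_aapi)
  counts$rest_per_aapi_missing <- is.na(counts$rest_per_aapi)
  counts$groc_per_aapi_missing <- is.na(counts$groc_per_aapi)
  counts
}

#' Outlet intensity: tract share of the county AAPI outlet total
#'
#' Tract AAPI outlet count divided by the county total of that kind;
#' intensities sum to one over tracts when the county total is positive. An
#' all-zero county yields all-zero intensities with a warning.
#'
#' @param counts Output of [count_outlets_by_tract()].
#' @return `counts` with added `rest_intensity`, `groc_intensity`.
#' @export
intensity <- function(counts) {
  share <- function(cnt, what) {
    tot <- sum(cnt)
    if (tot == 0) {
      warning("county total of ", what, " is zero; intensities set to 0")
      rep(0, length(cnt))
    } else cnt / tot
  }
  counts$rest_intensity <- share(counts$n_aapi_rest, "AAPI restaurants")
  counts$groc_intensity <- share(counts$n_aapi_groc, "AAPI groceries")
  counts
}

#' Share of population beyond a distance threshold from a supermarket
#'
#' For each representative population point, computes the Euclidean distance
#' to the nearest supermarket; the tract share is the population weight of
#' points strictly beyond the threshold, as a percent of the tract
#' population. Computed for the total population (`fara_ct`) and the AAPI
#' population (`fara_aapi`). With no supermarkets every positive-population
#' tract is 100; zero-population tracts are `NA`.
#'
#' @param tracts Tract data.frame (`tract_id`, `pop_total`, `pop_aapi`).
#' @param pop_points Output of [generate_population_points()] (or a
#'   compatible table with `tract_id`, `x`, `y`, `weight_total`,
#'   `weight_aapi`).
#' @param supermarkets data.frame with `x`, `y`; may be empty.
#' @param threshold Distance threshold in coordinate units; default 804.672 m
#'   (half a mile).
#' @return data.frame `tract_id`, `fara_ct`, `fara_aapi`.
#' @export
share_beyond <- function(tracts, pop_points, supermarkets,
                         threshold = 804.672) {
  if (!is.finite(threshold) || threshold <= 0)
    stop("`threshold` must be > 0", call. = FALSE)
  check_crs(pop_points, supermarkets, "population points and supermarkets")
  if (nrow(supermarkets) == 0) {
    beyond <- rep(TRUE, nrow(pop_points))
  } else {
    d2min <- rep(Inf, nrow(pop_points))
    for (s in seq_len(nrow(supermarkets))) {
      d2 <- (pop_points$x - supermarkets$x[s])^2 +
            (pop_points$y - supermarkets$y[s])^2
      d2min <- pmin(d2min, d2)
    }
    beyond <- sqrt(d2min) > threshold
  }
  bt <- tapply(pop_points$weight_total * beyond, pop_points$tract_id, sum)
  ba <- tapply(pop_points$weight_aapi * beyond, pop_points$tract_id, sum)
  i <- match(tracts$tract_id, names(bt))
  fara_ct <- ifelse(tracts$pop_total > 0,
                    100 * as.numeric(bt)[i] / tracts$pop_total, NA_real_)
  fara_aapi <- ifelse(tracts$pop_aapi > 0,
                      100 * as.numeric(ba)[i] / tracts$pop_aapi, NA_real_)
  data.frame(tract_id = tracts$tract_id, fara_ct = fara_ct,
             fara_aapi = fara_aapi, stringsAsFactors = FALSE)
}

#' Compute the full tract-level access-measure table
#'
#' Convenience wrapper: counts outlets by tract, then derives the six
#' ethnic-store measures (two ratios, two per-capita rates, two intensities)
#' and the two supermarket-distance shares.
#'
#' @param tracts Tract data.frame.
#' @param groups Classified outlets ([classify_outlets()]).
#' @param pop_points Representative population points.
#' @param supermarkets Supermarket points.
#' @param threshold Distance threshold in metres (default half a mile).
#' @return data.frame with one row per tract: counts, `rest_ratio`,
#'   `groc_ratio`, `rest_per_aapi`, `groc_per_aapi`, `rest_intensity`,
#'   `groc_intensity`, `fara_ct`, `fara_aapi`, and missingness flags.
#' @export
access_measures <- function(tracts, groups, pop_points, supermarkets,
                            threshold = 804.672) {
  counts <- count_outlets_by_tract(groups, tracts)
  counts <- relative_environment(counts)
  counts <- per_capita(counts, tracts$pop_aapi)
  counts <- intensity(counts)
  fara <- share_beyond(tracts, pop_points, supermarkets, threshold)
  out <- merge(counts, fara, by = "tract_id", sort = FALSE)
  out <- out[match(tracts$tract_id, out$tract_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_outside") <- attr(counts, "n_outside")
  out
}
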
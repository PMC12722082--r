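# internal helpers shared across modules

# deterministic per-stage seed derived from one root seed; keeps all
# stage-level randomness reproducible and below .Machine$integer.max
stage_seed <- function(seed, stage) {
  offsets <- c(tracts = 11L, points = 23L, outlets = 37L, supermarkets = 53L,
               cases = 71L, moran = 89L, battery = 101L, pipeline = 113L)
  off <- offsets[[stage]]
  as.integer((as.numeric(seed) * 2654435761 + off * 97) %% 2147483629) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_field <- function(field, msg) {
  stop(sprintf("invalid configuration: `%s` %s", field, msg), call. = FALSE)
}

# centroid of a simple closed polygon ring (shoelace-based)
polygon_centroid <- function(ring) {
  x <- as.numeric(ring[, 1]); y <- as.numeric(ring[, 2])
  n <- nrow(ring)
  if (x[1] != x[n] || y[1] != y[n]) { x <- c(x, x[1]); y <- c(y, y[1]); n <- n + 1 }
  cr <- x[-n] * y[-1] - x[-1] * y[-n]
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps) return(c(mean(x[-n]), mean(y[-n])))
  cx <- sum((x[-n] + x[-1]) * cr) / (6 * a)
  cy <- sum((y[-n] + y[-1]) * cr) / (6 * a)
  c(cx, cy)
}

check_crs <- function(a, b, what = "inputs") {
  ca <- attr(a, "crs"); cb <- attr(b, "crs")
  if (!is.null(ca) && !is.null(cb) && !identical(ca, cb)) {
    stop(sprintf("coordinate system mismatch between %s ('%s' vs '%s')",
                 what, ca, cb), call. = FALSE)
  }
  invisible(TRUE)
}
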
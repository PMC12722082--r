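#' Global Moran's I with normal or permutation inference
#'
#' Computes `I = (n / S0) * sum_ij w_ij z_i z_j / sum_i z_i^2` with
#' `z = x - mean(x)` and `S0` the sum of all weights. Under the
#' no-autocorrelation null the expectation is `-1/(n-1)`. Inference is either
#' the analytic normal approximation (Cliff-Ord moments under the normality
#' assumption) or a random-permutation test with pseudo p-value
#' `(1 + #{|I_perm - E| >= |I_obs - E|}) / (n_permutations + 1)`.
#' Missing values are dropped listwise with the weights subset (and
#' re-standardised if they were row-standardised).
#'
#' @param x Numeric vector aligned with `W$ids`.
#' @param W A [spweights] object.
#' @param method `"permutation"` (default) or `"normal"`.
#' @param n_permutations Number of permutations (permutation method).
#' @param seed Integer seed for the permutation draw.
#' @return An object of class `moran_test`: list with `I`, `expected`,
#'   `variance` (normal method), `z`, `p_value`, `method`, `n_permutations`,
#'   `seed`, `n`.
#' @examples
#' tr <- generate_tracts(county_config(n_rows = 5, n_cols = 5, sra_block = 5))
#' W <- row_standardize(queen_weights(tr))
#' morans_i(tr$pop_density, W, method = "normal")
#' @export
morans_i <- function(x, W, method = c("permutation", "normal"),
                     n_permutations = 999, seed = 1L) {
  method <- match.arg(method)
  if (length(x) != length(W$ids))
    stop("`x` must align with `W$ids`", call. = FALSE)
  keep <- !is.na(x)
  if (!all(keep)) {
    x <- x[keep]
    W <- subset_weights(W, keep)
  }
  n <- length(x)
  if (n < 3) stop("need at least 3 non-missing units", call. = FALSE)
  if (stats::sd(x) == 0)
    stop("Moran's I undefined: `x` has zero variance", call. = FALSE)

  Wm <- weights_matrix(W)
  z <- x - mean(x)
  S0 <- sum(Wm)
  ss <- sum(z^2)
  I_of <- function(z) (n / S0) * as.numeric(crossprod(z, Wm %*% z)) / sum(z^2)
  I_obs <- (n / S0) * as.numeric(crossprod(z, Wm %*% z)) / ss
  E <- -1 / (n - 1)

  if (method == "normal") {
    S1 <- sum((Wm + t(Wm))^2) / 2
    S2 <- sum((rowSums(Wm) + colSums(Wm))^2)
    varI <- (n^2 * S1 - n * S2 + 3 * S0^2) / (S0^2 * (n^2 - 1)) - E^2
    zstat <- (I_obs - E) / sqrt(varI)
    p <- 2 * stats::pnorm(-abs(zstat))
    res <- list(I = I_obs, expected = E, variance = varI, z = zstat,
                p_value = p, method = "normal", n_permutations = NA_integer_,
                seed = NA_integer_, n = n)
  } else {
    set.seed(seed)
    perm <- replicate(n_permutations, I_of(sample(z)))
    extreme <- sum(abs(perm - E) >= abs(I_obs - E))
    p <- (1 + extreme) / (n_permutations + 1)
    varI <- stats::var(perm)
    res <- list(I = I_obs, expected = E, variance = varI,
                z = (I_obs - E) / sqrt(varI), p_value = p,
                method = "permutation", n_permutations = n_permutations,
                seed = as.integer(seed), n = n)
  }
  class(res) <- "moran_test"
  res
}

#' @export
print.moran_test <- function(x, ...) {
  cat("Global Moran's I\n")
  cat(sprintf("  I = %.4f  (expected %.4f under the null), n = %d\n",
              x$I, x$expected, x$n))
  if (x$method == "normal") {
    cat(sprintf("  normal approximation: variance %.6f, z = %.3f, p = %.4g\n",
                x$variance, x$z, x$p_value))
  } else {
    cat(sprintf("  permutation test (%d draws, seed %d): p = %.4g\n",
                x$n_permutations, x$seed, x$p_value))
  }
  invisible(x)
}

#' Moran's I for several variables at once
#'
#' @param data data.frame of tract-aligned variables.
#' @param vars Column names to test.
#' @param W A [spweights] object aligned with `data` rows.
#' @inheritParams morans_i
#' @return data.frame with one row per variable: `variable`, `I`, `expected`,
#'   `z`, `p_value`, `n`.
#' @export
moran_report <- function(data, vars, W, method = "permutation",
                         n_permutations = 999, seed = 1L) {
  rows <- lapply(vars, function(v) {
    tryCatch({
      m <- morans_i(data[[v]], W, method = method,
                    n_permutations = n_permutations, seed = seed)
      data.frame(variable = v, I = m$I, expected = m$expected, z = m$z,
                 p_value = m$p_value, n = m$n, stringsAsFactors = FALSE)
    }, error = function(e) {
      warning(sprintf("Moran's I undefined for '%s': %s", v,
                      conditionMessage(e)))
      data.frame(variable = v, I = NA_real_, expected = NA_real_,
                 z = NA_real_, p_value = NA_real_, n = NA_integer_,
                 stringsAsFactors = FALSE)
    })
  })
  do.call(rbind, rows)
}
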
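#' Z-score standardisation
#'
#' Centres to mean zero and scales to unit sample standard deviation
#' (n - 1 denominator). Missing values are ignored in the moments and
#' propagate through the output.
#'
#' @param x Numeric vector with positive variance.
#' @return Standardised numeric vector.
#' @examples
#' zscore(c(1, 2, 3))  # -1 0 1
#' @export
zscore <- function(x) {
  s <- stats::sd(x, na.rm = TRUE)
  if (is.na(s) || s == 0)
    stop("zscore undefined: zero or undefined variance", call. = FALSE)
  (x - mean(x, na.rm = TRUE)) / s
}

#' Pearson correlation with a t-based two-sided p-value
#'
#' @param x,y Numeric vectors with positive variance; pairs with missing
#'   values are dropped.
#' @return List with `r` and `p_value` (t test on n - 2 df).
#' @export
pearson_r <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("Pearson r undefined: zero variance", call. = FALSE)
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Spearman correlation screen for collinear variables
#'
#' Computes the pairwise-complete Spearman rank correlation matrix and
#' applies a greedy screen: scanning pairs in input column order, whenever
#' `|rho| > threshold` the later column is dropped. Constant columns have
#' undefined correlations and never trigger a drop.
#'
#' @param data data.frame (or matrix) of at least two numeric variables.
#' @param threshold Absolute correlation above which the later variable is
#'   dropped (default 0.90).
#' @return List with `correlations` (Spearman matrix), `dropped` (data.frame
#'   `variable`, `correlated_with`, `rho`) and `kept` (surviving column
#'   names).
#' @export
spearman_screen <- function(data, threshold = 0.90) {
  data <- as.data.frame(data)
  if (ncol(data) < 2) stop("need at least 2 variables", call. = FALSE)
  suppressWarnings(
    rho <- stats::cor(data, method = "spearman", use = "pairwise.complete.obs"))
  const <- vapply(data, function(v) {
    s <- stats::sd(v, na.rm = TRUE); is.na(s) || s == 0
  }, logical(1))
  rho[const, ] <- NA_real_
  rho[, const] <- NA_real_
  diag(rho) <- 1
  p <- ncol(data)
  dropped <- logical(p)
  rec <- list()
  for (j1 in seq_len(p - 1)) {
    if (dropped[j1]) next
    for (j2 in seq((j1 + 1), p)) {
      if (dropped[j2]) next
      r <- rho[j1, j2]
      if (!is.na(r) && abs(r) > threshold) {
        dropped[j2] <- TRUE
        rec[[length(rec) + 1]] <- data.frame(
          variable = colnames(data)[j2],
          correlated_with = colnames(data)[j1],
          rho = r, stringsAsFactors = FALSE)
      }
    }
  }
  list(correlations = rho,
       dropped = if (length(rec)) do.call(rbind, rec)
                 else data.frame(variable = character(),
                                 correlated_with = character(),
                                 rho = numeric(), stringsAsFactors = FALSE),
       kept = colnames(data)[!dropped])
}

#' Welch two-sample comparison of a tract variable between groups
#'
#' Convenience wrapper around a Welch t-test, e.g. for comparing tracts with
#' and without a distance-share value.
#'
#' @param x Numeric vector.
#' @param group Logical or two-level factor splitting `x`.
#' @return data.frame with group means, the difference, the t statistic,
#'   degrees of freedom and p-value.
#' @export
welch_compare <- function(x, group) {
  g <- as.factor(group)
  if (nlevels(g) != 2) stop("`group` must have exactly two levels", call. = FALSE)
  tt <- stats::t.test(x ~ g)
  data.frame(level_1 = levels(g)[1], mean_1 = tt$estimate[[1]],
             level_2 = levels(g)[2], mean_2 = tt$estimate[[2]],
             difference = tt$estimate[[1]] - tt$estimate[[2]],
             t = unname(tt$statistic), df = unname(tt$parameter),
             p_value = tt$p.value, stringsAsFactors = FALSE)
}
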
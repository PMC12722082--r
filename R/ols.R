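#' Covariate-adjusted ordinary least squares fit
#'
#' Fits `outcome ~ exposure + covariates` by least squares after listwise
#' deletion, optionally z-scoring the exposure and covariates so coefficients
#' read as outcome change per one standard deviation (the outcome is left on
#' its natural scale). Reports t-based 95% confidence intervals, two-sided
#' p-values, the Gaussian maximum-likelihood log-likelihood and AIC.
#'
#' @param data data.frame holding all variables.
#' @param outcome Name of the outcome column.
#' @param exposure Name of the exposure column.
#' @param covariates Character vector of covariate column names (default:
#'   population density, percent obese, percent over 65).
#' @param standardize Z-score exposure and covariates (default TRUE).
#' @param conf_level Confidence level (default 0.95).
#' @return An object of class `access_ols`: coefficients, `se`, `ci_low`,
#'   `ci_high`, `p`, `residuals`, `fitted`, `sigma2` (ML error variance),
#'   `loglik`, `aic`, `n`, `kept` (row indices used), and the variable names.
#' @seealso [fit_slr()], [residual_moran()]
#' @export
fit_ols <- function(data, outcome, exposure,
                    covariates = c("pop_density", "pct_obese", "pct_over65"),
                    standardize = TRUE, conf_level = 0.95) {
  mm <- build_design(data, outcome, exposure, covariates, standardize)
  X <- mm$X; y <- mm$y
  n <- length(y); p <- ncol(X)
  if (n <= p) stop("more parameters than observations", call. = FALSE)
  qrX <- qr(X)
  if (qrX$rank < p) {
    bad <- colnames(X)[qrX$pivot[seq(qrX$rank + 1, p)]]
    stop("singular design matrix; collinear columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  fit <- stats::lm.fit(X, y)
  beta <- fit$coefficients
  res <- fit$residuals
  sse <- sum(res^2)
  sigma2_ml <- sse / n
  df <- n - p
  vc <- chol2inv(chol(crossprod(X))) * sse / df
  se <- sqrt(diag(vc))
  tstat <- beta / se
  pval <- 2 * stats::pt(-abs(tstat), df)
  tcrit <- stats::qt(1 - (1 - conf_level) / 2, df)
  loglik <- -n / 2 * (log(2 * pi) + log(sigma2_ml) + 1)
  structure(list(coefficients = beta, se = se,
                 ci_low = beta - tcrit * se, ci_high = beta + tcrit * se,
                 p = pval, residuals = res, fitted = fit$fitted.values,
                 sigma2 = sigma2_ml, loglik = loglik,
                 aic = 2 * (p + 1) - 2 * loglik, n = n, df = df,
                 outcome = outcome, exposure = exposure,
                 covariates = covariates, standardize = standardize,
                 kept = mm$kept, X = X, y = y),
            class = "access_ols")
}

# shared design-matrix builder: listwise deletion + optional z-scoring
build_design <- function(data, outcome, exposure, covariates, standardize) {
  vars <- c(outcome, exposure, covariates)
  missing_cols <- setdiff(vars, names(data))
  if (length(missing_cols))
    stop("columns not found: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (exposure %in% covariates)
    stop("`exposure` must not appear among `covariates`", call. = FALSE)
  d <- data[vars]
  keep <- stats::complete.cases(d)
  d <- d[keep, , drop = FALSE]
  rhs <- c(exposure, covariates)
  if (standardize) for (v in rhs) d[[v]] <- zscore(d[[v]])
  X <- cbind(`(Intercept)` = 1, as.matrix(d[rhs]))
  list(X = X, y = d[[outcome]], kept = which(keep))
}

#' @export
print.access_ols <- function(x, ...) {
  cat(sprintf("OLS fit: %s ~ %s + %s  (n = %d%s)\n", x$outcome, x$exposure,
              paste(x$covariates, collapse = " + "), x$n,
              if (x$standardize) ", z-scored predictors" else ""))
  print(round(data.frame(coef = x$coefficients, se = x$se, ci_low = x$ci_low,
                         ci_high = x$ci_high, p = x$p), 4))
  cat(sprintf("logLik %.2f, AIC %.2f\n", x$loglik, x$aic))
  invisible(x)
}

#' @export
summary.access_ols <- function(object, ...) print(object)

#' @export
coef.access_ols <- function(object, ...) object$coefficients

#' @export
residuals.access_ols <- function(object, ...) object$residuals

#' @export
fitted.access_ols <- function(object, ...) object$fitted

#' @export
logLik.access_ols <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients) + 1,
            nobs = object$n, class = "logLik")
}

#' @export
AIC.access_ols <- function(object, ..., k = 2) object$aic

#' @export
confint.access_ols <- function(object, parm, level = 0.95, ...) {
  ci <- cbind(object$ci_low, object$ci_high)
  rownames(ci) <- names(object$coefficients)
  colnames(ci) <- c("2.5 %", "97.5 %")
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' Moran's I of regression residuals
#'
#' Tests the residuals of an OLS or spatial-lag fit for spatial
#' autocorrelation under a given weights object, delegating to [morans_i()].
#' Rows dropped by listwise deletion in the fit are dropped from the weights.
#'
#' @param fit An `access_ols` or `access_slr` object.
#' @param W A [spweights] object aligned with the original data rows.
#' @inheritParams morans_i
#' @return A `moran_test`.
#' @export
residual_moran <- function(fit, W, method = c("normal", "permutation"),
                           n_permutations = 999, seed = 1L) {
  method <- match.arg(method)
  if (length(fit$kept) < length(W$ids)) W <- subset_weights(W, fit$kept)
  morans_i(fit$residuals, W, method = method,
           n_permutations = n_permutations, seed = seed)
}
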
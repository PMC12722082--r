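#' Maximum-likelihood spatial lag regression
#'
#' Fits the spatial lag model `y = rho W y + X beta + eps`,
#' `eps ~ N(0, sigma2 I)`, by maximum likelihood. The log-likelihood is
#' concentrated over `rho` using the two-residual decomposition
#' `e(rho) = e0 - rho ed` (residuals of `y` and of `Wy` on `X`), with the
#' Jacobian term `log det(I - rho W) = sum(log(1 - rho lambda_i))` evaluated
#' from the eigenvalues of `W` (computed once). `rho` is optimised by Brent
#' search on the open interval `(1/lambda_min, 1)` to tolerance `1e-8`;
#' `beta` and `sigma2` then follow in closed form. Standard errors come from
#' the observed information matrix (central-difference numerical Hessian of
#' the full log-likelihood at the optimum, step `1e-5 * max(1, |theta|)`),
#' with two-sided normal-approximation p-values.
#'
#' @inheritParams fit_ols
#' @param weights A row-standardised [spweights] object aligned with `data`
#'   rows; islands among the analysed units are an error (subset them out
#'   first).
#' @param eigenvalues Optional pre-computed eigenvalues of the (full)
#'   weights matrix, to avoid recomputation when fitting several models under
#'   the same weights with no missing data.
#' @param rho_tol Brent tolerance for the `rho` search.
#' @param rho_fixed Optional fixed value of `rho`: skips the optimisation and
#'   profiles `beta`, `sigma2` and the log-likelihood at that value (useful
#'   for likelihood-ratio comparisons; `rho_fixed = 0` reproduces the OLS
#'   fit). No `rho` standard error is reported.
#' @return An object of class `access_slr`: `rho`, `rho_se`, `rho_p`,
#'   `coefficients` (beta), `se`, `p`, `ci_low`/`ci_high`
#'   (normal-approximation), `sigma2`, `loglik`, `aic`
#'   (`2 * (n_beta + 2) - 2 * loglik`, counting `rho` and `sigma2`),
#'   `residuals` (`y - rho W y - X beta`), `fitted`, `converged`,
#'   `interval` (the feasible `rho` interval), `n`, `kept`.
#' @examples
#' cty <- simulate_county(county_config(n_rows = 8, n_cols = 8, sra_block = 4,
#'                                      seed = 3))
#' d <- cty$tracts
#' d$rate <- cty$cases$true_rates
#' fit <- fit_slr(d, "rate", "pct_obese",
#'                covariates = c("pop_density", "pct_over65"),
#'                weights = cty$weights)
#' fit$rho
#' @export
fit_slr <- function(data, outcome, exposure,
                    covariates = c("pop_density", "pct_obese", "pct_over65"),
                    weights, standardize = TRUE, eigenvalues = NULL,
                    rho_tol = 1e-8, rho_fixed = NULL, conf_level = 0.95) {
  if (!inherits(weights, "spweights"))
    stop("`weights` must be a spweights object", call. = FALSE)
  if (!identical(weights$style, "row_standardized"))
    stop("`weights` must be row-standardized", call. = FALSE)
  mm <- build_design(data, outcome, exposure, covariates, standardize)
  W <- weights
  if (length(mm$kept) < length(W$ids)) {
    W <- subset_weights(W, mm$kept)
    eigenvalues <- NULL  # subsetting changes the spectrum
  }
  if (any(lengths(W$nb) == 0))
    stop("islands among analysed units; subset them out before fitting",
         call. = FALSE)
  X <- mm$X; y <- mm$y
  n <- length(y); p <- ncol(X)
  Wm <- weights_matrix(W)
  Wy <- as.vector(Wm %*% y)
  if (is.null(eigenvalues)) {
    ev <- eigen(Wm, only.values = TRUE)$values
    if (max(abs(Im(ev))) > 1e-8 * max(abs(ev)))
      warning("weights matrix has markedly complex eigenvalues; ",
              "using real parts in the log-determinant")
    eigenvalues <- Re(ev)
  }
  lam <- eigenvalues
  lo <- 1 / min(lam)
  hi <- 1  # row-standardized: largest eigenvalue is 1
  if (!is.finite(lo) || lo >= 0) lo <- -1 + 1e-9

  XtX <- crossprod(X)
  XtXinv <- chol2inv(chol(XtX))
  H <- X %*% XtXinv %*% t(X)
  e0 <- y - H %*% y
  ed <- Wy - H %*% Wy
  e0e0 <- sum(e0^2); eded <- sum(ed^2); e0ed <- sum(e0 * ed)

  conc_ll <- function(rho) {
    sse <- e0e0 - 2 * rho * e0ed + rho^2 * eded
    sum(log1p(-rho * lam)) - n / 2 * (log(2 * pi) + 1) - n / 2 * log(sse / n)
  }
  eps <- 1e-7
  if (is.null(rho_fixed)) {
    opt <- stats::optimize(conc_ll, lower = lo + eps, upper = hi - eps,
                           maximum = TRUE, tol = rho_tol)
    rho <- opt$maximum
    converged <- rho > lo + 10 * eps && rho < hi - 10 * eps
  } else {
    if (rho_fixed <= lo || rho_fixed >= hi)
      stop(sprintf("rho_fixed outside the feasible interval (%.4f, %.4f)",
                   lo, hi), call. = FALSE)
    rho <- rho_fixed
    converged <- TRUE
  }

  beta <- as.vector(XtXinv %*% crossprod(X, y - rho * Wy))
  names(beta) <- colnames(X)
  resid <- as.vector(y - rho * Wy - X %*% beta)
  sigma2 <- sum(resid^2) / n
  loglik <- as.numeric(full_slr_ll(c(rho, beta, sigma2), y, Wy, X, lam, n))

  # observed information: numerical Hessian of the full log-likelihood
  # (restricted to beta, sigma2 when rho was held fixed)
  inv_info <- function(Hn, k) {
    info <- -Hn
    vc <- tryCatch(chol2inv(chol(info)), error = function(e) NULL)
    if (is.null(vc))
      vc <- tryCatch(solve(info), error = function(e) {
        warning("observed information is singular; standard errors unavailable")
        matrix(NA_real_, k, k)
      })
    vc
  }
  if (is.null(rho_fixed)) {
    theta <- c(rho = rho, beta, sigma2 = sigma2)
    vc <- inv_info(num_hessian(function(th) full_slr_ll(th, y, Wy, X, lam, n),
                               theta), length(theta))
    se_all <- sqrt(pmax(diag(vc), 0))
    rho_se <- se_all[1]
    se <- se_all[seq(2, 1 + p)]
    converged <- converged && all(is.finite(se_all))
  } else {
    vc <- inv_info(num_hessian(function(th)
      full_slr_ll(c(rho, th), y, Wy, X, lam, n), c(beta, sigma2 = sigma2)),
      p + 1)
    se_all <- sqrt(pmax(diag(vc), 0))
    rho_se <- NA_real_
    se <- se_all[seq_len(p)]
  }
  names(se) <- colnames(X)
  zed <- beta / se
  pval <- 2 * stats::pnorm(-abs(zed))
  rho_p <- if (is.na(rho_se)) NA_real_ else 2 * stats::pnorm(-abs(rho / rho_se))
  zcrit <- stats::qnorm(1 - (1 - conf_level) / 2)

  structure(list(rho = rho, rho_se = rho_se, rho_p = rho_p,
                 coefficients = beta, se = se, p = pval,
                 ci_low = beta - zcrit * se, ci_high = beta + zcrit * se,
                 rho_ci = c(rho - zcrit * rho_se, rho + zcrit * rho_se),
                 sigma2 = sigma2, loglik = loglik,
                 aic = 2 * (p + 2) - 2 * loglik,
                 residuals = resid, fitted = y - resid,
                 converged = converged, interval = c(lo, hi), n = n,
                 outcome = outcome, exposure = exposure,
                 covariates = covariates, standardize = standardize,
                 kept = mm$kept, eigenvalues = lam),
            class = "access_slr")
}

# full log-likelihood of the spatial lag model at theta = (rho, beta, sigma2)
full_slr_ll <- function(theta, y, Wy, X, lam, n) {
  rho <- theta[1]
  p <- ncol(X)
  beta <- theta[seq(2, 1 + p)]
  sigma2 <- theta[2 + p]
  if (sigma2 <= 0 || rho <= 1 / min(lam) || rho >= 1) return(-Inf)
  r <- y - rho * Wy - X %*% beta
  sum(log1p(-rho * lam)) - n / 2 * log(2 * pi * sigma2) -
    sum(r^2) / (2 * sigma2)
}

# central-difference Hessian with per-coordinate step 1e-5 * max(1, |theta|)
num_hessian <- function(f, theta) {
  k <- length(theta)
  h <- 1e-5 * pmax(1, abs(theta))
  H <- matrix(0, k, k)
  f0 <- f(theta)
  for (i in seq_len(k)) {
    for (j in i:k) {
      if (i == j) {
        tp <- theta; tp[i] <- tp[i] + h[i]
        tm <- theta; tm[i] <- tm[i] - h[i]
        H[i, i] <- (f(tp) - 2 * f0 + f(tm)) / h[i]^2
      } else {
        tpp <- theta; tpp[i] <- tpp[i] + h[i]; tpp[j] <- tpp[j] + h[j]
        tpm <- theta; tpm[i] <- tpm[i] + h[i]; tpm[j] <- tpm[j] - h[j]
        tmp <- theta; tmp[i] <- tmp[i] - h[i]; tmp[j] <- tmp[j] + h[j]
        tmm <- theta; tmm[i] <- tmm[i] - h[i]; tmm[j] <- tmm[j] - h[j]
        H[i, j] <- H[j, i] <-
          (f(tpp) - f(tpm) - f(tmp) + f(tmm)) / (4 * h[i] * h[j])
      }
    }
  }
  H
}

#' @export
print.access_slr <- function(x, ...) {
  cat(sprintf("Spatial lag fit (ML): %s ~ rho*W%s + %s + %s  (n = %d%s)\n",
              x$outcome, x$outcome, x$exposure,
              paste(x$covariates, collapse = " + "), x$n,
              if (x$standardize) ", z-scored predictors" else ""))
  cat(sprintf("rho = %.4f (se %.4f, p = %.4g), feasible (%.4f, %.4f)%s\n",
              x$rho, x$rho_se, x$rho_p, x$interval[1], x$interval[2],
              if (!x$converged) " [NOT CONVERGED]" else ""))
  print(round(data.frame(coef = x$coefficients, se = x$se, ci_low = x$ci_low,
                         ci_high = x$ci_high, p = x$p), 4))
  cat(sprintf("sigma2 %.4f, logLik %.2f, AIC %.2f\n", x$sigma2, x$loglik,
              x$aic))
  invisible(x)
}

#' @export
summary.access_slr <- function(object, ...) print(object)

#' @export
coef.access_slr <- function(object, ...) object$coefficients

#' @export
residuals.access_slr <- function(object, ...) object$residuals

#' @export
fitted.access_slr <- function(object, ...) object$fitted

#' @export
logLik.access_slr <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients) + 2,
            nobs = object$n, class = "logLik")
}

#' @export
AIC.access_slr <- function(object, ..., k = 2) object$aic

#' @export
confint.access_slr <- function(object, parm, level = 0.95, ...) {
  ci <- rbind(rho = object$rho_ci,
              cbind(object$ci_low, object$ci_high))
  rownames(ci) <- c("rho", names(object$coefficients))
  colnames(ci) <- c("2.5 %", "97.5 %")
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}
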
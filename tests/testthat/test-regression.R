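slr_covars <- c("pop_density", "pct_over65")

test_that("OLS interpolates exact linear data and matches the normal equations", {
  # exact linear data: recovered exactly, zero residuals
  d <- data.frame(y = 1 + 2 * (1:10), x = 1:10, c1 = rnorm(10))
  f <- fit_ols(d, "y", "x", covariates = "c1", standardize = FALSE)
  expect_equal(unname(coef(f)[c("(Intercept)", "x")]), c(1, 2),
               tolerance = 1e-10)
  expect_lt(max(abs(residuals(f))), 1e-10)

  # normal-equations oracle on random data
  set.seed(12)
  n <- 80
  d2 <- data.frame(y = rnorm(n), x = rnorm(n), c1 = rnorm(n), c2 = rnorm(n))
  f2 <- fit_ols(d2, "y", "x", covariates = c("c1", "c2"), standardize = FALSE)
  X <- cbind(1, d2$x, d2$c1, d2$c2)
  beta_oracle <- solve(t(X) %*% X, t(X) %*% d2$y)[, 1]
  expect_equal(unname(coef(f2)), unname(beta_oracle), tolerance = 1e-10)

  # CI brackets the estimate; p in (0, 1]
  expect_true(all(f2$ci_low <= coef(f2) & coef(f2) <= f2$ci_high))
  expect_true(all(f2$p > 0 & f2$p <= 1))

  # rank deficiency names the collinear column
  d3 <- d2; d3$c2 <- 2 * d3$c1
  expect_error(fit_ols(d3, "y", "x", covariates = c("c1", "c2")), "c2")
})

test_that("z-scored exposures make coefficients per-sd and scale-invariant", {
  set.seed(5)
  n <- 200
  d <- data.frame(x = rexp(n), c1 = rnorm(n))
  d$y <- 3 + 1.5 * d$x + 0.5 * d$c1 + rnorm(n, 0, 0.3)
  f_std <- fit_ols(d, "y", "x", covariates = "c1", standardize = TRUE)
  f_raw <- fit_ols(d, "y", "x", covariates = "c1", standardize = FALSE)
  expect_equal(f_std$coefficients[["x"]],
               f_raw$coefficients[["x"]] * sd(d$x), tolerance = 1e-10)
  # rescaling the exposure by c divides the raw coefficient by c but leaves
  # the standardized coefficient unchanged
  d2 <- d; d2$x <- d$x * 10
  f_std2 <- fit_ols(d2, "y", "x", covariates = "c1", standardize = TRUE)
  f_raw2 <- fit_ols(d2, "y", "x", covariates = "c1", standardize = FALSE)
  expect_equal(f_std2$coefficients[["x"]], f_std$coefficients[["x"]],
               tolerance = 1e-10)
  expect_equal(f_raw2$coefficients[["x"]], f_raw$coefficients[["x"]] / 10,
               tolerance = 1e-10)
})

test_that("the concentrated-likelihood optimum matches a fine grid search", {
  cfg <- county_config(n_rows = 10, n_cols = 10, sra_block = 5, seed = 17)
  tr <- generate_tracts(cfg)
  W <- row_standardize(queen_weights(tr))
  cs <- generate_cases(cfg, tr, W)
  d <- tr; d$rate <- cs$true_rates
  f <- fit_slr(d, "rate", "pct_obese", covariates = slr_covars, weights = W)

  X <- cbind(1, scale(as.matrix(d[c("pct_obese", slr_covars)])))
  y <- d$rate
  Wm <- weights_matrix(W)
  Wy <- as.vector(Wm %*% y)
  lam <- f$eigenvalues
  H <- X %*% solve(crossprod(X)) %*% t(X)
  e0 <- y - H %*% y; ed <- Wy - H %*% Wy
  n <- length(y)
  conc <- function(r) sum(log1p(-r * lam)) -
    n / 2 * log(sum((e0 - r * ed)^2) / n)
  grid <- seq(1 / min(lam) + 1e-4, 1 - 1e-4, by = 1e-4)
  rho_grid <- grid[which.max(vapply(grid, conc, numeric(1)))]
  expect_lt(abs(f$rho - rho_grid), 1e-3)
  expect_true(f$converged)
  expect_gt(f$rho, f$interval[1])
  expect_lt(f$rho, f$interval[2])
})

test_that("the spatial lag fit reduces to OLS when rho is held at zero", {
  cfg <- small_config(seed = 5)
  tr <- generate_tracts(cfg)
  W <- row_standardize(queen_weights(tr))
  cs <- generate_cases(cfg, tr, W)
  d <- tr; d$rate <- cs$true_rates
  f0 <- fit_slr(d, "rate", "pct_obese", covariates = slr_covars,
                weights = W, rho_fixed = 0)
  o <- fit_ols(d, "rate", "pct_obese", covariates = slr_covars)
  expect_equal(coef(f0), coef(o), tolerance = 1e-6)
  expect_equal(f0$loglik, o$loglik, tolerance = 1e-10)
  # and the ML optimum can only improve on the rho = 0 likelihood
  f <- fit_slr(d, "rate", "pct_obese", covariates = slr_covars, weights = W)
  expect_gte(f$loglik, o$loglik)
  expect_equal(f$aic, 2 * (length(coef(f)) + 2) - 2 * f$loglik)
})

test_that("rho is estimated near zero on non-spatial data", {
  rhos <- numeric(30)
  W <- NULL
  for (s in 1:30) {
    cfg <- county_config(n_rows = 10, n_cols = 10, sra_block = 5,
                         seed = 300 + s, true_rho = 0)
    tr <- generate_tracts(cfg)
    if (is.null(W)) { W <- row_standardize(queen_weights(tr)); ev <- NULL }
    cs <- generate_cases(cfg, tr, W)
    d <- tr; d$rate <- cs$true_rates
    f <- fit_slr(d, "rate", "pct_obese", covariates = slr_covars,
                 weights = W, eigenvalues = ev)
    ev <- f$eigenvalues
    rhos[s] <- f$rho
  }
  expect_lt(abs(median(rhos)), 0.05)
})

test_that("residual Moran delegates to morans_i on the residual vector", {
  cfg <- small_config(seed = 19)
  tr <- generate_tracts(cfg)
  W <- row_standardize(queen_weights(tr))
  cs <- generate_cases(cfg, tr, W)
  d <- tr; d$rate <- cs$true_rates
  f <- fit_ols(d, "rate", "pct_obese", covariates = slr_covars)
  m1 <- residual_moran(f, W, method = "normal")
  m2 <- morans_i(residuals(f), W, method = "normal")
  expect_equal(m1$I, m2$I, tolerance = 1e-15)
  expect_equal(m1$p_value, m2$p_value, tolerance = 1e-15)
})

test_that("residual Moran has power against spatially lagged outcomes", {
  rej <- 0
  W <- NULL
  for (s in 1:100) {
    cfg <- county_config(n_rows = 15, n_cols = 15, sra_block = 5,
                         seed = 2000 + s, true_rho = 0.7)
    tr <- generate_tracts(cfg)
    if (is.null(W)) W <- row_standardize(queen_weights(tr))
    cs <- generate_cases(cfg, tr, W)
    d <- tr; d$rate <- cs$true_rates
    f <- fit_ols(d, "rate", "pct_obese", covariates = slr_covars)
    rej <- rej + (residual_moran(f, W, method = "normal")$p_value < 0.01)
  }
  expect_gte(rej / 100, 0.95)
})

test_that("the model battery reports one OLS and one SLR row per exposure", {
  cfg0 <- county_config(n_rows = 10, n_cols = 10, sra_block = 5, seed = 1)
  tr <- generate_tracts(cfg0)
  W <- row_standardize(queen_weights(tr))
  Wk <- knn_weights(tr, 8)
  Wm <- weights_matrix(W)
  A <- solve(diag(100) - 0.5 * Wm)
  set.seed(77)
  d <- tr
  for (j in 1:6) d[[paste0("expo", j)]] <- rnorm(100)
  Xc <- scale(cbind(d$pop_density, d$pct_obese, d$pct_over65))
  d$rate <- as.vector(A %*% (Xc %*% c(0.3, 0.5, 0.4) - 1.3 * d$expo3 +
                               rnorm(100)))
  b <- run_model_battery(d, "rate", paste0("expo", 1:6),
                         covariates = c("pop_density", "pct_obese",
                                        "pct_over65"),
                         weights_queen = W, weights_knn = Wk)
  expect_s3_class(b, "model_battery")
  expect_equal(nrow(b), 6)
  expect_setequal(b$exposure, paste0("expo", 1:6))
  expect_false(is.unsorted(b$slr_aic))
  expect_true(all(b$converged))
  # identical call reproduces the report exactly
  b2 <- run_model_battery(d, "rate", paste0("expo", 1:6),
                          covariates = c("pop_density", "pct_obese",
                                         "pct_over65"),
                          weights_queen = W, weights_knn = Wk)
  expect_identical(as.data.frame(b), as.data.frame(b2))
  # a failing exposure yields an NA row, not an abort
  d$bad <- rep(1, 100)
  expect_warning(b3 <- run_model_battery(d, "rate", c("expo1", "bad"),
                                         covariates = c("pop_density"),
                                         weights_queen = W), "bad")
  expect_equal(nrow(b3), 2)
  expect_true(any(is.na(b3$ols_coef)))
})

test_that("planted-signal exposures win the AIC comparison", {
  cfg0 <- county_config(n_rows = 10, n_cols = 10, sra_block = 5, seed = 1)
  tr <- generate_tracts(cfg0)
  W <- row_standardize(queen_weights(tr))
  Wm <- weights_matrix(W)
  A <- solve(diag(100) - 0.5 * Wm)
  hit <- 0
  for (s in 1:50) {
    set.seed(s)
    d <- tr
    for (j in 1:6) d[[paste0("expo", j)]] <- rnorm(100)
    Xc <- scale(cbind(d$pop_density, d$pct_obese, d$pct_over65))
    d$rate <- as.vector(A %*% (Xc %*% c(0.3, 0.5, 0.4) - 1.3 * d$expo3 +
                                 rnorm(100)))
    b <- suppressWarnings(
      run_model_battery(d, "rate", paste0("expo", 1:6),
                        covariates = c("pop_density", "pct_obese",
                                       "pct_over65"),
                        weights_queen = W))
    hit <- hit + (b$exposure[1] == "expo3")
  }
  expect_gte(hit / 50, 0.8)
})
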
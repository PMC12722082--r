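test_that("queen contiguity on grids matches enumeration", {
  tr2 <- generate_tracts(county_config(n_rows = 2, n_cols = 2, sra_block = 2))
  W2 <- queen_weights(tr2)
  expect_true(all(lengths(W2$nb) == 3))  # corner contact counts

  tr3 <- generate_tracts(county_config(n_rows = 3, n_cols = 3, sra_block = 3))
  W3 <- queen_weights(tr3)
  # centre cell (row 2, col 2) has all 8 neighbours
  centre <- which(tr3$row == 2 & tr3$col == 2)
  expect_equal(length(W3$nb[[centre]]), 8)
  expect_equal(sort(lengths(W3$nb)), c(3, 3, 3, 3, 5, 5, 5, 5, 8))

  # symmetry
  Wm <- weights_matrix(W3)
  expect_identical(Wm, t(Wm))

  # single polygon: island with warning
  tr1 <- tr3[1, ]
  expect_warning(W1 <- queen_weights(tr1), "island")
  expect_equal(lengths(W1$nb), 0)

  expect_error(queen_weights(rbind(tr3, tr3)), "duplicate")
})

test_that("kNN weights have exactly k neighbours with id tie-breaking", {
  tr3 <- generate_tracts(county_config(n_rows = 3, n_cols = 3, sra_block = 3))
  W <- knn_weights(tr3, k = 8)
  expect_true(all(lengths(W$nb) == 8))  # saturation: everyone neighbours all

  # collinear centroids: middle unit ties broken towards the smaller id
  tr <- data.frame(tract_id = c("A", "B", "C"), x = c(0, 1, 2), y = 0,
                   stringsAsFactors = FALSE)
  W1 <- knn_weights(tr, k = 1)
  expect_equal(W1$ids[W1$nb[[2]]], "A")

  # cardinality on random point sets
  set.seed(7)
  trr <- data.frame(tract_id = sprintf("P%02d", 1:30),
                    x = runif(30), y = runif(30), stringsAsFactors = FALSE)
  for (k in c(1, 4, 9)) expect_true(all(lengths(knn_weights(trr, k)$nb) == k))

  expect_error(knn_weights(tr, k = 3), "smaller")
})

test_that("row standardisation is idempotent and preserves islands", {
  tr <- generate_tracts(county_config(n_rows = 3, n_cols = 3, sra_block = 3))
  W <- queen_weights(tr)
  Ws <- row_standardize(W)
  expect_true(all(abs(vapply(Ws$w, sum, numeric(1)) - 1) < 1e-12))
  # binary row of 5 neighbours -> 0.2 each; a rook row of 4 -> 0.25 each
  i5 <- which(lengths(W$nb) == 5)[1]
  expect_equal(Ws$w[[i5]], rep(0.2, 5))
  Wr <- row_standardize(rook_grid_weights(3))
  expect_equal(Wr$w[[5]], rep(0.25, 4))
  expect_identical(row_standardize(Ws), Ws)
})

test_that("Moran's I matches its closed forms and the double-sum oracle", {
  # expectation -1/(n-1)
  set.seed(2)
  W <- rook_grid_weights(4)
  m <- morans_i(rnorm(16), W, method = "normal")
  expect_equal(m$expected, -1 / 15, tolerance = 1e-12)
  m10 <- morans_i(rnorm(9), rook_grid_weights(3), method = "normal")
  expect_equal(m10$expected, -1 / 8)

  # perfect checkerboard on rook grids -> I = -1
  expect_equal(morans_i(checkerboard(2), rook_grid_weights(2),
                        method = "normal")$I, -1, tolerance = 1e-12)
  expect_equal(morans_i(checkerboard(4), rook_grid_weights(4),
                        method = "normal")$I, -1, tolerance = 1e-12)

  # brute-force double loop equivalence on random data, n <= 50
  set.seed(11)
  for (rep in 1:5) {
    n_side <- sample(4:7, 1)
    tr <- generate_tracts(county_config(n_rows = n_side, n_cols = n_side,
                                        sra_block = 1, seed = rep))
    W <- row_standardize(queen_weights(tr))
    x <- rnorm(n_side^2)
    m <- morans_i(x, W, method = "normal")
    Wm <- weights_matrix(W)
    z <- x - mean(x)
    num <- 0
    for (i in seq_along(z)) for (j in seq_along(z))
      num <- num + Wm[i, j] * z[i] * z[j]
    I_brute <- length(z) / sum(Wm) * num / sum(z^2)
    expect_equal(m$I, I_brute, tolerance = 1e-12)
  }

  expect_error(morans_i(rep(1, 16), rook_grid_weights(4), method = "normal"),
               "variance")
})

test_that("Moran's I agrees with an independent implementation", {
  skip_if_not_installed("ape")
  set.seed(5)
  tr <- generate_tracts(county_config(n_rows = 6, n_cols = 6, sra_block = 3))
  W <- row_standardize(queen_weights(tr))
  x <- rnorm(36)
  ours <- morans_i(x, W, method = "normal")
  ref <- ape::Moran.I(x, weights_matrix(W))
  expect_equal(ours$I, ref$observed, tolerance = 1e-12)
  expect_equal(ours$expected, ref$expected, tolerance = 1e-12)
})

test_that("permutation inference is seeded, bounded and stable", {
  cfg <- county_config(n_rows = 10, n_cols = 10, sra_block = 5, seed = 6,
                       true_rho = 0.6)
  tr <- generate_tracts(cfg)
  W <- row_standardize(queen_weights(tr))
  cs <- generate_cases(cfg, tr, W)
  x <- cs$true_rates
  m1 <- morans_i(x, W, n_permutations = 999, seed = 9)
  m2 <- morans_i(x, W, n_permutations = 999, seed = 9)
  expect_identical(m1$p_value, m2$p_value)
  expect_gte(m1$p_value, 1 / 1000)
  m3 <- morans_i(x, W, n_permutations = 1999, seed = 9)
  expect_lt(abs(m1$p_value - m3$p_value), 0.02)

  # missing values: listwise drop with weights subset
  x_na <- x; x_na[c(3, 50)] <- NA
  m4 <- morans_i(x_na, W, method = "normal")
  expect_equal(m4$n, 98)
})

test_that("Moran's I detects strong synthetic autocorrelation", {
  pos <- 0
  W <- NULL
  for (s in 1:100) {
    cfg <- county_config(n_rows = 10, n_cols = 10, sra_block = 5,
                         seed = 800 + s, true_rho = 0.6)
    tr <- generate_tracts(cfg)
    if (is.null(W)) W <- row_standardize(queen_weights(tr))
    cs <- generate_cases(cfg, tr, W)
    m <- morans_i(cs$true_rates, W, method = "normal")
    pos <- pos + (m$I > 0 && m$p_value < 0.01)
  }
  expect_gte(pos / 100, 0.95)
})

test_that("zscore centres, scales and is idempotent", {
  expect_equal(zscore(c(1, 2, 3)), c(-1, 0, 1))
  set.seed(1)
  x <- rexp(50)
  z <- zscore(x)
  expect_lt(abs(mean(z)), 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  expect_equal(zscore(z), z)
  x[3] <- NA
  expect_true(is.na(zscore(x)[3]))
  expect_error(zscore(rep(2, 5)), "variance")
})

test_that("welch_compare reports group means and a two-sided p", {
  set.seed(8)
  x <- c(rnorm(40, 0), rnorm(40, 2))
  g <- rep(c("without", "with"), each = 40)
  out <- welch_compare(x, g)
  expect_equal(out$mean_1, mean(x[g == "with"]), tolerance = 1e-12)
  expect_equal(out$difference, out$mean_1 - out$mean_2, tolerance = 1e-12)
  expect_lt(out$p_value, 0.001)
  expect_error(welch_compare(x, rep("a", 80)), "two levels")
})

test_that("pearson_r matches the definitional oracle and handles edge cases", {
  set.seed(3)
  x <- rnorm(40); y <- rnorm(40)
  pr <- pearson_r(x, y)
  r_brute <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pr$r, r_brute, tolerance = 1e-12)
  expect_equal(pearson_r(x, 2 * x + 1)$r, 1, tolerance = 1e-12)
  expect_equal(pearson_r(x, -x)$r, -1, tolerance = 1e-12)
  expect_error(pearson_r(x, rep(1, 40)), "variance")
})

test_that("the Spearman screen drops the later of a correlated pair", {
  set.seed(4)
  x <- rnorm(100)
  d <- data.frame(a = x, b = rnorm(100), a_copy = x)
  sc <- spearman_screen(d, 0.9)
  expect_equal(sc$dropped$variable, "a_copy")
  expect_equal(sc$dropped$correlated_with, "a")
  expect_equal(sc$kept, c("a", "b"))

  # rank-preserving transform is perfectly rank-correlated
  d2 <- data.frame(x = x, ex = exp(x))
  sc2 <- spearman_screen(d2, 0.9)
  expect_equal(sc2$dropped$variable, "ex")
  expect_equal(sc2$dropped$rho, 1)

  # independent columns rarely exceed 0.9 at n = 200
  drops <- 0
  for (s in 1:50) {
    set.seed(s)
    dd <- as.data.frame(matrix(rnorm(200 * 4), 200, 4))
    drops <- drops + nrow(spearman_screen(dd, 0.9)$dropped)
  }
  expect_equal(drops, 0)

  # constant column never triggers a drop
  d3 <- data.frame(a = x, k = rep(1, 100), b = x)
  sc3 <- spearman_screen(d3, 0.9)
  expect_equal(sc3$dropped$variable, "b")
  expect_true("k" %in% sc3$kept)
})
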
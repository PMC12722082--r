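#' Generate the tract grid of a synthetic county
#'
#' Tiles a rectangle with `n_rows` x `n_cols` square tracts, assigns each
#' tract to a square SRA block, and draws demographics: total population
#' (log-normal), AAPI population (Beta share of total), percent over 65,
#' percent obese, percent below 200% of the federal poverty line, and
#' population density over a randomly drawn residential fraction of the tract
#' area. Deterministic given `config$seed`.
#'
#' @param config A [county_config()].
#' @return A data.frame with one row per tract: `tract_id`, `sra_id`,
#'   `row`, `col`, `pop_total`, `pop_aapi`, `pct_over65`, `pct_obese`,
#'   `pct_below_200fpl`, `pop_density`, and a `geometry` list-column of closed
#'   polygon rings (matrices of x/y in metres).
#' @examples
#' tr <- generate_tracts(county_config(n_rows = 4, n_cols = 4, sra_block = 2))
#' nrow(tr)          # 16 tracts
#' length(unique(tr$sra_id))  # 4 SRAs
#' @export
generate_tracts <- function(config) {
  config <- validate_county_config(config)
  set.seed(stage_seed(config$seed, "tracts"))
  nr <- config$n_rows; nc <- config$n_cols; s <- config$tract_side
  n <- nr * nc
  idx <- seq_len(n)
  row <- (idx - 1L) %/% nc + 1L
  col <- (idx - 1L) %% nc + 1L
  sra_row <- (row - 1L) %/% config$sra_block + 1L
  sra_col <- (col - 1L) %/% config$sra_block + 1L
  sra_id <- sprintf("S%02d-%02d", sra_row, sra_col)
  tract_id <- sprintf("T%04d", idx)

  geometry <- lapply(idx, function(i) {
    x0 <- (col[i] - 1L) * s; y0 <- (row[i] - 1L) * s
    cbind(x = c(x0, x0 + s, x0 + s, x0, x0),
          y = c(y0, y0, y0 + s, y0 + s, y0))
  })

  pop_total <- round(stats::rlnorm(n, config$pop_log_mean, config$pop_log_sd))
  aapi_share <- stats::rbeta(n, config$aapi_beta_a, config$aapi_beta_b)
  pop_aapi <- round(aapi_share * pop_total)
  clamp_pct <- function(x) pmin(100, pmax(0, x))
  pct_over65 <- clamp_pct(stats::rnorm(n, 14.4, 5))
  pct_obese <- clamp_pct(stats::rnorm(n, 23.3, 6))
  pct_below_200fpl <- clamp_pct(stats::rnorm(n, 30, 10))
  res_frac <- stats::runif(n, 0.2, 0.8)
  pop_density <- pop_total / (res_frac * (s / 1000)^2)  # persons per km^2 residential

  out <- data.frame(tract_id = tract_id, sra_id = sra_id, row = row, col = col,
                    pop_total = pop_total, pop_aapi = pop_aapi,
                    pct_over65 = pct_over65, pct_obese = pct_obese,
                    pct_below_200fpl = pct_below_200fpl,
                    pop_density = pop_density,
                    stringsAsFactors = FALSE)
  out$geometry <- geometry
  attr(out, "crs") <- "synthetic-metre-grid"
  out
}

#' Representative population points for each tract
#'
#' Places `pop_points_per_tract` points on a jittered sub-grid inside each
#' tract; each point carries an equal share of the tract's total and AAPI
#' population, so point weights sum exactly to the tract populations. These
#' points stand in for sub-tract population placement when computing the
#' share of population beyond a distance threshold from a supermarket.
#'
#' @param config A [county_config()].
#' @param tracts Output of [generate_tracts()].
#' @return data.frame: `tract_id`, `x`, `y`, `weight_total`, `weight_aapi`.
#' @export
generate_population_points <- function(config, tracts) {
  config <- validate_county_config(config)
  set.seed(stage_seed(config$seed, "points"))
  np <- config$pop_points_per_tract
  m <- ceiling(sqrt(np))
  res <- vector("list", nrow(tracts))
  for (i in seq_len(nrow(tracts))) {
    ring <- tracts$geometry[[i]]
    x0 <- min(ring[, 1]); y0 <- min(ring[, 2])
    side <- max(ring[, 1]) - x0
    cell <- side / m
    gx <- rep(seq_len(m), each = m)[seq_len(np)]
    gy <- rep(seq_len(m), times = m)[seq_len(np)]
    px <- x0 + (gx - 1) * cell + stats::runif(np, 0.1, 0.9) * cell
    py <- y0 + (gy - 1) * cell + stats::runif(np, 0.1, 0.9) * cell
    res[[i]] <- data.frame(tract_id = tracts$tract_id[i], x = px, y = py,
                           weight_total = tracts$pop_total[i] / np,
                           weight_aapi = tracts$pop_aapi[i] / np,
                           stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "crs") <- attr(tracts, "crs")
  out
}

# category pools the generator draws from; all resolve correctly under
# default_lexicon()
.gen_pools <- list(
  aapi_rest    = list(c("chinese"), c("vietnamese"), c("korean"), c("japanese"),
                      c("thai"), c("filipino"), c("hawaiian"), c("asian fusion"),
                      c("ramen"), c("poke"), c("bubble tea", "coffee & tea")),
  nonaapi_rest = list(c("mexican"), c("traditional american"), c("italian"),
                      c("pizza"), c("burgers"), c("soul food"), c("seafood"),
                      c("sandwiches"), c("beer bar", "pubs")),
  aapi_groc    = list(c("asian grocery store"), c("hawaiian food market"),
                      c("japanese grocery store")),
  nonaapi_groc = list(c("farmer's market"), c("health markets"),
                      c("mexican grocery store"), c("organic food market")),
  ambiguous    = list(c("grocery"), c("food market"), c("international grocery")),
  neither      = list(c("convenience stores"), c("bakeries"), c("wineries"),
                      c("butcher")),
  excluded     = list(c("bookstores"), c("food delivery services"))
)

#' Generate food outlets for a synthetic county
#'
#' Draws a Poisson number of outlets per tract with mean
#' `outlet_rate_per_1k * pop_total / 1000`, places each uniformly inside its
#' tract, and samples a category list. The probability that a restaurant or
#' grocery carries AAPI categories follows a logistic curve in the tract AAPI
#' share with slope `aapi_outlet_affinity` (0 = independent of composition).
#' A fraction of groceries receive only generic categories ("grocery",
#' "food market", ...) and are therefore content-ambiguous; their true
#' content is returned as a resolution table, mirroring a manual review step.
#' A small fraction of records are non-food businesses carrying excluded
#' categories.
#'
#' @param config A [county_config()].
#' @param tracts Output of [generate_tracts()].
#' @return A data.frame of outlets (`outlet_id`, `name`, `tract_id_true`,
#'   `x`, `y`, `categories` list-column) with attribute `resolutions`: a
#'   data.frame (`outlet_id`, `content`) giving the true content of every
#'   ambiguous outlet.
#' @export
generate_outlets <- function(config, tracts) {
  config <- validate_county_config(config)
  if (nrow(tracts) == 0) stop("`tracts` must be nonempty", call. = FALSE)
  set.seed(stage_seed(config$seed, "outlets"))
  lam <- config$outlet_rate_per_1k * tracts$pop_total / 1000
  n_per <- stats::rpois(nrow(tracts), lam)
  total <- sum(n_per)
  if (total == 0) {
    out <- data.frame(outlet_id = character(), name = character(),
                      tract_id_true = character(), x = numeric(), y = numeric(),
                      stringsAsFactors = FALSE)
    out$categories <- list()
    attr(out, "resolutions") <- data.frame(outlet_id = character(),
                                           content = character(),
                                           stringsAsFactors = FALSE)
    attr(out, "crs") <- attr(tracts, "crs")
    return(out)
  }
  ti <- rep(seq_len(nrow(tracts)), n_per)
  share <- ifelse(tracts$pop_total > 0, tracts$pop_aapi / tracts$pop_total, 0)
  p_aapi <- stats::plogis(stats::qlogis(0.25) +
                            config$aapi_outlet_affinity * (share[ti] - 0.5))

  # outlet mix: restaurants dominate, some groceries, some neither/excluded
  kind <- sample(c("rest", "groc", "neither", "excluded"), total, replace = TRUE,
                 prob = c(0.62, 0.16, 0.18, 0.04))
  is_aapi <- stats::runif(total) < p_aapi
  ambiguous <- kind == "groc" & stats::runif(total) < 0.3

  pool_name <- ifelse(kind == "neither", "neither",
               ifelse(kind == "excluded", "excluded",
               ifelse(ambiguous, "ambiguous",
               ifelse(kind == "rest",
                      ifelse(is_aapi, "aapi_rest", "nonaapi_rest"),
                      ifelse(is_aapi, "aapi_groc", "nonaapi_groc")))))
  categories <- lapply(pool_name, function(p) {
    pool <- .gen_pools[[p]]
    pool[[sample.int(length(pool), 1)]]
  })

  # uniform placement within the (square) tract
  xs <- numeric(total); ys <- numeric(total)
  for (j in seq_len(total)) {
    ring <- tracts$geometry[[ti[j]]]
    xs[j] <- stats::runif(1, min(ring[, 1]), max(ring[, 1]))
    ys[j] <- stats::runif(1, min(ring[, 2]), max(ring[, 2]))
  }

  out <- data.frame(outlet_id = sprintf("O%06d", seq_len(total)),
                    name = sprintf("Outlet %06d", seq_len(total)),
                    tract_id_true = tracts$tract_id[ti],
                    x = xs, y = ys, stringsAsFactors = FALSE)
  out$categories <- categories
  amb_idx <- which(ambiguous)
  attr(out, "resolutions") <- data.frame(
    outlet_id = out$outlet_id[amb_idx],
    content = ifelse(is_aapi[amb_idx], "aapi", "non_aapi"),
    stringsAsFactors = FALSE)
  attr(out, "crs") <- attr(tracts, "crs")
  out
}

#' Generate supermarket locations
#'
#' Poisson counts per tract with mean `supermarket_rate_per_10k *
#' pop_total / 10000`, uniform placement within the tract.
#'
#' @param config A [county_config()].
#' @param tracts Output of [generate_tracts()].
#' @return data.frame: `supermarket_id`, `x`, `y`.
#' @export
generate_supermarkets <- function(config, tracts) {
  config <- validate_county_config(config)
  set.seed(stage_seed(config$seed, "supermarkets"))
  lam <- config$supermarket_rate_per_10k * tracts$pop_total / 10000
  n_per <- stats::rpois(nrow(tracts), lam)
  total <- sum(n_per)
  ti <- rep(seq_len(nrow(tracts)), n_per)
  xs <- numeric(total); ys <- numeric(total)
  for (j in seq_len(total)) {
    ring <- tracts$geometry[[ti[j]]]
    xs[j] <- stats::runif(1, min(ring[, 1]), max(ring[, 1]))
    ys[j] <- stats::runif(1, min(ring[, 2]), max(ring[, 2]))
  }
  out <- data.frame(supermarket_id = sprintf("M%04d", seq_len(total)),
                    x = xs, y = ys, stringsAsFactors = FALSE)
  attr(out, "crs") <- attr(tracts, "crs")
  out
}

#' Generate SRA-level disease case records from a spatial-lag rate process
#'
#' Latent tract rates follow `y = (I - rho W)^{-1} (X beta + eps)` with `X`
#' the z-scored covariates (population density, percent obese, percent over
#' 65) and `eps ~ N(0, noise_sd^2)`; the latent values are shifted so the
#' minimum is slightly above zero (rates cannot be negative). Expected annual
#' cases per tract are `rate * pop_aapi / 100000`; yearly counts are Poisson,
#' summed to SRA by year. SRAs whose mean annual count falls below
#' `suppression_threshold` are flagged suppressed and their yearly counts
#' withheld; the county mean annual total is retained on the unsuppressed
#' scale.
#'
#' @param config A [county_config()].
#' @param tracts Output of [generate_tracts()].
#' @param weights A row-standardised [queen_weights()] object aligned with
#'   `tracts`.
#' @return An object of class `sra_case_records`: a list with `sra_id`,
#'   `pop_aapi`, `suppressed`, `yearly` (SRA x year count matrix, NA rows
#'   where suppressed), `county_total_mean_cases`, `n_years`, plus
#'   `true_rates` (latent tract rates per 100,000) and `true_sra_mean`
#'   (pre-suppression SRA mean annual counts) for validation.
#' @export
generate_cases <- function(config, tracts, weights) {
  config <- validate_county_config(config)
  if (abs(config$true_rho) >= 1) stop_field("true_rho", "must satisfy |rho| < 1")
  if (!identical(weights$style, "row_standardized"))
    stop("`weights` must be row-standardized", call. = FALSE)
  if (!identical(weights$ids, tracts$tract_id))
    stop("`weights` ids must align with `tracts`", call. = FALSE)
  set.seed(stage_seed(config$seed, "cases"))
  n <- nrow(tracts)
  X <- scale(cbind(tracts$pop_density, tracts$pct_obese, tracts$pct_over65))
  eps <- stats::rnorm(n, 0, config$noise_sd)
  Wm <- weights_matrix(weights)
  y0 <- solve(diag(n) - config$true_rho * Wm, as.vector(X %*% config$true_beta) + eps)
  shift <- if (min(y0) < 0) abs(min(y0)) + 0.5 else 0.5
  rate <- y0 + shift

  lam <- rate * tracts$pop_aapi / 1e5
  yearly_tract <- matrix(stats::rpois(n * config$n_years, rep(lam, config$n_years)),
                         nrow = n, ncol = config$n_years)
  sra_ids <- sort(unique(tracts$sra_id))
  yearly_sra <- t(vapply(sra_ids, function(s) {
    colSums(yearly_tract[tracts$sra_id == s, , drop = FALSE])
  }, numeric(config$n_years)))
  sra_mean <- rowMeans(yearly_sra)
  suppressed <- sra_mean < config$suppression_threshold
  county_total <- sum(sra_mean)
  pop_sra <- vapply(sra_ids, function(s) sum(tracts$pop_aapi[tracts$sra_id == s]),
                    numeric(1))
  yearly_out <- yearly_sra
  yearly_out[suppressed, ] <- NA_real_
  structure(list(sra_id = sra_ids, pop_aapi = unname(pop_sra),
                 suppressed = unname(suppressed), yearly = unname(yearly_out),
                 county_total_mean_cases = county_total,
                 n_years = config$n_years,
                 true_rates = rate, true_sra_mean = unname(sra_mean)),
            class = "sra_case_records")
}

#' @export
print.sra_case_records <- function(x, ...) {
  cat(sprintf("SRA case records: %d SRAs, %d years, %d suppressed\n",
              length(x$sra_id), x$n_years, sum(x$suppressed)))
  cat(sprintf("  county mean annual total (unsuppressed scale): %.2f\n",
              x$county_total_mean_cases))
  invisible(x)
}

#' Simulate a complete synthetic county
#'
#' Runs every generator stage in order (tracts, population points, outlets,
#' supermarkets, queen weights, cases) under substreams of one root seed.
#'
#' @param config A [county_config()].
#' @return An object of class `synthetic_county`: a list with elements
#'   `config`, `tracts`, `pop_points`, `outlets`, `resolutions`,
#'   `supermarkets`, `weights` (row-standardised queen), and `cases`.
#' @examples
#' cty <- simulate_county(county_config(n_rows = 6, n_cols = 6, sra_block = 3,
#'                                      seed = 7))
#' cty
#' @export
simulate_county <- function(config = county_config()) {
  config <- validate_county_config(config)
  tracts <- generate_tracts(config)
  pop_points <- generate_population_points(config, tracts)
  outlets <- generate_outlets(config, tracts)
  supermarkets <- generate_supermarkets(config, tracts)
  W <- row_standardize(queen_weights(tracts))
  cases <- generate_cases(config, tracts, W)
  structure(list(config = config, tracts = tracts, pop_points = pop_points,
                 outlets = outlets,
                 resolutions = attr(outlets, "resolutions"),
                 supermarkets = supermarkets, weights = W, cases = cases),
            class = "synthetic_county")
}

#' @export
print.synthetic_county <- function(x, ...) {
  cat(sprintf("Synthetic county: %d tracts in %d SRAs, %d outlets, %d supermarkets\n",
              nrow(x$tracts), length(unique(x$tracts$sra_id)),
              nrow(x$outlets), nrow(x$supermarkets)))
  cat(sprintf("  %d of %d SRAs suppressed at threshold %d; county mean annual cases %.1f\n",
              sum(x$cases$suppressed), length(x$cases$sra_id),
              x$config$suppression_threshold, x$cases$county_total_mean_cases))
  invisible(x)
}
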
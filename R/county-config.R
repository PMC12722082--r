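#' Configuration for the synthetic county generator
#'
#' Bundles and validates every parameter of the synthetic county: the tract
#' grid, subregional-area (SRA) blocking, population and outlet intensities,
#' the spatial-lag disease-rate process, and the small-count suppression rule.
#' Defaults emulate a mid-size urban county: 625 square tracts nested in 25
#' SRAs, a mean tract population of about 5000 with an 11% mean AAPI share,
#' roughly 3.7 food outlets per 1000 residents, and seven years of case data
#' with cells suppressed when the mean annual count falls below 11 (a common
#' public-health small-cell rule).
#'
#' @param n_rows,n_cols Tract-grid dimensions; `sra_block` must divide both.
#' @param tract_side Side length of each square tract in metres.
#' @param sra_block Number of tract rows/columns per square SRA block.
#' @param seed Integer root seed; every generator stage derives its own
#'   substream from it.
#' @param pop_log_mean,pop_log_sd Log-normal parameters for tract total
#'   population.
#' @param aapi_beta_a,aapi_beta_b Beta parameters for the tract AAPI share.
#' @param outlet_rate_per_1k Mean food outlets per 1000 residents.
#' @param aapi_outlet_affinity Log-odds slope linking tract AAPI share to the
#'   probability that an outlet carries AAPI categories; 0 makes outlet
#'   content independent of tract composition.
#' @param supermarket_rate_per_10k Mean supermarkets per 10,000 residents.
#' @param true_rho Spatial-lag coefficient of the latent rate process, in
#'   (-1, 1).
#' @param true_beta Named coefficient vector for the z-scored covariates
#'   (population density, percent obese, percent over 65).
#' @param noise_sd Standard deviation of the rate-process error, in rate
#'   units (cases per 100,000).
#' @param suppression_threshold Minimum mean annual SRA case count that is
#'   reported; SRAs below it are suppressed. 0 disables suppression.
#' @param n_years Number of years of case data.
#' @param pop_points_per_tract Representative population points per tract used
#'   by the supermarket-distance share.
#'
#' @return An object of class `county_config` (a validated named list).
#' @seealso [simulate_county()]
#' @examples
#' cfg <- county_config(n_rows = 10, n_cols = 10, sra_block = 5, seed = 42)
#' cfg
#' @export
county_config <- function(n_rows = 25, n_cols = 25, tract_side = 2000,
                          sra_block = 5, seed = 1L,
                          pop_log_mean = log(5000), pop_log_sd = 0.4,
                          aapi_beta_a = 1.5, aapi_beta_b = 12,
                          outlet_rate_per_1k = 3.7,
                          aapi_outlet_affinity = 2,
                          supermarket_rate_per_10k = 1.2,
                          true_rho = 0.5,
                          true_beta = c(pop_density = 1.5, pct_obese = 10,
                                        pct_over65 = 7),
                          noise_sd = 22,
                          suppression_threshold = 11L,
                          n_years = 7L,
                          pop_points_per_tract = 25L) {
  cfg <- list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
              tract_side = tract_side, sra_block = as.integer(sra_block),
              seed = as.integer(seed),
              pop_log_mean = pop_log_mean, pop_log_sd = pop_log_sd,
              aapi_beta_a = aapi_beta_a, aapi_beta_b = aapi_beta_b,
              outlet_rate_per_1k = outlet_rate_per_1k,
              aapi_outlet_affinity = aapi_outlet_affinity,
              supermarket_rate_per_10k = supermarket_rate_per_10k,
              true_rho = true_rho, true_beta = true_beta,
              noise_sd = noise_sd,
              suppression_threshold = suppression_threshold,
              n_years = as.integer(n_years),
              pop_points_per_tract = as.integer(pop_points_per_tract))
  class(cfg) <- "county_config"
  validate_county_config(cfg)
}

validate_county_config <- function(cfg) {
  for (f in c("n_rows", "n_cols", "sra_block", "pop_points_per_tract")) {
    v <- cfg[[f]]
    if (length(v) != 1 || is.na(v) || v < 1) stop_field(f, "must be an integer >= 1")
  }
  if (cfg$n_rows %% cfg$sra_block != 0 || cfg$n_cols %% cfg$sra_block != 0)
    stop_field("sra_block", "must divide both n_rows and n_cols")
  if (!is.finite(cfg$tract_side) || cfg$tract_side <= 0)
    stop_field("tract_side", "must be > 0")
  if (!is.finite(cfg$true_rho) || abs(cfg$true_rho) >= 1)
    stop_field("true_rho", "must satisfy |rho| < 1")
  if (cfg$suppression_threshold < 0)
    stop_field("suppression_threshold", "must be >= 0")
  if (cfg$n_years < 1) stop_field("n_years", "must be >= 1")
  if (cfg$outlet_rate_per_1k < 0) stop_field("outlet_rate_per_1k", "must be >= 0")
  if (cfg$supermarket_rate_per_10k < 0)
    stop_field("supermarket_rate_per_10k", "must be >= 0")
  if (cfg$noise_sd < 0) stop_field("noise_sd", "must be >= 0")
  if (cfg$pop_log_sd < 0) stop_field("pop_log_sd", "must be >= 0")
  if (cfg$aapi_beta_a <= 0 || cfg$aapi_beta_b <= 0)
    stop_field("aapi_beta_a", "and aapi_beta_b must be > 0")
  if (length(cfg$true_beta) != 3)
    stop_field("true_beta", "must have length 3 (pop_density, pct_obese, pct_over65)")
  cfg
}

#' @export
print.county_config <- function(x, ...) {
  cat("Synthetic county configuration\n")
  cat(sprintf("  grid: %d x %d tracts (side %.0f m), SRA blocks of %d x %d\n",
              x$n_rows, x$n_cols, x$tract_side, x$sra_block, x$sra_block))
  cat(sprintf("  population: lognormal(meanlog %.2f, sdlog %.2f); AAPI share Beta(%.2f, %.2f)\n",
              x$pop_log_mean, x$pop_log_sd, x$aapi_beta_a, x$aapi_beta_b))
  cat(sprintf("  outlets: %.2f per 1k residents, AAPI affinity %.2f; supermarkets %.2f per 10k\n",
              x$outlet_rate_per_1k, x$aapi_outlet_affinity, x$supermarket_rate_per_10k))
  cat(sprintf("  rate process: rho = %.2f, beta = (%s), noise sd = %.2f\n",
              x$true_rho, paste(sprintf("%.2f", x$true_beta), collapse = ", "),
              x$noise_sd))
  cat(sprintf("  cases: %d years, suppression threshold %d; seed %d\n",
              x$n_years, x$suppression_threshold, x$seed))
  invisible(x)
}
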
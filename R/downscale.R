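#' Mean annual case count
#'
#' Arithmetic mean of a nonempty series of yearly counts (averaging precedes
#' any rate computation).
#'
#' @param yearly_cases Numeric vector of nonnegative yearly counts.
#' @return The mean.
#' @examples
#' mean_annual_cases(c(10, 20, 30, 40, 50, 60, 70))  # 40
#' @export
mean_annual_cases <- function(yearly_cases) {
  if (length(yearly_cases) == 0)
    stop("`yearly_cases` must be nonempty", call. = FALSE)
  if (any(is.na(yearly_cases)) || any(yearly_cases < 0))
    stop("`yearly_cases` must be nonnegative and non-missing", call. = FALSE)
  mean(yearly_cases)
}

#' Annual rate per 100,000 population
#'
#' @param cases Nonnegative case count (may be fractional).
#' @param pop_aapi Nonnegative population. A zero population yields rate 0
#'   with attribute `zero_pop = TRUE`.
#' @return Rate per 100,000.
#' @examples
#' rate_per_100k(38, 600000)  # 6.333...
#' @export
rate_per_100k <- function(cases, pop_aapi) {
  if (any(cases < 0) || any(pop_aapi < 0))
    stop("`cases` and `pop_aapi` must be nonnegative", call. = FALSE)
  r <- ifelse(pop_aapi > 0, 1e5 * cases / pop_aapi, 0)
  attr(r, "zero_pop") <- pop_aapi == 0
  r
}

#' Reallocate the county residual to suppressed SRAs
#'
#' The residual `R` is the county mean annual total minus the sum of the
#' reported SRA mean annual counts; it is split among the suppressed SRAs in
#' proportion to their AAPI populations. With no suppressed SRA the residual
#' must be zero (within tolerance) and an empty vector is returned.
#'
#' @param county_total_mean_cases County mean annual case total on the
#'   unsuppressed scale.
#' @param records An `sra_case_records` object (see [generate_cases()]) or a
#'   list with `sra_id`, `pop_aapi`, `suppressed`, `yearly`.
#' @param tol Relative tolerance for residual consistency (default 1e-9).
#' @return Named numeric vector of mean annual cases for each suppressed SRA.
#' @examples
#' rec <- list(sra_id = c("A", "B", "C"), pop_aapi = c(5000, 100, 300),
#'             suppressed = c(FALSE, TRUE, TRUE),
#'             yearly = rbind(c(3150, 3150), c(NA, NA), c(NA, NA)))
#' reallocate_suppressed(3530, rec)  # A reported; residual 380 split 95:285
#' @export
reallocate_suppressed <- function(county_total_mean_cases, records,
                                  tol = 1e-9) {
  sup <- records$suppressed
  reported <- if (any(!sup)) {
    sum(apply(records$yearly[!sup, , drop = FALSE], 1, mean_annual_cases))
  } else 0
  R <- county_total_mean_cases - reported
  scale <- max(1, abs(county_total_mean_cases))
  if (R < -tol * scale)
    stop(sprintf(paste0("data inconsistency: reported SRA cases (%.6f) exceed ",
                        "the county total (%.6f)"), reported,
                 county_total_mean_cases), call. = FALSE)
  R <- max(R, 0)
  if (!any(sup)) {
    if (R > tol * scale)
      stop("no suppressed SRA to absorb a positive county residual of ",
           format(R), call. = FALSE)
    return(stats::setNames(numeric(0), character(0)))
  }
  pops <- records$pop_aapi[sup]
  if (sum(pops) <= 0)
    stop("suppressed SRAs have zero total AAPI population; cannot apportion",
         call. = FALSE)
  stats::setNames(R * pops / sum(pops), records$sra_id[sup])
}

#' Apportion SRA cases to constituent tracts
#'
#' Tract cases are the SRA mean annual cases times the tract share of the
#' SRA AAPI population; tract rates are then cases per 100,000 tract AAPI
#' population, which makes the rate constant across the SRA's
#' positive-population tracts. Zero-AAPI tracts receive 0 cases and rate 0.
#' An SRA with zero AAPI population yields all-zero rows flagged `zero_pop`.
#' Fractional cases are retained so that tract cases re-aggregate exactly.
#'
#' @param sra_cases Mean annual cases of the SRA.
#' @param sra_pop_aapi SRA AAPI population; must match the tract sum to
#'   relative tolerance `tol`.
#' @param tracts_in_sra data.frame with `tract_id` and `pop_aapi`.
#' @param tol Relative tolerance for the population consistency check.
#' @return data.frame `tract_id`, `pop_aapi`, `apportioned_cases`,
#'   `rate_per_100k`, `zero_pop`.
#' @export
apportion_to_tracts <- function(sra_cases, sra_pop_aapi, tracts_in_sra,
                                tol = 1e-6) {
  tract_pop <- tracts_in_sra$pop_aapi
  if (abs(sum(tract_pop) - sra_pop_aapi) >
      tol * max(1, abs(sra_pop_aapi)))
    stop(sprintf("tract AAPI populations (%.4f) do not sum to the SRA total (%.4f)",
                 sum(tract_pop), sra_pop_aapi), call. = FALSE)
  if (sra_pop_aapi <= 0) {
    return(data.frame(tract_id = tracts_in_sra$tract_id, pop_aapi = tract_pop,
                      apportioned_cases = 0, rate_per_100k = 0,
                      zero_pop = TRUE, stringsAsFactors = FALSE))
  }
  cases <- sra_cases * tract_pop / sra_pop_aapi
  rate <- ifelse(tract_pop > 0, 1e5 * cases / tract_pop, 0)
  data.frame(tract_id = tracts_in_sra$tract_id, pop_aapi = tract_pop,
             apportioned_cases = cases, rate_per_100k = rate,
             zero_pop = tract_pop == 0, stringsAsFactors = FALSE)
}

#' Downscale SRA case records to tract-level annual rates
#'
#' Full downscaling chain: mean annual counts per reported SRA, proportional
#' reallocation of the county residual to suppressed SRAs
#' ([reallocate_suppressed()]), then population-proportional apportionment of
#' each SRA's cases to its tracts ([apportion_to_tracts()]).
#'
#' @param records An `sra_case_records` object (or compatible list; see
#'   [reallocate_suppressed()]) including `county_total_mean_cases`.
#' @param tracts Tract data.frame with `tract_id`, `sra_id`, `pop_aapi`.
#' @return data.frame with one row per tract: `tract_id`, `sra_id`,
#'   `pop_aapi`, `apportioned_cases`, `rate_per_100k`, `provenance`
#'   (`reported`, `reallocated` or `zero_pop`).
#' @export
downscale_rates <- function(records, tracts) {
  if (!all(records$sra_id %in% tracts$sra_id))
    stop("case records reference SRAs absent from `tracts`", call. = FALSE)
  sup <- records$suppressed
  means <- stats::setNames(rep(NA_real_, length(records$sra_id)),
                           records$sra_id)
  if (any(!sup))
    means[!sup] <- apply(records$yearly[!sup, , drop = FALSE], 1,
                         mean_annual_cases)
  realloc <- reallocate_suppressed(records$county_total_mean_cases, records)
  means[names(realloc)] <- realloc
  out <- vector("list", length(records$sra_id))
  for (i in seq_along(records$sra_id)) {
    sid <- records$sra_id[i]
    rows <- apportion_to_tracts(means[[sid]], records$pop_aapi[i],
                                tracts[tracts$sra_id == sid,
                                       c("tract_id", "pop_aapi")])
    rows$sra_id <- sid
    rows$provenance <- ifelse(rows$zero_pop, "zero_pop",
                              if (sup[i]) "reallocated" else "reported")
    out[[i]] <- rows
  }
  res <- do.call(rbind, out)
  res <- res[match(tracts$tract_id, res$tract_id),
             c("tract_id", "sra_id", "pop_aapi", "apportioned_cases",
               "rate_per_100k", "provenance")]
  rownames(res) <- NULL
  res
}
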
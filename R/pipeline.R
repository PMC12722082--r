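#' Pipeline configuration
#'
#' @param mode `"synthetic"` (generate a county) or `"files"` (load inputs).
#' @param county A [county_config()] (synthetic mode).
#' @param paths Named list of input paths (files mode): `tracts` (GeoJSON),
#'   `outlets` (CSV), `supermarkets` (CSV), `pop_points` (CSV), `cases` and
#'   `sra_pop` (CSV), `resolutions` (CSV), and numeric
#'   `county_total_mean_cases`.
#' @param lexicon A [lexicon()] (default [default_lexicon()]).
#' @param distance_threshold Supermarket-distance threshold in metres
#'   (default 804.672, half a mile).
#' @param knn_k Neighbours for the kNN residual diagnostics (default 8).
#' @param permutations Permutation draws for variable-level Moran tests.
#' @param screen_threshold Spearman screen threshold (default 0.90).
#' @param seed Root seed.
#' @param out_dir Output directory for artifacts.
#' @return A validated `pipeline_config` object.
#' @export
pipeline_config <- function(mode = c("synthetic", "files"),
                            county = county_config(), paths = list(),
                            lexicon = default_lexicon(),
                            distance_threshold = 804.672, knn_k = 8,
                            permutations = 999, screen_threshold = 0.90,
                            seed = 1L, out_dir = tempfile("foodaccess-run-")) {
  mode <- match.arg(mode)
  if (distance_threshold <= 0) stop_field("distance_threshold", "must be > 0")
  if (screen_threshold <= 0) stop_field("screen_threshold", "must be > 0")
  if (knn_k < 1) stop_field("knn_k", "must be >= 1")
  if (mode == "files") {
    need <- c("tracts", "outlets", "supermarkets", "pop_points", "cases",
              "sra_pop", "county_total_mean_cases")
    miss <- setdiff(need, names(paths))
    if (length(miss))
      stop_field("paths", paste("missing entries:", paste(miss, collapse = ", ")))
  }
  structure(list(mode = mode, county = county, paths = paths,
                 lexicon = lexicon, distance_threshold = distance_threshold,
                 knn_k = knn_k, permutations = permutations,
                 screen_threshold = screen_threshold, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "pipeline_config")
}

stage_error <- function(stage, e) {
  stop(sprintf("[stage:%s] %s", stage, conditionMessage(e)), call. = FALSE)
}

#' Run the full food-access analysis pipeline
#'
#' Orchestrates generate-or-load, outlet classification, access measures,
#' rate downscaling, per-variable Moran tests, the Spearman collinearity
#' screen, and the OLS + spatial-lag model battery, writing every report to
#' `config$out_dir` along with a run manifest (seed, stage counts, config
#' hash, package version). Any stage error aborts with a stage-tagged
#' message; artifacts written before the failure are retained.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the in-memory results (`tracts`,
#'   `measures`, `rates`, `moran`, `screen`, `battery`, `manifest`) and
#'   `artifacts` (the written file paths).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  art <- function(f) file.path(config$out_dir, f)
  log_counts <- list()

  # --- stage: inputs -------------------------------------------------------
  inputs <- tryCatch({
    if (config$mode == "synthetic") {
      cty_cfg <- config$county
      cty_cfg$seed <- stage_seed(config$seed, "pipeline")
      cty <- simulate_county(cty_cfg)
      list(tracts = cty$tracts, outlets = cty$outlets,
           resolutions = cty$resolutions, supermarkets = cty$supermarkets,
           pop_points = cty$pop_points, cases = cty$cases,
           weights = cty$weights)
    } else {
      tracts <- read_tracts_geojson(config$paths$tracts)
      outlets <- read_outlets_csv(config$paths$outlets)
      resolutions <- if (!is.null(config$paths$resolutions))
        utils::read.csv(config$paths$resolutions, stringsAsFactors = FALSE)
      else data.frame(outlet_id = character(), content = character())
      list(tracts = tracts, outlets = outlets, resolutions = resolutions,
           supermarkets = utils::read.csv(config$paths$supermarkets,
                                          stringsAsFactors = FALSE),
           pop_points = utils::read.csv(config$paths$pop_points,
                                        stringsAsFactors = FALSE),
           cases = read_sra_cases_csv(config$paths$cases,
                                      config$paths$sra_pop,
                                      config$paths$county_total_mean_cases),
           weights = NULL)
    }
  }, error = function(e) stage_error("inputs", e))
  tracts <- inputs$tracts
  W_queen <- inputs$weights %||% row_standardize(queen_weights(tracts))
  W_knn <- knn_weights(tracts, k = config$knn_k)
  log_counts$n_tracts <- nrow(tracts)
  log_counts$n_outlets_in <- nrow(inputs$outlets)

  # --- stage: classify -----------------------------------------------------
  groups <- tryCatch(
    classify_outlets(inputs$outlets, config$lexicon, inputs$resolutions),
    error = function(e) stage_error("classify", e))
  log_counts$n_excluded <- attr(groups, "n_excluded")
  log_counts$n_ambiguous_resolved <-
    sum(groups$content_label %in% c("aapi", "non_aapi") &
          groups$outlet_id %in% inputs$resolutions$outlet_id)
  log_counts$group_counts <- as.list(attr(groups, "counts"))
  write_outlets_csv(groups, art("classified_outlets.csv"))

  # --- stage: measures -----------------------------------------------------
  measures <- tryCatch(
    access_measures(tracts, groups, inputs$pop_points, inputs$supermarkets,
                    threshold = config$distance_threshold),
    error = function(e) stage_error("measures", e))
  log_counts$n_outlets_outside <- attr(measures, "n_outside") %||% 0
  log_counts$n_tracts_missing_measures <-
    sum(!stats::complete.cases(measures[c("rest_ratio", "groc_ratio",
                                          "rest_per_aapi", "groc_per_aapi",
                                          "fara_ct", "fara_aapi")]))
  utils::write.csv(measures, art("measures.csv"), row.names = FALSE)

  # --- stage: downscale ----------------------------------------------------
  rates <- tryCatch(downscale_rates(inputs$cases, tracts),
                    error = function(e) stage_error("downscale", e))
  log_counts$n_sras_reallocated <- sum(inputs$cases$suppressed)
  utils::write.csv(rates, art("rates.csv"), row.names = FALSE)

  # --- stage: spatial statistics ------------------------------------------
  d <- merge(merge(tracts[setdiff(names(tracts), "geometry")],
                   measures, by = "tract_id", sort = FALSE),
             rates[c("tract_id", "rate_per_100k")], by = "tract_id",
             sort = FALSE)
  d <- d[match(tracts$tract_id, d$tract_id), ]
  # order matters for the greedy screen: the later of a correlated pair is
  # dropped, so list the preferred representative of each aspect first
  measure_vars <- c("fara_aapi", "fara_ct", "rest_per_aapi", "groc_per_aapi",
                    "rest_ratio", "groc_ratio", "rest_intensity",
                    "groc_intensity")
  moran <- tryCatch(
    moran_report(d, c("rate_per_100k", measure_vars), W_knn,
                 method = "permutation",
                 n_permutations = config$permutations,
                 seed = stage_seed(config$seed, "moran")),
    error = function(e) stage_error("moran", e))
  utils::write.csv(moran, art("moran_report.csv"), row.names = FALSE)
  write_weights_csv(W_queen, art("weights_queen.csv"))

  screen <- tryCatch(
    spearman_screen(d[measure_vars], threshold = config$screen_threshold),
    error = function(e) stage_error("screen", e))
  utils::write.csv(screen$dropped, art("screen_dropped.csv"),
                   row.names = FALSE)

  # --- stage: models -------------------------------------------------------
  battery <- tryCatch(
    run_model_battery(d, "rate_per_100k", screen$kept,
                      weights_queen = W_queen, weights_knn = W_knn,
                      seed = stage_seed(config$seed, "battery")),
    error = function(e) stage_error("models", e))
  utils::write.csv(as.data.frame(battery), art("model_battery.csv"),
                   row.names = FALSE)

  # --- manifest ------------------------------------------------------------
  cfg_json <- jsonlite::toJSON(
    list(mode = config$mode,
         county = if (config$mode == "synthetic") unclass(config$county),
         distance_threshold = config$distance_threshold,
         knn_k = config$knn_k, permutations = config$permutations,
         screen_threshold = config$screen_threshold, seed = config$seed),
    auto_unbox = TRUE, digits = NA)
  cfg_path <- art("config.json")
  writeLines(cfg_json, cfg_path)
  manifest <- list(config_hash = unname(tools::md5sum(cfg_path)),
                   seed = config$seed,
                   package_version = as.character(
                     utils::packageVersion("foodaccess")),
                   counts = log_counts)
  jsonlite::write_json(manifest, art("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(list(tracts = tracts, measures = measures, rates = rates,
                 moran = moran, screen = screen, battery = battery,
                 manifest = manifest,
                 artifacts = file.path(config$out_dir,
                                       c("classified_outlets.csv",
                                         "measures.csv", "rates.csv",
                                         "moran_report.csv",
                                         "weights_queen.csv",
                                         "screen_dropped.csv",
                                         "model_battery.csv",
                                         "config.json", "manifest.json"))))
}
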
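#' Read and write tract tables as GeoJSON
#'
#' Tracts are exchanged as a GeoJSON FeatureCollection, one Polygon feature
#' per tract with the demographic fields as properties. Coordinates are
#' assumed planar (a projected system with metre units).
#'
#' @param tracts Tract data.frame with a `geometry` list-column.
#' @param path Output file.
#' @return `write_tracts_geojson()` returns `path` invisibly;
#'   `read_tracts_geojson()` returns the tract data.frame.
#' @export
write_tracts_geojson <- function(tracts, path) {
  props <- tracts[setdiff(names(tracts), "geometry")]
  features <- lapply(seq_len(nrow(tracts)), function(i) {
    ring <- tracts$geometry[[i]]
    list(type = "Feature",
         properties = as.list(props[i, , drop = FALSE]),
         geometry = list(type = "Polygon",
                         coordinates = list(unname(
                           lapply(seq_len(nrow(ring)),
                                  function(r) c(ring[r, 1], ring[r, 2]))))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_tracts_geojson
#' @export
read_tracts_geojson <- function(path) {
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(gj$type, "FeatureCollection"))
    stop("not a GeoJSON FeatureCollection", call. = FALSE)
  rows <- lapply(gj$features, function(f) as.data.frame(f$properties,
                                                        stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out$geometry <- lapply(gj$features, function(f) {
    ring <- f$geometry$coordinates[[1]]
    m <- do.call(rbind, lapply(ring, function(p) as.numeric(c(p[[1]], p[[2]]))))
    colnames(m) <- c("x", "y")
    m
  })
  out
}

#' Write point tables (outlets, supermarkets, population points) as CSV
#'
#' Outlet category lists are serialised pipe-delimited.
#'
#' @param outlets Outlet data.frame with a `categories` list-column.
#' @param path Output file.
#' @return `path`, invisibly; readers return the data.frame.
#' @export
write_outlets_csv <- function(outlets, path) {
  df <- outlets[setdiff(names(outlets), "categories")]
  df$categories <- vapply(outlets$categories, paste, character(1),
                          collapse = "|")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_outlets_csv
#' @export
read_outlets_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$categories <- strsplit(df$categories, "|", fixed = TRUE)
  df
}

#' Write and read SRA case records as CSV
#'
#' The long CSV has columns `sra_id`, `year`, `cases`; suppressed SRAs have
#' blank `cases`. SRA AAPI populations and the county total travel in a
#' second table (`sra_id`, `pop_aapi`) written alongside with a
#' `county_total_mean_cases` attribute row encoded in a JSON sidecar by the
#' pipeline's manifest; `read_sra_cases_csv()` takes both paths.
#'
#' @param records An `sra_case_records` object.
#' @param path Output file for the long case table.
#' @param pop_path Output file for the SRA population table.
#' @return `path`, invisibly.
#' @export
write_sra_cases_csv <- function(records, path, pop_path) {
  n_sra <- length(records$sra_id)
  long <- data.frame(
    sra_id = rep(records$sra_id, each = records$n_years),
    year = rep(seq_len(records$n_years), times = n_sra),
    cases = as.vector(t(records$yearly)))
  utils::write.csv(long, path, row.names = FALSE, na = "")
  utils::write.csv(data.frame(sra_id = records$sra_id,
                              pop_aapi = records$pop_aapi),
                   pop_path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sra_cases_csv
#' @param county_total_mean_cases County mean annual total on the
#'   unsuppressed scale (kept outside the long table because suppressed
#'   cells are blank).
#' @export
read_sra_cases_csv <- function(path, pop_path, county_total_mean_cases) {
  long <- utils::read.csv(path, stringsAsFactors = FALSE)
  pop <- utils::read.csv(pop_path, stringsAsFactors = FALSE)
  sra_ids <- unique(long$sra_id)
  n_years <- max(long$year)
  yearly <- matrix(NA_real_, length(sra_ids), n_years)
  for (i in seq_along(sra_ids)) {
    sub <- long[long$sra_id == sra_ids[i], ]
    yearly[i, sub$year] <- sub$cases
  }
  suppressed <- apply(yearly, 1, function(r) all(is.na(r)))
  structure(list(sra_id = sra_ids,
                 pop_aapi = pop$pop_aapi[match(sra_ids, pop$sra_id)],
                 suppressed = unname(suppressed), yearly = yearly,
                 county_total_mean_cases = county_total_mean_cases,
                 n_years = n_years),
            class = "sra_case_records")
}
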
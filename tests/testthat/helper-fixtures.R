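# small fixtures shared across tests; everything is built in code

small_config <- function(seed = 1L, ...) {
  county_config(n_rows = 6, n_cols = 6, sra_block = 3, seed = seed, ...)
}

# rook-adjacency weights on a k x k grid, built by hand (Moran fixtures)
rook_grid_weights <- function(k) {
  n <- k * k
  ids <- sprintf("R%03d", seq_len(n))
  nb <- vector("list", n)
  for (r in seq_len(k)) for (c in seq_len(k)) {
    i <- (r - 1) * k + c
    v <- integer()
    if (r > 1) v <- c(v, i - k)
    if (r < k) v <- c(v, i + k)
    if (c > 1) v <- c(v, i - 1)
    if (c < k) v <- c(v, i + 1)
    nb[[i]] <- sort(v)
  }
  foodaccess:::new_spweights(ids, nb,
                             lapply(nb, function(v) rep(1, length(v))),
                             scheme = "queen", style = "binary")
}

# checkerboard +/-1 pattern on a k x k grid, row-major
checkerboard <- function(k) {
  as.vector(t(outer(seq_len(k), seq_len(k),
                    function(r, c) ifelse((r + c) %% 2 == 0, 1, -1))))
}

# minimal lexicon used by classifier unit tests
tiny_lexicon <- function() {
  lexicon(restaurant_categories = c("chinese", "mexican", "ramen", "pizza"),
          grocery_keywords = c("grocery", "farmer's market", "food market",
                               "health market"),
          aapi_categories = c("chinese", "ramen", "bubble tea",
                              "asian grocery store"),
          non_aapi_categories = c("mexican", "pizza", "health markets"),
          ambiguous_categories = c("herbs & spices", "grocery", "food market"),
          excluded_categories = c("bookstores"))
}

# tiny outlet table from a named list of category vectors
outlet_table <- function(cats, x = NULL, y = NULL) {
  n <- length(cats)
  out <- data.frame(outlet_id = sprintf("O%03d", seq_len(n)),
                    name = sprintf("outlet %d", seq_len(n)),
                    x = x %||% runif(n), y = y %||% runif(n),
                    stringsAsFactors = FALSE)
  out$categories <- unname(cats)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# hand-built SRA case records list
make_records <- function(sra_id, pop_aapi, suppressed, yearly,
                         county_total = NULL) {
  if (is.null(county_total)) county_total <- sum(rowMeans(yearly), na.rm = TRUE)
  yr <- yearly
  yr[suppressed, ] <- NA_real_
  structure(list(sra_id = sra_id, pop_aapi = pop_aapi,
                 suppressed = suppressed, yearly = yr,
                 county_total_mean_cases = county_total,
                 n_years = ncol(yearly)),
            class = "sra_case_records")
}
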
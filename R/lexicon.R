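#' Build a classification lexicon
#'
#' The lexicon drives the rule-based outlet classifier: exact-match category
#' sets for restaurant type, AAPI / non-AAPI / ambiguous content and
#' exclusions, plus substring keywords for the grocery type. All entries are
#' lower-cased and whitespace-normalised on construction. The AAPI,
#' non-AAPI and ambiguous sets must be pairwise disjoint, and the grocery
#' keywords must include at least "grocery", "farmer's market", "food market"
#' and "health market".
#'
#' @param restaurant_categories Character vector of restaurant categories.
#' @param grocery_keywords Character vector of grocery substrings.
#' @param aapi_categories,non_aapi_categories,ambiguous_categories Character
#'   vectors of content categories.
#' @param excluded_categories Categories marking non-food or location-less
#'   businesses to drop.
#' @return An object of class `lexicon`.
#' @seealso [default_lexicon()], [read_lexicon()]
#' @export
lexicon <- function(restaurant_categories, grocery_keywords,
                    aapi_categories, non_aapi_categories,
                    ambiguous_categories, excluded_categories = character()) {
  norm <- function(x) unique(normalize_category(x))
  lx <- list(restaurant_categories = norm(restaurant_categories),
             grocery_keywords = norm(grocery_keywords),
             aapi_categories = norm(aapi_categories),
             non_aapi_categories = norm(non_aapi_categories),
             ambiguous_categories = norm(ambiguous_categories),
             excluded_categories = norm(excluded_categories))
  required <- c("grocery", "farmer's market", "food market", "health market")
  missing <- setdiff(required, lx$grocery_keywords)
  if (length(missing))
    stop("grocery_keywords must include: ", paste(missing, collapse = ", "),
         call. = FALSE)
  pairs <- list(c("aapi_categories", "non_aapi_categories"),
                c("aapi_categories", "ambiguous_categories"),
                c("non_aapi_categories", "ambiguous_categories"))
  for (p in pairs) {
    ov <- intersect(lx[[p[1]]], lx[[p[2]]])
    if (length(ov))
      stop(sprintf("%s and %s overlap: %s", p[1], p[2],
                   paste(ov, collapse = ", ")), call. = FALSE)
  }
  structure(lx, class = "lexicon")
}

normalize_category <- function(x) {
  x <- tolower(trimws(x))
  gsub("[[:space:]]+", " ", x)
}

#' Default classification lexicon
#'
#' A starter lexicon covering common Yelp-style category names: Asian and
#' Pacific cuisine identifiers and foods (chinese, hawaiian, asian fusion,
#' bubble tea, poke, ramen, ...), non-AAPI cuisines (mexican, traditional
#' american, soul food, beer bar, ...), generic ambiguous terms that may
#' cover AAPI food (herbs & spices, grocery, food market, ...), the grocery
#' keyword set, and exclusions for non-food businesses. Intended as a seed:
#' real registries carry hundreds of categories and users should extend it.
#'
#' @return A [lexicon()].
#' @export
default_lexicon <- function() {
  aapi_rest <- c("chinese", "vietnamese", "korean", "japanese", "thai",
                 "filipino", "indian", "hawaiian", "asian fusion",
                 "bubble tea", "poke", "ramen", "sushi bars", "dim sum",
                 "pan asian", "taiwanese", "cantonese", "szechuan")
  nonaapi_rest <- c("mexican", "traditional american", "american (new)",
                    "italian", "pizza", "burgers", "sandwiches", "seafood",
                    "soul food", "beer bar", "pubs", "steakhouses", "french",
                    "mediterranean", "greek", "breakfast & brunch",
                    "coffee & tea", "delis", "barbeque")
  lexicon(
    restaurant_categories = c(aapi_rest, nonaapi_rest, "restaurants",
                              "food trucks", "buffets"),
    grocery_keywords = c("grocery", "farmer's market", "food market",
                         "health market"),
    aapi_categories = c(aapi_rest, "asian grocery store",
                        "japanese grocery store", "hawaiian food market",
                        "asian market"),
    non_aapi_categories = c(nonaapi_rest, "health markets",
                            "mexican grocery store", "organic food market",
                            "convenience stores", "bakeries", "wineries",
                            "butcher", "farmer's market"),
    ambiguous_categories = c("herbs & spices", "grocery", "food market",
                             "international grocery", "specialty food"),
    excluded_categories = c("bookstores", "food delivery services",
                            "pop-up restaurants"))
}

#' @export
print.lexicon <- function(x, ...) {
  cat("Outlet classification lexicon\n")
  for (f in names(x))
    cat(sprintf("  %s: %d entries\n", f, length(x[[f]])))
  invisible(x)
}

#' Read or write a lexicon as JSON or YAML
#'
#' @param path File path; format chosen by extension (`.json`, `.yaml`/`.yml`).
#' @return `read_lexicon()` returns a [lexicon()]; `write_lexicon()` returns
#'   `path` invisibly.
#' @export
read_lexicon <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is required to read YAML lexicons", call. = FALSE)
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  do.call(lexicon, raw[intersect(names(raw),
                                 c("restaurant_categories", "grocery_keywords",
                                   "aapi_categories", "non_aapi_categories",
                                   "ambiguous_categories", "excluded_categories"))])
}

#' @rdname read_lexicon
#' @param lx A [lexicon()].
#' @export
write_lexicon <- function(lx, path) {
  jsonlite::write_json(unclass(lx), path, auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}
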
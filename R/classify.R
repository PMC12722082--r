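#' Assign the outlet type from its category list
#'
#' Precedence: excluded (any category in the excluded set) > restaurant (any
#' category in the restaurant set) > grocery (any category containing a
#' grocery keyword as a substring) > neither.
#'
#' @param categories Character vector of category strings (lower-cased and
#'   whitespace-normalised internally).
#' @param lexicon A [lexicon()].
#' @return One of `"excluded"`, `"restaurant"`, `"grocery"`, `"neither"`.
#' @examples
#' lx <- default_lexicon()
#' assign_type("chinese", lx)              # restaurant
#' assign_type("asian grocery store", lx)  # grocery (substring match)
#' assign_type("bookstores", lx)           # excluded
#' @export
assign_type <- function(categories, lexicon) {
  cats <- normalize_category(categories)
  if (length(cats) == 0 || all(!nzchar(cats)))
    stop("category list must be nonempty", call. = FALSE)
  if (any(cats %in% lexicon$excluded_categories)) return("excluded")
  if (any(cats %in% lexicon$restaurant_categories)) return("restaurant")
  for (kw in lexicon$grocery_keywords)
    if (any(grepl(kw, cats, fixed = TRUE))) return("grocery")
  "neither"
}

#' Assign the outlet content (AAPI / non-AAPI / ambiguous)
#'
#' Precedence: aapi (any category in the AAPI set) > ambiguous (any category
#' in the ambiguous set) > non_aapi. An outlet with one clearly AAPI category
#' is AAPI regardless of co-occurring general terms.
#'
#' @inheritParams assign_type
#' @return One of `"aapi"`, `"ambiguous"`, `"non_aapi"`.
#' @examples
#' lx <- default_lexicon()
#' assign_content("bubble tea", lx)      # aapi
#' assign_content("herbs & spices", lx)  # ambiguous
#' assign_content("mexican", lx)         # non_aapi
#' @export
assign_content <- function(categories, lexicon) {
  cats <- normalize_category(categories)
  if (length(cats) == 0 || all(!nzchar(cats)))
    stop("category list must be nonempty", call. = FALSE)
  if (any(cats %in% lexicon$aapi_categories)) return("aapi")
  if (any(cats %in% lexicon$ambiguous_categories)) return("ambiguous")
  "non_aapi"
}

#' Classify outlets into five mutually exclusive groups
#'
#' Applies [assign_type()] and [assign_content()] to every outlet, resolves
#' content-ambiguous restaurants and groceries through the supplied
#' resolution table (the reproducible stand-in for a manual review), and
#' partitions all non-excluded outlets into: AAPI restaurants, non-AAPI
#' restaurants, AAPI groceries, non-AAPI groceries, and neither.
#'
#' @param outlets data.frame with columns `outlet_id` and a `categories`
#'   list-column (or a single `categories` character column of
#'   pipe-delimited strings).
#' @param lexicon A [lexicon()].
#' @param resolutions data.frame with columns `outlet_id`, `content`
#'   (values `"aapi"` or `"non_aapi"`); required for every ambiguous
#'   restaurant or grocery.
#' @return An object of class `outlet_groups`: the input data.frame with
#'   added `type_label`, `content_label` and `group` columns, plus attributes
#'   `counts` (named group sizes) and `n_excluded`. Group values:
#'   `aapi_restaurants`, `non_aapi_restaurants`, `aapi_groceries`,
#'   `non_aapi_groceries`, `neither`; excluded outlets carry `NA`.
#' @export
classify_outlets <- function(outlets, lexicon,
                             resolutions = data.frame(outlet_id = character(),
                                                      content = character())) {
  if (!is.list(outlets$categories))
    outlets$categories <- strsplit(as.character(outlets$categories), "|",
                                   fixed = TRUE)
  if (length(resolutions$content) &&
      !all(resolutions$content %in% c("aapi", "non_aapi")))
    stop("resolution values must be 'aapi' or 'non_aapi'", call. = FALSE)
  n <- nrow(outlets)
  type <- character(n); content <- character(n)
  for (i in seq_len(n)) {
    type[i] <- assign_type(outlets$categories[[i]], lexicon)
    content[i] <- if (type[i] == "excluded") "unset"
                  else assign_content(outlets$categories[[i]], lexicon)
  }
  needs_res <- type %in% c("restaurant", "grocery") & content == "ambiguous"
  if (any(needs_res)) {
    m <- match(outlets$outlet_id[needs_res], resolutions$outlet_id)
    if (anyNA(m)) {
      missing_ids <- outlets$outlet_id[needs_res][is.na(m)]
      stop("unresolved ambiguous outlets (provide resolutions): ",
           paste(missing_ids, collapse = ", "), call. = FALSE)
    }
    content[needs_res] <- resolutions$content[m]
  }
  group <- rep(NA_character_, n)
  retained <- type != "excluded"
  group[type == "restaurant"] <- ifelse(content[type == "restaurant"] == "aapi",
                                        "aapi_restaurants", "non_aapi_restaurants")
  group[type == "grocery"] <- ifelse(content[type == "grocery"] == "aapi",
                                     "aapi_groceries", "non_aapi_groceries")
  group[type == "neither"] <- "neither"
  outlets$type_label <- type
  outlets$content_label <- content
  outlets$group <- group
  lv <- c("aapi_restaurants", "non_aapi_restaurants", "aapi_groceries",
          "non_aapi_groceries", "neither")
  counts <- table(factor(group[retained], levels = lv))
  structure(outlets, counts = as.integer(counts) |> stats::setNames(lv),
            n_excluded = sum(!retained), class = c("outlet_groups", "data.frame"))
}

#' @export
print.outlet_groups <- function(x, ...) {
  cnt <- attr(x, "counts")
  cat(sprintf("Classified outlets: %d retained, %d excluded\n",
              sum(cnt), attr(x, "n_excluded")))
  for (g in names(cnt)) cat(sprintf("  %-22s %d\n", g, cnt[[g]]))
  invisible(x)
}
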
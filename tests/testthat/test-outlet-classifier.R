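test_that("type assignment follows excluded > restaurant > grocery > neither", {
  lx <- tiny_lexicon()
  expect_equal(assign_type("chinese", lx), "restaurant")
  expect_equal(assign_type("asian grocery store", lx), "grocery")
  expect_equal(assign_type("bookstores", lx), "excluded")
  expect_equal(assign_type("candle shop", lx), "neither")
  # precedence: restaurant beats grocery keywords, excluded beats everything
  expect_equal(assign_type(c("chinese", "asian grocery store"), lx),
               "restaurant")
  expect_equal(assign_type(c("bookstores", "chinese"), lx), "excluded")
  # substring matching for grocery keywords only
  expect_equal(assign_type("neighborhood food market", lx), "grocery")
  # normalisation: case and whitespace
  expect_equal(assign_type("  Chinese ", lx), "restaurant")
  expect_error(assign_type(character(), lx), "nonempty")
})

test_that("content assignment follows aapi > ambiguous > non_aapi", {
  lx <- tiny_lexicon()
  expect_equal(assign_content("bubble tea", lx), "aapi")
  expect_equal(assign_content("herbs & spices", lx), "ambiguous")
  expect_equal(assign_content("mexican", lx), "non_aapi")
  expect_equal(assign_content(c("grocery", "ramen"), lx), "aapi")
  expect_equal(assign_content("anything unknown", lx), "non_aapi")
  expect_error(assign_content(character(), lx), "nonempty")
})

test_that("classification partitions outlets into the five groups", {
  lx <- tiny_lexicon()
  # one outlet per terminal path
  cats <- list(c("chinese"),                 # aapi restaurant
               c("pizza"),                   # non-aapi restaurant
               c("asian grocery store"),     # aapi grocery
               c("health markets"),          # non-aapi grocery
               c("candle shop"),             # neither
               c("bookstores"))              # excluded
  g <- classify_outlets(outlet_table(cats), lx)
  cnt <- attr(g, "counts")
  expect_equal(unname(cnt), c(1, 1, 1, 1, 1))
  expect_equal(attr(g, "n_excluded"), 1)
  expect_true(is.na(g$group[6]))

  # empty input: five empty groups
  g0 <- classify_outlets(outlet_table(list()), lx)
  expect_equal(sum(attr(g0, "counts")), 0)

  # ambiguous outlets require resolution
  amb <- outlet_table(list(c("grocery"), c("food market")))
  expect_error(classify_outlets(amb, lx), "O001.*O002")
  res <- data.frame(outlet_id = c("O001", "O002"),
                    content = c("aapi", "non_aapi"))
  g2 <- classify_outlets(amb, lx, res)
  expect_equal(g2$group, c("aapi_groceries", "non_aapi_groceries"))
  expect_error(classify_outlets(amb, lx,
                                data.frame(outlet_id = "O001",
                                           content = "maybe")),
               "aapi")
})

test_that("partition, idempotence and monotone-growth properties hold on random inputs", {
  set.seed(101)
  universe <- c(sprintf("cat%02d", 1:40), "grocery", "food market")
  for (rep in 1:20) {
    pools <- split(sample(sprintf("cat%02d", 1:40)),
                   rep(1:4, length.out = 40))
    lx <- lexicon(restaurant_categories = pools[[1]],
                  grocery_keywords = c("grocery", "farmer's market",
                                       "food market", "health market"),
                  aapi_categories = pools[[2]],
                  non_aapi_categories = pools[[3]],
                  ambiguous_categories = c(pools[[4]], "grocery",
                                           "food market"),
                  excluded_categories = "bookstores")
    cats <- replicate(60, sample(universe, sample(1:3, 1)), simplify = FALSE)
    ot <- outlet_table(cats)
    res <- data.frame(outlet_id = ot$outlet_id,
                      content = sample(c("aapi", "non_aapi"), 60,
                                       replace = TRUE))
    g <- classify_outlets(ot, lx, res)
    retained <- !is.na(g$group)
    # partition: groups disjoint and exhaustive over retained outlets
    expect_equal(sum(attr(g, "counts")), sum(retained))
    expect_equal(sum(attr(g, "counts")) + attr(g, "n_excluded"), nrow(ot))
    # idempotence: reclassifying yields identical labels
    g2 <- classify_outlets(as.data.frame(g), lx, res)
    expect_equal(g2$group, g$group)
    expect_equal(g2$type_label, g$type_label)
    # monotone growth: adding a category to the AAPI set never removes
    # an outlet from an AAPI group
    newcat <- sample(setdiff(pools[[3]], character(0)), 1)
    lx2 <- lexicon(restaurant_categories = lx$restaurant_categories,
                   grocery_keywords = lx$grocery_keywords,
                   aapi_categories = c(lx$aapi_categories, newcat),
                   non_aapi_categories = setdiff(lx$non_aapi_categories,
                                                 newcat),
                   ambiguous_categories = lx$ambiguous_categories,
                   excluded_categories = lx$excluded_categories)
    g3 <- classify_outlets(ot, lx2, res)
    was_aapi <- g$group %in% c("aapi_restaurants", "aapi_groceries")
    expect_true(all(g3$group[was_aapi] %in% c("aapi_restaurants",
                                              "aapi_groceries")))
  }
})

test_that("lexicon construction enforces disjointness and required keywords", {
  expect_error(lexicon(restaurant_categories = "a",
                       grocery_keywords = "grocery",
                       aapi_categories = "b", non_aapi_categories = "c",
                       ambiguous_categories = "d"),
               "grocery_keywords")
  expect_error(lexicon(restaurant_categories = "a",
                       grocery_keywords = c("grocery", "farmer's market",
                                            "food market", "health market"),
                       aapi_categories = "b", non_aapi_categories = "b",
                       ambiguous_categories = "d"),
               "overlap")
})

test_that("lexicon JSON round-trips", {
  lx <- default_lexicon()
  p <- withr::local_tempfile(fileext = ".json")
  write_lexicon(lx, p)
  lx2 <- read_lexicon(p)
  expect_equal(lx2, lx)
})
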
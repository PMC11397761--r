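test_that("registry parsing round-trips rows and collects rejects with reasons", {
  rows <- rbind(
    do.call(rbind, lapply(sprintf("M%02d", 1:10), basic_basket_rows)),
    registry_row("M11", food_name = "arroz", quantity = 2, unit = "docena"),
    registry_row("M12", food_name = "arroz", quantity = -3),
    registry_row("M13", food_name = "arroz", beneficiaries = 0)
  )
  parsed <- parse_registry(write_temp_registry(rows))
  expect_equal(nrow(parsed$items) + nrow(parsed$rejects), nrow(rows))
  expect_equal(nrow(parsed$municipalities), 10)
  expect_setequal(parsed$rejects$reject_reason,
                  c("unknown unit", "non-positive quantity", "beneficiaries < 1"))

  # same rows through the JSON dialect
  jpath <- tempfile(fileext = ".json")
  jsonlite::write_json(rows, jpath, dataframe = "rows", na = "null")
  jparsed <- parse_registry(jpath)
  expect_equal(jparsed$items$quantity, parsed$items$quantity)
  expect_equal(nrow(jparsed$rejects), nrow(parsed$rejects))
})

test_that("an empty registry yields an empty result with a warning", {
  path <- tempfile(fileext = ".csv")
  writeLines(paste(canasta:::REGISTRY_COLUMNS, collapse = ","), path)
  expect_warning(parsed <- parse_registry(path), "empty")
  expect_equal(nrow(parsed$items), 0)
})

test_that("missing registry columns raise a schema error", {
  rows <- basic_basket_rows()
  rows$unit <- NULL
  expect_error(parse_registry(write_temp_registry(rows)),
               regexp = "unit", class = "canasta_schema_error")
})

test_that("unit records convert to grams through market prices", {
  expect_equal(approximate_weight(1, 5.00, 10.00), 500)
  expect_equal(approximate_weight(4, 2.50, 10.00), 1000)
  expect_error(approximate_weight(1, NA_real_, 10), class = "canasta_unresolved_item")
  expect_error(approximate_weight(1, 5, NA_real_), class = "canasta_unresolved_item")

  # strictly increasing in price and quantity
  prices <- seq(0.5, 10, by = 0.5)
  expect_true(all(diff(approximate_weight(2, prices, 8)) > 0))
  expect_true(all(diff(approximate_weight(prices, 2, 8)) > 0))
})

test_that("volume units convert with per-group density overrides", {
  g <- canasta:::unit_to_grams(
    quantity = c(2, 500, 1, 250), unit = c("kg", "g", "L", "mL"),
    group = c("cereals", "cereals", "oils", "dairy")
  )
  expect_equal(g, c(2000, 500, 1000, 250))
  g2 <- canasta:::unit_to_grams(1, "L", "oils", densities = c(oils = 0.92))
  expect_equal(g2, 920)
})

test_that("basket selection takes the most-distributed variant, deterministically", {
  b <- data.frame(basket_id = c("b1", "b2"), beneficiaries = c(500, 1200))
  expect_equal(select_basket(b), "b2")
  expect_equal(select_basket(b[1, ]), "b1")
  tie <- data.frame(basket_id = c("b2", "b1"), beneficiaries = c(800, 800))
  expect_equal(select_basket(tie), "b1")
  expect_equal(select_basket(tie[2:1, ]), "b1")
})

test_that("inclusion/exclusion partitions baskets with machine-readable reasons", {
  tab <- tiny_composition()
  prices <- tiny_prices()
  rows <- rbind(
    basic_basket_rows("M1"),                       # kept: 3 foods, sane masses
    basic_basket_rows("M2")[1:2, ],                # too few foods
    {
      r <- basic_basket_rows("M3")                 # one 600 kg item
      r$quantity[1] <- 600
      r
    }
  )
  parsed <- parse_registry(write_temp_registry(rows))
  res <- resolve_items(parsed$items, tab, prices)
  out <- apply_inclusion_exclusion(res$resolved, res$unresolved)

  expect_equal(length(out$kept), 1)
  expect_equal(out$kept[[1]]$municipality_id, "M1")
  expect_gte(out$kept[[1]]$n_distinct_foods, 3)
  expect_equal(out$excluded$reason[out$excluded$municipality_id == "M2"],
               "too_few_foods")
  expect_equal(out$excluded$reason[out$excluded$municipality_id == "M3"],
               "extreme_value")
  # partition: kept + excluded = input baskets
  expect_equal(length(out$kept) + nrow(out$excluded), 3)
})

test_that("baskets with too many unresolvable items are excluded", {
  tab <- tiny_composition()
  prices <- tiny_prices()
  rows <- basic_basket_rows("M1")
  rows <- rbind(rows, registry_row("M1", food_name = "qqqq zzzz", quantity = 1),
                registry_row("M1", food_name = "wwww vvvv", quantity = 1))
  parsed <- parse_registry(write_temp_registry(rows))
  res <- resolve_items(parsed$items, tab, prices)
  expect_equal(nrow(res$unresolved), 2)
  expect_true(all(res$unresolved$reason == "unresolved_food"))
  out <- apply_inclusion_exclusion(res$resolved, res$unresolved)
  expect_equal(out$excluded$reason, "unresolved_items")

  # a unit record without a price is unresolved, not fatal
  rows2 <- basic_basket_rows("M2")
  rows2$unit[1] <- "unit"
  parsed2 <- parse_registry(write_temp_registry(rows2))
  res2 <- resolve_items(parsed2$items, tab, prices[-1, ])
  expect_equal(res2$unresolved$reason, "no_price_for_unit_record")
})
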
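test_that("basket energy and caloric distribution follow the Atwater factors", {
  tab <- as_composition_table(data.frame(
    code = "X1", name = "mixed food", group = "cereals",
    energy_kcal_100g = 165, protein_g_100g = 10, fat_g_100g = 10,
    carb_g_100g = 10, stringsAsFactors = FALSE
  ))
  p <- basket_profile(make_basket("X1", 100, tab), tab)
  expect_equal(p$energy_kcal, 170) # 4*10 + 9*10 + 4*10
  expect_equal(p$pct_protein, 100 * 40 / 170)
  expect_equal(p$pct_fat, 100 * 90 / 170)
  expect_equal(p$pct_carb, 100 * 40 / 170)
  expect_equal(p$table_energy_kcal, 165)

  # a pure-oil basket puts all energy on fat
  oil <- tiny_composition()
  po <- basket_profile(make_basket("O01", 1000, oil), oil)
  expect_equal(po$pct_fat, 100)
  expect_equal(po$pct_protein, 0)
  expect_equal(po$pct_carb, 0)
})

test_that("profiles are additive across items (item-by-item oracle)", {
  tab <- tiny_composition()
  codes <- c("R01", "S01", "O01", "M01", "L01")
  masses <- c(10000, 4000, 1000, 700, 2000)

  p <- basket_profile(make_basket(codes, masses, tab), tab)

  # brute-force: sum nutrients_for_mass item by item
  acc <- c(protein_g = 0, fat_g = 0, carb_g = 0)
  for (i in seq_along(codes)) {
    e <- tab$entries[tab$entries$code == codes[i], ]
    nf <- nutrients_for_mass(e, masses[i])
    acc <- acc + c(nf$protein_g, nf$fat_g, nf$carb_g)
  }
  expect_equal(p$protein_g, acc[["protein_g"]])
  expect_equal(p$fat_g, acc[["fat_g"]])
  expect_equal(p$carb_g, acc[["carb_g"]])
  expect_equal(p$energy_kcal, 4 * acc[["protein_g"]] + 9 * acc[["fat_g"]] +
                 4 * acc[["carb_g"]])

  # two-item basket equals the sum of its single-item profiles
  p1 <- basket_profile(make_basket("R01", 5000, tab), tab)
  p2 <- basket_profile(make_basket("L01", 2000, tab), tab)
  p12 <- basket_profile(make_basket(c("R01", "L01"), c(5000, 2000), tab), tab)
  expect_equal(p12$protein_g, p1$protein_g + p2$protein_g)
  expect_equal(p12$energy_kcal, p1$energy_kcal + p2$energy_kcal)
})

test_that("percentages are scale-invariant and sum to 100", {
  tab <- tiny_composition()
  codes <- c("R01", "S01", "O01", "M01")
  masses <- c(8000, 3000, 1500, 900)
  p <- basket_profile(make_basket(codes, masses, tab), tab)
  p3 <- basket_profile(make_basket(codes, 3 * masses, tab), tab)
  expect_equal(p3$energy_kcal, 3 * p$energy_kcal)
  expect_equal(p3$protein_g, 3 * p$protein_g)
  expect_equal(p3$pct_protein, p$pct_protein)
  expect_equal(p3$pct_fat, p$pct_fat)
  expect_equal(p$pct_protein + p$pct_fat + p$pct_carb, 100, tolerance = 1e-12)
})

test_that("swapping protein and carbohydrate grams swaps their percentages", {
  base <- data.frame(
    code = "Y1", name = "foodstuff", group = "cereals",
    energy_kcal_100g = 200, protein_g_100g = 12, fat_g_100g = 5,
    carb_g_100g = 30, stringsAsFactors = FALSE
  )
  swapped <- base
  swapped$protein_g_100g <- base$carb_g_100g
  swapped$carb_g_100g <- base$protein_g_100g
  t1 <- as_composition_table(base)
  t2 <- as_composition_table(swapped)
  p1 <- basket_profile(make_basket("Y1", 500, t1), t1)
  p2 <- basket_profile(make_basket("Y1", 500, t2), t2)
  expect_equal(p1$pct_protein, p2$pct_carb)
  expect_equal(p1$pct_carb, p2$pct_protein)
  expect_equal(p1$pct_fat, p2$pct_fat)
})

test_that("zero-energy baskets are flagged, not silently zeroed", {
  tab <- as_composition_table(data.frame(
    code = "W1", name = "water like", group = "vegetables",
    energy_kcal_100g = 0, protein_g_100g = 0, fat_g_100g = 0,
    carb_g_100g = 0, stringsAsFactors = FALSE
  ))
  expect_error(basket_profile(make_basket("W1", 1000, tab), tab),
               class = "canasta_zero_energy")
})

test_that("group quantities sum per group in kg and report absent groups as 0", {
  tab <- tiny_composition()
  q <- group_quantities(make_basket(c("R01", "S01", "O01"),
                                    c(5000, 2000, 1000), tab))
  expect_equal(q[["cereals"]], 5)
  expect_equal(q[["sugars"]], 2)
  expect_equal(q[["oils"]], 1)
  expect_equal(sum(q[c("meats", "dairy", "legumes", "fruits", "eggs",
                       "vegetables", "tubers")]), 0)
  expect_equal(sum(q), 8) # total basket mass, kg

  # duplicate foods in the same group accumulate
  qq <- group_quantities(make_basket(c("R01", "R01"), c(3000, 4000), tab))
  expect_equal(qq[["cereals"]], 7)

  # degenerate: no items at all
  empty <- structure(list(items = data.frame(mass_g = numeric(0),
                                             group = character(0))),
                     class = "basket_record")
  expect_equal(sum(group_quantities(empty)), 0)
})
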
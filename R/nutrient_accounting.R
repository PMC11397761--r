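# Per-basket energy, macronutrient totals, caloric-distribution percentages
# and per-food-group quantities.

# Atwater energy-conversion factors, kcal per gram
ATWATER <- c(protein = 4, fat = 9, carb = 4)

#' Nutrient profile of a basket
#'
#' Sums the contributions of every resolved item (no food is excluded from
#' the accounting) and derives the caloric distribution: each macronutrient's
#' energy divided by the basket's total energy, times 100. Total energy is
#' the Atwater sum `4*protein + 9*fat + 4*carb`, so the three percentages
#' always sum to exactly 100; the composition table's own energy column is
#' also accumulated and reported as `table_energy_kcal` for comparison.
#'
#' @param basket a `basket_record`.
#' @param table a `composition_table`.
#' @return a `nutrient_profile`: list with `municipality_id`, `protein_g`,
#'   `fat_g`, `carb_g`, `energy_kcal`, `table_energy_kcal`, `pct_protein`,
#'   `pct_fat`, `pct_carb`.
#' @export
basket_profile <- function(basket, table) {
  stopifnot(inherits(basket, "basket_record"), inherits(table, "composition_table"))
  idx <- match(basket$items$code, table$entries$code)
  if (anyNA(idx)) {
    canasta_error("canasta_unknown_code",
                  sprintf("basket %s/%s holds code(s) absent from the composition table",
                          basket$municipality_id, basket$basket_id))
  }
  f <- basket$items$mass_g / 100
  protein_g <- sum(table$entries$protein_g_100g[idx] * f)
  fat_g <- sum(table$entries$fat_g_100g[idx] * f)
  carb_g <- sum(table$entries$carb_g_100g[idx] * f)
  table_energy_kcal <- sum(table$entries$energy_kcal_100g[idx] * f)
  energy_kcal <- ATWATER[["protein"]] * protein_g + ATWATER[["fat"]] * fat_g +
    ATWATER[["carb"]] * carb_g
  if (energy_kcal <= 0) {
    canasta_error("canasta_zero_energy",
                  sprintf("basket %s/%s has zero total energy; caloric distribution undefined",
                          basket$municipality_id, basket$basket_id))
  }
  structure(
    list(
      municipality_id = basket$municipality_id,
      basket_id = basket$basket_id,
      domain = basket$domain,
      budget_group = basket$budget_group,
      protein_g = protein_g, fat_g = fat_g, carb_g = carb_g,
      energy_kcal = energy_kcal,
      table_energy_kcal = table_energy_kcal,
      pct_protein = 100 * ATWATER[["protein"]] * protein_g / energy_kcal,
      pct_fat = 100 * ATWATER[["fat"]] * fat_g / energy_kcal,
      pct_carb = 100 * ATWATER[["carb"]] * carb_g / energy_kcal
    ),
    class = "nutrient_profile"
  )
}

#' @export
print.nutrient_profile <- function(x, ...) {
  cat(sprintf(
    "<nutrient_profile> %s: %.0f kcal | protein %.1f%%, carb %.1f%%, fat %.1f%%\n",
    x$municipality_id, x$energy_kcal, x$pct_protein, x$pct_carb, x$pct_fat
  ))
  invisible(x)
}

#' Quantities per food group in a basket
#'
#' Total kilograms per Food Guide group (volumes already converted to mass at
#' ingest); the ten groups are always reported, absent groups as 0.
#'
#' @param basket a `basket_record`.
#' @return named numeric vector over the ten food groups, in kg.
#' @export
group_quantities <- function(basket) {
  stopifnot(inherits(basket, "basket_record"))
  out <- stats::setNames(numeric(length(FOOD_GROUPS)), FOOD_GROUPS)
  if (nrow(basket$items)) {
    sums <- tapply(basket$items$mass_g, basket$items$group, sum)
    out[names(sums)] <- sums / 1000
  }
  out
}

#' Collect nutrient profiles for a list of baskets into a data frame
#'
#' @param baskets list of `basket_record` objects.
#' @param table a `composition_table`.
#' @return data frame, one row per basket, with grams, kcal and percentages.
#' @export
profile_table <- function(baskets, table) {
  rows <- lapply(baskets, function(b) {
    p <- basket_profile(b, table)
    data.frame(
      municipality_id = p$municipality_id, basket_id = p$basket_id,
      domain = p$domain, budget_group = p$budget_group,
      energy_kcal = p$energy_kcal, table_energy_kcal = p$table_energy_kcal,
      protein_g = p$protein_g, fat_g = p$fat_g, carb_g = p$carb_g,
      pct_protein = p$pct_protein, pct_fat = p$pct_fat, pct_carb = p$pct_carb,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Collect per-group quantities for a list of baskets into a data frame
#'
#' @inheritParams profile_table
#' @return data frame, one row per basket, one column per food group (kg).
#' @export
group_quantity_table <- function(baskets) {
  rows <- lapply(baskets, function(b) {
    q <- group_quantities(b)
    cbind(
      data.frame(municipality_id = b$municipality_id, basket_id = b$basket_id,
                 domain = b$domain, budget_group = b$budget_group,
                 stringsAsFactors = FALSE),
      as.data.frame(as.list(q))
    )
  })
  do.call(rbind, rows)
}
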
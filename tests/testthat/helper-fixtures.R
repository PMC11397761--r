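# Shared fixtures: tiny in-code composition tables, registry builders, and
# an independent simulation oracle for the generator's implied caloric
# distribution.

tiny_composition <- function() {
  as_composition_table(data.frame(
    code = c("R01", "S01", "O01", "M01", "L01"),
    name = c("arroz", "azucar", "aceite vegetal", "canned fish", "lenteja"),
    group = c("cereals", "sugars", "oils", "meats", "legumes"),
    energy_kcal_100g = c(358, 380, 884, 105, 338),
    protein_g_100g = c(7.8, 0, 0, 23.6, 23.5),
    fat_g_100g = c(0.7, 0, 100, 1.0, 1.3),
    carb_g_100g = c(81.7, 98, 0, 0, 60.8),
    stringsAsFactors = FALSE
  ))
}

tiny_prices <- function() {
  data.frame(
    food_name = c("arroz", "azucar", "aceite vegetal", "canned fish", "lenteja"),
    wholesale_price_per_kg = c(3, 2.5, 6, 16, 5),
    retail_price_per_kg = c(4, 3.5, 8, 20, 7),
    mean_price_per_kg = c(3.5, 3, 7, 18, 6),
    stringsAsFactors = FALSE
  )
}

registry_row <- function(municipality_id = "M1", domain = "sierra",
                         budget_group = "A", population = 5000,
                         basket_id = "B1", beneficiaries = 100,
                         food_name = "arroz", quantity = 10, unit = "kg",
                         unit_price = NA_real_) {
  data.frame(municipality_id, domain, budget_group, population, basket_id,
             beneficiaries, food_name, quantity, unit, unit_price,
             stringsAsFactors = FALSE)
}

write_temp_registry <- function(rows) {
  path <- tempfile(fileext = ".csv")
  utils::write.csv(rows, path, row.names = FALSE, na = "")
  path
}

# A standard three-food basket that passes inclusion
basic_basket_rows <- function(municipality_id = "M1", basket_id = "B1",
                              beneficiaries = 100, domain = "sierra",
                              budget_group = "A") {
  rbind(
    registry_row(municipality_id, domain, budget_group, 5000, basket_id,
                 beneficiaries, "arroz", 10, "kg"),
    registry_row(municipality_id, domain, budget_group, 5000, basket_id,
                 beneficiaries, "azucar", 4, "kg"),
    registry_row(municipality_id, domain, budget_group, 5000, basket_id,
                 beneficiaries, "aceite vegetal", 1, "L")
  )
}

# Build a basket_record directly from (code, mass_g) pairs against a table
make_basket <- function(codes, mass_g, table, municipality_id = "M1") {
  idx <- match(codes, table$entries$code)
  items <- data.frame(
    municipality_id = municipality_id, basket_id = "B1", domain = "sierra",
    budget_group = "A", beneficiaries = 100,
    food_name = table$entries$name[idx], code = codes,
    group = table$entries$group[idx], mass_g = mass_g,
    weight_approximated = FALSE, similarity_matched = FALSE,
    stringsAsFactors = FALSE
  )
  canasta:::new_basket_record(items)
}

# Independent oracle: the median caloric distribution implied by a generator
# configuration, computed by drawing group masses directly from the
# configured distributions (not through registry generation or the
# pipeline). Shares only the configuration semantics with the generator.
direct_pct_median_oracle <- function(cfg, M = 60000, seed = 4242) {
  comp <- utils::read.csv(canasta_example("composition_table.csv"))
  menu <- canasta:::CORE_MENU
  minor <- canasta:::MINOR_MENU
  core <- names(cfg$group_medians_kg)
  sigma_tot <- sqrt(cfg$group_sigma^2 + cfg$basket_sigma^2)

  # re-derive the median-centered stratum log-shifts from the ratio tables
  dlr <- log(canasta:::DOMAIN_RATIOS[, core, drop = FALSE])
  blr <- log(canasta:::BUDGET_RATIOS[, core, drop = FALSE])
  w16 <- as.numeric(outer(cfg$domain_weights, cfg$budget_weights))
  for (g in core) {
    s <- as.numeric(outer(dlr[, g], blr[, g], "+"))
    c_g <- stats::uniroot(
      function(cc) sum(w16 * stats::pnorm((cc - s) / sigma_tot[[g]])) - 0.5,
      interval = range(s) + c(-1, 1)
    )$root
    dlr[, g] <- dlr[, g] - c_g
  }
  if (!cfg$stratum_effects) {
    dlr[] <- 0
    blr[] <- 0
  }

  set.seed(seed)
  dom <- sample(rownames(dlr), M, TRUE, cfg$domain_weights)
  bud <- sample(rownames(blr), M, TRUE, cfg$budget_weights)
  size <- stats::rnorm(M, 0, cfg$basket_sigma)
  dens <- function(fn, col) comp[[col]][match(fn, comp$name)]
  P <- F_ <- C <- numeric(M)
  for (g in core) {
    m_kg <- exp(log(cfg$group_medians_kg[[g]]) + dlr[dom, g] + blr[bud, g] +
                  size + stats::rnorm(M, 0, cfg$group_sigma[[g]]))
    mn <- menu[menu$group == g, , drop = FALSE]
    for (i in seq_len(nrow(mn))) {
      u <- m_kg * mn$share[i] * 10 # kg -> units of 100 g
      P <- P + u * dens(mn$food_name[i], "protein_g_100g")
      F_ <- F_ + u * dens(mn$food_name[i], "fat_g_100g")
      C <- C + u * dens(mn$food_name[i], "carb_g_100g")
    }
  }
  for (i in seq_len(nrow(minor))) {
    inc <- stats::runif(M) < cfg$minor_group_prob
    u <- exp(log(minor$median_kg[i]) + stats::rnorm(M, 0, 0.4)) * inc * 10
    P <- P + u * dens(minor$food_name[i], "protein_g_100g")
    F_ <- F_ + u * dens(minor$food_name[i], "fat_g_100g")
    C <- C + u * dens(minor$food_name[i], "carb_g_100g")
  }
  E <- 4 * P + 9 * F_ + 4 * C
  c(pct_protein = stats::median(400 * P / E),
    pct_fat = stats::median(900 * F_ / E),
    pct_carb = stats::median(400 * C / E))
}

# Run the full pipeline on a generated registry; returns run_pipeline()'s value
run_synthetic_pipeline <- function(cfg, out_dir = tempfile("synthrun_")) {
  frame <- generate_frame(cfg)
  gen <- generate_registry(frame, cfg)
  path <- tempfile(fileext = ".csv")
  write_registry(gen$registry, path)
  run_pipeline(pipeline_config(path, out_dir = out_dir, seed = cfg$seed))
}
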
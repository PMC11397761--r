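# Synthetic registry generator: emulates the structure of the municipal
# basket reports (stratified frame, multi-basket municipalities, log-normal
# food quantities with domain/budget shifts, "unit" records priced per item,
# extreme data-entry errors) so the whole pipeline runs without any download.

# Published national medians and IQRs (kg; oils in L) per core food group,
# used as the default quantity targets.
DEFAULT_GROUP_MEDIANS <- c(
  sugars = 5.0, meats = 0.7, cereals = 13.1, oils = 2.0, dairy = 1.6, legumes = 2.0
)
DEFAULT_GROUP_IQR <- list(
  sugars = c(3.0, 6.0), meats = c(0.5, 1.0), cereals = c(10.0, 17.0),
  oils = c(1.0, 3.0), dairy = c(1.2, 2.0), legumes = c(2.0, 4.0)
)

# Stratum medians relative to the national medians (same published table),
# stored as ratios; converted to centered log-shifts at generation time.
DOMAIN_RATIOS <- rbind(
  lima_metropolitana = c(sugars = 0.30, meats = 1.43, cereals = 0.76, oils = 0.50, dairy = 1.00, legumes = 1.00),
  resto_costa        = c(sugars = 0.60, meats = 1.00, cereals = 0.88, oils = 0.50, dairy = 1.00, legumes = 1.00),
  sierra             = c(sugars = 1.00, meats = 1.14, cereals = 1.09, oils = 1.00, dairy = 1.00, legumes = 1.50),
  selva              = c(sugars = 0.60, meats = 1.00, cereals = 0.99, oils = 1.00, dairy = 0.75, legumes = 1.00)
)
BUDGET_RATIOS <- rbind(
  A = c(sugars = 1.00, meats = 1.14, cereals = 1.11, oils = 1.00, dairy = 1.00, legumes = 1.30),
  B = c(sugars = 0.80, meats = 1.14, cereals = 1.02, oils = 1.00, dairy = 1.00, legumes = 1.00),
  C = c(sugars = 0.60, meats = 1.00, cereals = 0.92, oils = 0.90, dairy = 0.75, legumes = 1.00),
  D = c(sugars = 0.30, meats = 1.29, cereals = 0.73, oils = 0.50, dairy = 1.00, legumes = 1.00)
)

# Fixed basket menu: foods and mass shares within each core group; single
# anchor foods for the minor groups (present in few baskets, medians 0).
CORE_MENU <- data.frame(
  group = c("cereals", "cereals", "cereals", "sugars", "meats", "meats", "meats",
            "oils", "dairy", "legumes", "legumes", "legumes"),
  food_name = c("arroz pilado", "fideos tallarin", "avena hojuelas", "azucar rubia",
                "conserva de pescado en agua", "atun en conserva en aceite",
                "anchoveta en salsa de tomate", "aceite vegetal",
                "leche evaporada entera", "lenteja", "frijol canario",
                "arveja seca partida"),
  share = c(0.65, 0.20, 0.15, 1.00, 0.60, 0.25, 0.15, 1.00, 1.00, 0.50, 0.30, 0.20),
  stringsAsFactors = FALSE
)
MINOR_MENU <- data.frame(
  group = c("fruits", "eggs", "vegetables", "tubers"),
  food_name = c("platano de seda", "huevo de gallina", "cebolla de cabeza", "papa blanca"),
  median_kg = c(1.0, 0.9, 1.0, 2.0),
  stringsAsFactors = FALSE
)

# Typical package mass (kg) used when an item is registered in "units"
UNIT_PACKAGE_KG <- c(
  "conserva de pescado en agua" = 0.170, "atun en conserva en aceite" = 0.170,
  "anchoveta en salsa de tomate" = 0.425, "leche evaporada entera" = 0.400,
  "huevo de gallina" = 0.060, "aceite vegetal" = 0.900
)

#' Configuration for the synthetic registry generator
#'
#' Defaults reproduce the conditions of the municipal basket program: a frame
#' of 1874 municipalities over four geographic domains and four budget
#' groups, per-group quantities log-normal around the published national
#' medians with dispersion solved from the published IQRs, 53% of
#' municipalities registering more than one basket variant, about 10% of
#' item rows registered in "units" (concentrated in meats, which held 52.2%
#' of the weight approximations), and 2% of baskets carrying an extreme
#' data-entry error.
#'
#' @param n_municipalities frame size; default 1874.
#' @param domain_weights probabilities over the four geographic domains.
#' @param budget_weights probabilities over budget groups A-D (uniform by
#'   default; the real joint distribution is unpublished).
#' @param group_medians_kg national median kg (oils: L) per core food group.
#' @param group_iqr_kg list of `c(q1, q3)` per core group.
#' @param basket_sigma log-normal sigma of the basket-level size factor
#'   shared by all groups in a basket (invisible to caloric percentages).
#' @param minor_group_prob probability a basket includes each minor group
#'   (fruits, eggs, vegetables, tubers).
#' @param p_unit_records overall fraction of item rows registered as "unit".
#' @param unit_meat_share fraction of unit records that fall in meats.
#' @param p_extreme probability a basket carries an extreme-value error.
#' @param p_multi_basket probability a municipality registers >= 2 variants.
#' @param stratum_effects apply domain/budget multiplicative shifts
#'   (centered so national medians are preserved); default TRUE.
#' @param seed integer seed; all generation is deterministic given it.
#' @return a `generator_config` list.
#' @export
generator_config <- function(n_municipalities = 1874,
                             domain_weights = c(lima_metropolitana = 0.05,
                                                resto_costa = 0.25,
                                                sierra = 0.50,
                                                selva = 0.20),
                             budget_weights = c(A = 0.25, B = 0.25, C = 0.25, D = 0.25),
                             group_medians_kg = DEFAULT_GROUP_MEDIANS,
                             group_iqr_kg = DEFAULT_GROUP_IQR,
                             basket_sigma = 0.25,
                             minor_group_prob = 0.15,
                             p_unit_records = 0.10,
                             unit_meat_share = 0.522,
                             p_extreme = 0.02,
                             p_multi_basket = 0.53,
                             stratum_effects = TRUE,
                             seed = 1L) {
  stopifnot(
    n_municipalities >= 0,
    abs(sum(domain_weights) - 1) < 1e-8, abs(sum(budget_weights) - 1) < 1e-8,
    all(domain_weights >= 0), all(budget_weights >= 0),
    all(group_medians_kg > 0),
    p_unit_records >= 0, p_unit_records <= 1,
    p_extreme >= 0, p_extreme <= 1,
    p_multi_basket >= 0, p_multi_basket <= 1,
    minor_group_prob >= 0, minor_group_prob <= 1
  )
  core <- names(group_medians_kg)
  # log-normal sigma per group from the IQR: log(q3/q1) spans 2 * 0.6745 sd;
  # part of the spread is a shared basket-size factor, the rest group-specific
  total_sigma <- vapply(core, function(g) {
    q <- group_iqr_kg[[g]]
    log(q[2] / q[1]) / (2 * stats::qnorm(0.75))
  }, numeric(1))
  group_sigma <- sqrt(pmax(total_sigma^2 - basket_sigma^2, 0.10^2))
  structure(list(
    n_municipalities = n_municipalities,
    domain_weights = domain_weights[GEO_DOMAINS],
    budget_weights = budget_weights[BUDGET_GROUPS],
    group_medians_kg = group_medians_kg,
    group_sigma = group_sigma,
    basket_sigma = basket_sigma,
    minor_group_prob = minor_group_prob,
    p_unit_records = p_unit_records,
    unit_meat_share = unit_meat_share,
    p_extreme = p_extreme,
    p_multi_basket = p_multi_basket,
    stratum_effects = stratum_effects,
    seed = as.integer(seed)
  ), class = "generator_config")
}

# Centered log-shift matrices. The mixture over strata of lognormals with
# per-stratum shifts must keep the configured value as its *median*, so per
# group we solve sum_i w_i Phi((c - s_i) / sigma) = 1/2 for the offset c and
# subtract it (mean-centering would bias the mixture median when shifts are
# asymmetric, as they are for sugars).
centered_shifts <- function(domain_ratios, budget_ratios, domain_w, budget_w,
                            groups, sigma_tot) {
  dlr <- log(domain_ratios[GEO_DOMAINS, groups, drop = FALSE])
  blr <- log(budget_ratios[BUDGET_GROUPS, groups, drop = FALSE])
  w <- as.numeric(outer(domain_w[GEO_DOMAINS], budget_w[BUDGET_GROUPS]))
  for (g in groups) {
    s <- as.numeric(outer(dlr[, g], blr[, g], "+"))
    c_g <- stats::uniroot(
      function(c) sum(w * stats::pnorm((c - s) / sigma_tot[[g]])) - 0.5,
      interval = range(s) + c(-1, 1)
    )$root
    dlr[, g] <- dlr[, g] - c_g
  }
  list(domain = dlr, budget = blr)
}

with_seed <- function(seed, code) {
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  code
}

#' Generate a municipality frame
#'
#' @param config a `generator_config`.
#' @return data frame: `municipality_id`, `domain`, `budget_group`,
#'   `population`; deterministic under the config seed.
#' @export
generate_frame <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  n <- config$n_municipalities
  if (n == 0L) {
    return(data.frame(municipality_id = character(0), domain = character(0),
                      budget_group = character(0), population = integer(0),
                      stringsAsFactors = FALSE))
  }
  with_seed(config$seed, {
    data.frame(
      municipality_id = sprintf("M%05d", seq_len(n)),
      domain = sample(GEO_DOMAINS, n, replace = TRUE, prob = config$domain_weights),
      budget_group = sample(BUDGET_GROUPS, n, replace = TRUE, prob = config$budget_weights),
      population = 500L + as.integer(round(stats::rlnorm(n, log(8000), 1.1))),
      stringsAsFactors = FALSE
    )
  })
}

#' Generate a synthetic basket registry
#'
#' Emits the registry CSV dialect consumed by [parse_registry()] plus a
#' truth-label sidecar recording every injected unit record and extreme
#' value, so downstream detection can be asserted against ground truth.
#'
#' Each municipality registers 1-3 basket variants; each basket holds the
#' fixed core menu (cereals, sugars, meats, oils, dairy, legumes) with
#' log-normal group masses (shared basket-size factor times a group-specific
#' residual, with centered domain/budget shifts) plus occasional minor-group
#' foods. A fraction of rows is registered in "units" with a per-unit price
#' coherent with the market price table; a fraction of baskets carries a
#' mass inflated 1000-fold (a kg/g data-entry error).
#'
#' @param frame municipality frame from [generate_frame()] (or a sampled
#'   subset of it).
#' @param config a `generator_config`.
#' @param prices price table used to back out coherent unit prices.
#' @return list with `registry` (data frame in registry schema) and `truth`
#'   (list: `unit_rows`, `extreme_rows`, `n_baskets`).
#' @export
generate_registry <- function(frame, config,
                              prices = load_price_table()) {
  stopifnot(inherits(config, "generator_config"))
  if (nrow(frame) == 0L) {
    canasta_error("canasta_domain_error", "empty municipality frame")
  }
  core <- names(config$group_medians_kg)
  sigma_tot <- sqrt(config$group_sigma^2 + config$basket_sigma^2)
  shifts <- centered_shifts(DOMAIN_RATIOS, BUDGET_RATIOS,
                            config$domain_weights, config$budget_weights,
                            core, sigma_tot)
  dshift <- shifts$domain
  bshift <- shifts$budget
  if (!config$stratum_effects) {
    dshift[] <- 0
    bshift[] <- 0
  }
  menu <- CORE_MENU[CORE_MENU$group %in% core, , drop = FALSE]

  with_seed(config$seed + 1L, {
    # baskets per municipality
    extra <- stats::rbinom(nrow(frame), 1, config$p_multi_basket)
    nb <- ifelse(extra == 1, sample(2:3, nrow(frame), replace = TRUE), 1L)
    B <- sum(nb)
    bmuni <- rep(seq_len(nrow(frame)), nb)
    bid <- sprintf("B%d", unlist(lapply(nb, seq_len)))
    benef <- pmax(1L, as.integer(round(stats::rlnorm(B, log(300), 0.8))))

    # per-basket group masses (kg), log-normal around shifted medians
    size_f <- stats::rnorm(B, 0, config$basket_sigma)
    gmass <- vapply(core, function(g) {
      mu <- log(config$group_medians_kg[[g]]) +
        dshift[frame$domain[bmuni], g] + bshift[frame$budget_group[bmuni], g]
      exp(mu + size_f + stats::rnorm(B, 0, config$group_sigma[[g]]))
    }, numeric(B))

    # expand the core menu over baskets
    n_menu <- nrow(menu)
    rows <- data.frame(
      b = rep(seq_len(B), each = n_menu),
      food_name = rep(menu$food_name, B),
      group = rep(menu$group, B),
      mass_kg = as.numeric(t(gmass[, match(menu$group, core), drop = FALSE])) *
        rep(menu$share, B),
      stringsAsFactors = FALSE
    )

    # minor groups, occasionally present
    for (i in seq_len(nrow(MINOR_MENU))) {
      inc <- stats::runif(B) < config$minor_group_prob
      if (any(inc)) {
        rows <- rbind(rows, data.frame(
          b = which(inc),
          food_name = MINOR_MENU$food_name[i],
          group = MINOR_MENU$group[i],
          mass_kg = exp(log(MINOR_MENU$median_kg[i]) +
                          stats::rnorm(sum(inc), 0, 0.4)),
          stringsAsFactors = FALSE
        ))
      }
    }
    rows <- rows[order(rows$b), , drop = FALSE]

    # extreme-value injection: the basket's largest item recorded 1000-fold
    # (a kg-for-g staple typo), so the error always trips the ceilings
    extreme_b <- which(stats::runif(B) < config$p_extreme)
    extreme_idx <- integer(0)
    for (b in extreme_b) {
      cand <- which(rows$b == b)
      pick <- cand[which.max(rows$mass_kg[cand])]
      rows$mass_kg[pick] <- rows$mass_kg[pick] * 1000
      extreme_idx <- c(extreme_idx, pick)
    }

    # unit records, concentrated in meats
    f_meat <- mean(rows$group == "meats")
    p_meat <- min(1, config$p_unit_records * config$unit_meat_share / max(f_meat, 1e-9))
    p_other <- min(1, config$p_unit_records * (1 - config$unit_meat_share) /
                     max(1 - f_meat, 1e-9))
    p_row <- ifelse(rows$group == "meats", p_meat, p_other)
    unit_idx <- which(stats::runif(nrow(rows)) < p_row)
    unit_idx <- setdiff(unit_idx, extreme_idx)

    unit <- rep("kg", nrow(rows))
    quantity <- rows$mass_kg
    unit[rows$group %in% c("oils", "dairy")] <- "L" # volumes at 1 g/mL
    unit_price <- rep(NA_real_, nrow(rows))
    if (length(unit_idx)) {
      pkg <- UNIT_PACKAGE_KG[rows$food_name[unit_idx]]
      pkg[is.na(pkg)] <- 0.5
      n_units <- pmax(1, round(rows$mass_kg[unit_idx] / pkg))
      mp <- prices$mean_price_per_kg[match(rows$food_name[unit_idx], prices$food_name)]
      unit[unit_idx] <- "unit"
      quantity[unit_idx] <- n_units
      unit_price[unit_idx] <- rows$mass_kg[unit_idx] / n_units * mp
    }

    registry <- data.frame(
      municipality_id = frame$municipality_id[bmuni][rows$b],
      domain = frame$domain[bmuni][rows$b],
      budget_group = frame$budget_group[bmuni][rows$b],
      population = frame$population[bmuni][rows$b],
      basket_id = bid[rows$b],
      beneficiaries = benef[rows$b],
      food_name = rows$food_name,
      quantity = quantity,
      unit = unit,
      unit_price = unit_price,
      stringsAsFactors = FALSE
    )
    rownames(registry) <- NULL
    truth <- list(
      unit_rows = registry[unit_idx, c("municipality_id", "basket_id", "food_name")],
      extreme_rows = registry[extreme_idx, c("municipality_id", "basket_id", "food_name")],
      n_baskets = stats::setNames(as.integer(nb), frame$municipality_id)
    )
    list(registry = registry, truth = truth)
  })
}

#' Caloric-distribution targets implied by a generator configuration
#'
#' The deterministic national "median basket": each core group at its
#' configured median mass, split across the fixed menu shares, evaluated
#' against the composition table with Atwater factors. Because the
#' basket-size factor cancels from percentages and stratum shifts are
#' centered, pipeline-recovered national medians converge to these values
#' as the number of municipalities grows.
#'
#' @param config a `generator_config`.
#' @param table composition table used for nutrient densities.
#' @return named vector: `pct_protein`, `pct_fat`, `pct_carb`.
#' @export
implied_pct_targets <- function(config, table = load_composition_table()) {
  core <- names(config$group_medians_kg)
  menu <- CORE_MENU[CORE_MENU$group %in% core, , drop = FALSE]
  mass_g <- config$group_medians_kg[menu$group] * menu$share * 1000
  idx <- match(normalize_food_name(menu$food_name),
               normalize_food_name(table$entries$name))
  stopifnot(!anyNA(idx))
  protein <- sum(table$entries$protein_g_100g[idx] * mass_g / 100)
  fat <- sum(table$entries$fat_g_100g[idx] * mass_g / 100)
  carb <- sum(table$entries$carb_g_100g[idx] * mass_g / 100)
  kcal <- 4 * protein + 9 * fat + 4 * carb
  c(pct_protein = 400 * protein / kcal,
    pct_fat = 900 * fat / kcal,
    pct_carb = 400 * carb / kcal)
}

#' Write a registry (and optional truth labels) to disk
#'
#' @param registry registry data frame from [generate_registry()].
#' @param path CSV output path.
#' @param truth optional truth-label list; written as JSON next to the
#'   registry when given.
#' @return `path`, invisibly.
#' @export
write_registry <- function(registry, path, truth = NULL) {
  utils::write.csv(registry, path, row.names = FALSE, na = "")
  if (!is.null(truth)) {
    jsonlite::write_json(truth, sub("\\.csv$", "_truth.json", path),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
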
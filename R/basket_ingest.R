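# Registry parsing, basket selection, unit-to-weight approximation and the
# inclusion/exclusion flow (>= 3 foods, extreme-value screening).

REGISTRY_COLUMNS <- c(
  "municipality_id", "domain", "budget_group", "population",
  "basket_id", "beneficiaries", "food_name", "quantity", "unit", "unit_price"
)

VALID_UNITS <- c("kg", "g", "L", "mL", "unit")

#' Parse a raw basket registry
#'
#' Reads a registry (CSV or JSON array of records) with one row per food item
#' per basket per municipality. Malformed rows are not silently dropped: they
#' are collected into a rejects table with a machine-readable reason.
#'
#' @param path registry file; format inferred from the extension
#'   (`.json` vs anything else treated as CSV).
#' @return list with `items` (valid rows), `municipalities` (one row per
#'   municipality: id, domain, budget group, population) and `rejects`
#'   (invalid rows plus a `reject_reason` column).
#' @export
parse_registry <- function(path) {
  if (!file.exists(path)) {
    canasta_error("canasta_missing_file", sprintf("registry not found: %s", path))
  }
  if (tolower(tools::file_ext(path)) == "json") {
    df <- jsonlite::fromJSON(path)
    df <- as.data.frame(df, stringsAsFactors = FALSE)
  } else {
    df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                   error = function(e) data.frame())
  }
  if (nrow(df) == 0L) {
    warning("registry is empty")
    empty <- stats::setNames(
      data.frame(matrix(character(0), 0, length(REGISTRY_COLUMNS))), REGISTRY_COLUMNS
    )
    return(list(
      items = empty,
      municipalities = empty[c("municipality_id", "domain", "budget_group", "population")],
      rejects = cbind(empty, reject_reason = character(0))
    ))
  }
  missing <- setdiff(REGISTRY_COLUMNS, names(df))
  if (length(missing)) {
    canasta_error(
      "canasta_schema_error",
      sprintf("registry lacks column(s): %s", paste(missing, collapse = ", "))
    )
  }
  df <- df[REGISTRY_COLUMNS]
  df$municipality_id <- as.character(df$municipality_id)
  df$basket_id <- as.character(df$basket_id)
  df$quantity <- suppressWarnings(as.numeric(df$quantity))
  df$beneficiaries <- suppressWarnings(as.numeric(df$beneficiaries))
  df$unit_price <- suppressWarnings(as.numeric(df$unit_price))

  reason <- rep(NA_character_, nrow(df))
  flag <- function(cond, why) ifelse(is.na(reason) & cond, why, reason)
  reason <- flag(!df$unit %in% VALID_UNITS, "unknown unit")
  reason <- flag(!is.finite(df$quantity) | df$quantity <= 0, "non-positive quantity")
  reason <- flag(!is.finite(df$beneficiaries) | df$beneficiaries < 1, "beneficiaries < 1")
  reason <- flag(!nzchar(trimws(df$food_name)), "empty food name")
  reason <- flag(!df$domain %in% GEO_DOMAINS, "unknown domain")
  reason <- flag(!df$budget_group %in% BUDGET_GROUPS, "unknown budget group")

  bad <- !is.na(reason)
  rejects <- df[bad, , drop = FALSE]
  if (nrow(rejects)) rejects$reject_reason <- reason[bad]
  items <- df[!bad, , drop = FALSE]
  munis <- unique(items[c("municipality_id", "domain", "budget_group", "population")])
  rownames(items) <- rownames(munis) <- NULL
  list(items = items, municipalities = munis, rejects = rejects)
}

#' Load a market price table
#'
#' @param path CSV with columns `food_name,wholesale_price_per_kg,retail_price_per_kg`.
#' @return data frame with an extra `mean_price_per_kg` column.
#' @export
load_price_table <- function(path = canasta_example("price_table.csv")) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("food_name", "wholesale_price_per_kg", "retail_price_per_kg")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    canasta_error("canasta_schema_error",
                  sprintf("price table lacks column(s): %s", paste(missing, collapse = ", ")))
  }
  if (any(df$wholesale_price_per_kg <= 0) || any(df$retail_price_per_kg <= 0)) {
    canasta_error("canasta_validation_error", "prices must be positive")
  }
  df$mean_price_per_kg <- (df$wholesale_price_per_kg + df$retail_price_per_kg) / 2
  df
}

#' Approximate the weight of an item registered in "units"
#'
#' Items registered without a weight carry a per-unit price; the mass is
#' approximated from the average of wholesale and retail market prices per kg:
#' `mass_g = quantity * (unit_price / mean_price_per_kg) * 1000`.
#'
#' @param quantity number of units (> 0).
#' @param unit_price price per unit in soles (> 0).
#' @param mean_price_per_kg average market price per kg (> 0).
#' @return approximated mass in grams.
#' @export
approximate_weight <- function(quantity, unit_price, mean_price_per_kg) {
  if (any(!is.finite(unit_price)) || any(unit_price <= 0)) {
    canasta_error("canasta_unresolved_item", "unit record lacks a positive unit_price")
  }
  if (any(!is.finite(mean_price_per_kg)) || any(mean_price_per_kg <= 0)) {
    canasta_error("canasta_unresolved_item", "no market price available for unit record")
  }
  stopifnot(all(quantity > 0))
  quantity * (unit_price / mean_price_per_kg) * 1000
}

#' Select the reported basket for a municipality
#'
#' When a municipality registered several basket variants, the one
#' distributed to the largest number of beneficiaries is analyzed; ties are
#' broken by the smallest basket id, so selection is deterministic and
#' independent of row order.
#'
#' @param baskets data frame with columns `basket_id` and `beneficiaries`
#'   (one row per basket, or per item — duplicates are collapsed).
#' @return the selected `basket_id`.
#' @export
select_basket <- function(baskets) {
  b <- unique(baskets[c("basket_id", "beneficiaries")])
  if (nrow(b) == 0L) canasta_error("canasta_domain_error", "no baskets to select from")
  b <- b[order(-b$beneficiaries, b$basket_id), , drop = FALSE]
  b$basket_id[1]
}

# Convert quantity+unit to grams. Volumes use a density of 1 g/mL by default;
# per-group overrides (named vector, g/mL) may be supplied.
unit_to_grams <- function(quantity, unit, group, densities = numeric(0)) {
  dens <- rep(1, length(quantity))
  if (length(densities)) {
    idx <- match(group, names(densities))
    dens[!is.na(idx)] <- densities[idx[!is.na(idx)]]
  }
  out <- rep(NA_real_, length(quantity))
  out[unit == "kg"] <- quantity[unit == "kg"] * 1000
  out[unit == "g"] <- quantity[unit == "g"]
  out[unit == "L"] <- quantity[unit == "L"] * 1000 * dens[unit == "L"]
  out[unit == "mL"] <- quantity[unit == "mL"] * dens[unit == "mL"]
  out
}

#' Resolve registry items to composition codes and masses in grams
#'
#' Maps each item's free-text name to a composition code (exact or similarity
#' match), converts kg/g/L/mL quantities to grams, and approximates the mass
#' of `"unit"` records from market prices. Items that cannot be resolved
#' (unknown food above the similarity floor, or a unit record without a
#' usable price) are returned separately with a reason; the exclusion flow
#' decides what happens to their baskets.
#'
#' @param items data frame of registry items (see [parse_registry()]).
#' @param table a `composition_table`.
#' @param prices a price table from [load_price_table()].
#' @param similarity_floor minimum name-similarity for a match; default 0.6.
#' @param densities named numeric vector of g/mL densities per food group
#'   applied to volume units; unlisted groups use 1.
#' @return list with `resolved` (items plus `code`, `group`, `mass_g`,
#'   `weight_approximated`, `similarity_matched`) and `unresolved`
#'   (items plus `reason`).
#' @export
resolve_items <- function(items, table, prices, similarity_floor = 0.6,
                          densities = numeric(0)) {
  stopifnot(inherits(table, "composition_table"))
  n <- nrow(items)
  if (n == 0L) {
    return(list(resolved = cbind(items, code = character(0), group = character(0),
                                 mass_g = numeric(0), weight_approximated = logical(0),
                                 similarity_matched = logical(0)),
                unresolved = cbind(items, reason = character(0))))
  }
  # memoise name resolution: registries repeat a small food vocabulary
  uniq <- unique(items$food_name)
  res <- lapply(uniq, function(nm) {
    tryCatch(resolve_food(nm, table, floor = similarity_floor),
             canasta_unresolved_food = function(e) NULL)
  })
  names(res) <- uniq
  code <- vapply(items$food_name, function(nm) {
    r <- res[[nm]]
    if (is.null(r)) NA_character_ else r$code
  }, character(1), USE.NAMES = FALSE)
  kind <- vapply(items$food_name, function(nm) {
    r <- res[[nm]]
    if (is.null(r)) NA_character_ else r$match_kind
  }, character(1), USE.NAMES = FALSE)
  group <- table$entries$group[match(code, table$entries$code)]

  mass_g <- unit_to_grams(items$quantity, items$unit, group, densities)
  is_unit <- items$unit == "unit"
  if (any(is_unit)) {
    mp <- prices$mean_price_per_kg[match(items$food_name[is_unit], prices$food_name)]
    ok <- is.finite(mp) & mp > 0 & is.finite(items$unit_price[is_unit]) &
      items$unit_price[is_unit] > 0
    m <- rep(NA_real_, sum(is_unit))
    if (any(ok)) {
      m[ok] <- approximate_weight(items$quantity[is_unit][ok],
                                  items$unit_price[is_unit][ok], mp[ok])
    }
    mass_g[is_unit] <- m
  }

  reason <- rep(NA_character_, n)
  reason[is.na(code)] <- "unresolved_food"
  reason[is.na(reason) & !is.finite(mass_g)] <- "no_price_for_unit_record"
  bad <- !is.na(reason)

  resolved <- items[!bad, , drop = FALSE]
  resolved$code <- code[!bad]
  resolved$group <- group[!bad]
  resolved$mass_g <- mass_g[!bad]
  resolved$weight_approximated <- is_unit[!bad]
  resolved$similarity_matched <- kind[!bad] == "similarity"
  unresolved <- items[bad, , drop = FALSE]
  if (nrow(unresolved)) unresolved$reason <- reason[bad]
  rownames(resolved) <- rownames(unresolved) <- NULL
  list(resolved = resolved, unresolved = unresolved)
}

#' Apply the basket inclusion/exclusion flow
#'
#' A basket is analyzed only if it contains at least three distinct foods and
#' shows no sign of data-entry error: no single item above the per-item
#' ceiling, no basket total above the basket ceiling, and not too many
#' unresolvable items. Exclusions carry a machine-readable reason
#' (`too_few_foods`, `extreme_value`, `unresolved_items`); kept and excluded
#' baskets always partition the input.
#'
#' @param resolved resolved items from [resolve_items()].
#' @param unresolved unresolved items from [resolve_items()].
#' @param item_ceiling_kg per-item mass ceiling; default 100 kg.
#' @param basket_ceiling_kg basket total ceiling; default 500 kg.
#' @param max_unresolved_frac exclude the basket when more than this fraction
#'   of its items is unresolved; default 0.2.
#' @param min_foods minimum distinct foods for inclusion; default 3.
#' @return list with `kept` (list of `basket_record` objects) and `excluded`
#'   (data frame municipality_id, basket_id, reason).
#' @export
apply_inclusion_exclusion <- function(resolved, unresolved,
                                      item_ceiling_kg = 100,
                                      basket_ceiling_kg = 500,
                                      max_unresolved_frac = 0.2,
                                      min_foods = 3L) {
  key <- function(df) paste(df$municipality_id, df$basket_id, sep = "\r")
  all_keys <- unique(c(key(resolved), if (nrow(unresolved)) key(unresolved)))
  kept <- list()
  excl <- list()
  res_split <- split(resolved, key(resolved))
  unres_n <- if (nrow(unresolved)) table(key(unresolved)) else table(character(0))

  for (k in sort(all_keys)) {
    items <- res_split[[k]]
    n_res <- if (is.null(items)) 0L else nrow(items)
    n_unres <- if (k %in% names(unres_n)) as.integer(unres_n[[k]]) else 0L
    ids <- strsplit(k, "\r", fixed = TRUE)[[1]]
    n_foods <- if (n_res) length(unique(items$code)) else 0L
    reason <- NA_character_
    if (n_unres / (n_unres + n_res) > max_unresolved_frac) {
      reason <- "unresolved_items"
    } else if (n_foods < min_foods) {
      reason <- "too_few_foods"
    } else if (any(items$mass_g > item_ceiling_kg * 1000) ||
               sum(items$mass_g) > basket_ceiling_kg * 1000) {
      reason <- "extreme_value"
    }
    if (is.na(reason)) {
      kept[[length(kept) + 1L]] <- new_basket_record(items)
    } else {
      excl[[length(excl) + 1L]] <- data.frame(
        municipality_id = ids[1], basket_id = ids[2], reason = reason,
        stringsAsFactors = FALSE
      )
    }
  }
  excluded <- if (length(excl)) do.call(rbind, excl) else
    data.frame(municipality_id = character(0), basket_id = character(0),
               reason = character(0), stringsAsFactors = FALSE)
  list(kept = kept, excluded = excluded)
}

new_basket_record <- function(items) {
  stopifnot(all(is.finite(items$mass_g)), all(items$mass_g > 0))
  structure(
    list(
      municipality_id = items$municipality_id[1],
      basket_id = items$basket_id[1],
      domain = items$domain[1],
      budget_group = items$budget_group[1],
      beneficiaries = items$beneficiaries[1],
      items = items[c("food_name", "code", "group", "mass_g",
                      "weight_approximated", "similarity_matched")],
      n_distinct_foods = length(unique(items$code))
    ),
    class = "basket_record"
  )
}

#' @export
print.basket_record <- function(x, ...) {
  cat(sprintf(
    "<basket_record> municipality %s basket %s: %d items, %d distinct foods, %.1f kg\n",
    x$municipality_id, x$basket_id, nrow(x$items), x$n_distinct_foods,
    sum(x$items$mass_g) / 1000
  ))
  invisible(x)
}
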
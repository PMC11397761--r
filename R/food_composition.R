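# Food-composition reference table: loading, name resolution, nutrient scaling.

COMPOSITION_COLUMNS <- c(
  "code", "name", "group",
  "energy_kcal_100g", "protein_g_100g", "fat_g_100g", "carb_g_100g"
)

#' Normalize a free-text food name for matching
#'
#' Lowercases, transliterates accents to ASCII, strips punctuation and
#' collapses whitespace, so that registry spellings such as
#' `"Azúcar  Rubia."` and `"azucar rubia"` compare equal.
#'
#' @param x character vector of food names.
#' @return normalized character vector.
#' @export
normalize_food_name <- function(x) {
  x <- tolower(trimws(as.character(x)))
  x <- iconv(x, from = "UTF-8", to = "ASCII//TRANSLIT", sub = "")
  # transliteration may leave free-standing accent marks; drop them outright
  x <- gsub("[`´^~¨']+", "", x)
  x <- gsub("[[:punct:]]+", " ", x)
  x <- gsub("[[:space:]]+", " ", x)
  trimws(x)
}

#' Load a food-composition table
#'
#' Reads a per-100 g composition table (energy in kcal; protein, fat and
#' carbohydrate in grams; one of the ten Food Guide groups) and validates
#' every row. The packaged `composition_table.csv` is a synthetic 40-food
#' stand-in for the Peruvian Tables of Food Composition, which cannot be
#' redistributed; values are transcribed from public composition references.
#'
#' @param path CSV file with columns
#'   `code,name,group,energy_kcal_100g,protein_g_100g,fat_g_100g,carb_g_100g`.
#' @return a `composition_table` object: a validated data frame of entries
#'   plus a normalized-name index.
#' @export
load_composition_table <- function(path = canasta_example("composition_table.csv")) {
  if (!file.exists(path)) {
    canasta_error("canasta_missing_file", sprintf("composition table not found: %s", path))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(COMPOSITION_COLUMNS, names(df))
  if (length(missing)) {
    canasta_error(
      "canasta_schema_error",
      sprintf("composition table lacks column(s): %s", paste(missing, collapse = ", "))
    )
  }
  as_composition_table(df[COMPOSITION_COLUMNS])
}

#' Build a composition table from a data frame
#'
#' @param df data frame with the composition-table columns.
#' @return a `composition_table` object.
#' @export
as_composition_table <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) {
    canasta_error("canasta_validation_error", "composition table is empty")
  }
  df$code <- as.character(df$code)
  dup <- unique(df$code[duplicated(df$code)])
  if (length(dup)) {
    canasta_error(
      "canasta_validation_error",
      sprintf("duplicate composition code(s): %s", paste(dup, collapse = ", "))
    )
  }
  bad_group <- !df$group %in% FOOD_GROUPS
  if (any(bad_group)) {
    canasta_error(
      "canasta_validation_error",
      sprintf(
        "unknown food group '%s' (row %d); expected one of: %s",
        df$group[which(bad_group)[1]], which(bad_group)[1],
        paste(FOOD_GROUPS, collapse = ", ")
      )
    )
  }
  nut_cols <- c("energy_kcal_100g", "protein_g_100g", "fat_g_100g", "carb_g_100g")
  for (col in nut_cols) {
    v <- df[[col]]
    if (!is.numeric(v) || anyNA(v) || any(v < 0)) {
      canasta_error(
        "canasta_validation_error",
        sprintf(
          "column %s must be numeric and >= 0 (first bad row: %d)",
          col, which(!is.finite(v) | v < 0)[1]
        )
      )
    }
  }
  macro_sum <- df$protein_g_100g + df$fat_g_100g + df$carb_g_100g
  if (any(macro_sum > 100 + 1e-9)) {
    canasta_error(
      "canasta_validation_error",
      sprintf(
        "protein + fat + carb exceed 100 g per 100 g in row %d (%s)",
        which(macro_sum > 100 + 1e-9)[1], df$name[which(macro_sum > 100 + 1e-9)[1]]
      )
    )
  }
  structure(
    list(entries = df, name_index = stats::setNames(df$code, normalize_food_name(df$name))),
    class = "composition_table"
  )
}

#' @export
print.composition_table <- function(x, ...) {
  cat(sprintf(
    "<composition_table> %d foods across %d groups\n",
    nrow(x$entries), length(unique(x$entries$group))
  ))
  invisible(x)
}

composition_entry <- function(table, code) {
  i <- match(code, table$entries$code)
  if (is.na(i)) {
    canasta_error("canasta_unknown_code", sprintf("code '%s' not in composition table", code))
  }
  table$entries[i, , drop = FALSE]
}

# Token-set similarity ratio in [0, 1]: edit-distance ratio between the
# sorted-token intersection string and each sorted full string (and between
# the two full strings), taking the best. This makes "canned tuna in oil"
# score high against "canned fish" through their shared token prefix, while
# unrelated strings stay low.
string_ratio <- function(a, b) {
  if (!nzchar(a) && !nzchar(b)) return(1)
  d <- utils::adist(a, b)
  (nchar(a) + nchar(b) - d) / (nchar(a) + nchar(b))
}

token_set_similarity <- function(a, b) {
  ta <- sort(unique(strsplit(a, " ", fixed = TRUE)[[1]]))
  tb <- sort(unique(strsplit(b, " ", fixed = TRUE)[[1]]))
  common <- intersect(ta, tb)
  s0 <- paste(common, collapse = " ")
  s1 <- paste(c(common, setdiff(ta, common)), collapse = " ")
  s2 <- paste(c(common, setdiff(tb, common)), collapse = " ")
  if (length(common) == 0L) {
    return(string_ratio(s1, s2))
  }
  max(string_ratio(s0, s1), string_ratio(s0, s2), string_ratio(s1, s2))
}

#' Resolve a free-text food name to a composition code
#'
#' Exact normalized-name matches are preferred; otherwise the
#' highest-similarity entry is used ("similarity approximation", the rule
#' applied by hand to foods absent from the reference table, most often
#' canned fish varieties). When a food-group hint is supplied, similarity
#' candidates are restricted to that group. Ties are broken by the
#' lexicographically smallest code, so resolution is deterministic.
#'
#' @param name free-text food name.
#' @param table a `composition_table`.
#' @param group optional group hint restricting similarity candidates.
#' @param floor minimum acceptable similarity in \[0, 1\]; default 0.6.
#' @return list with `code`, `match_kind` (`"exact"` or `"similarity"`) and
#'   `similarity` (1 for exact matches).
#' @export
resolve_food <- function(name, table, group = NULL, floor = 0.6) {
  stopifnot(inherits(table, "composition_table"))
  norm <- normalize_food_name(name)
  if (!nzchar(norm)) {
    canasta_error("canasta_unresolved_food", "empty food name after normalization",
                  food_name = name)
  }
  hit <- table$name_index[norm]
  if (!is.na(hit)) {
    return(list(code = unname(hit), match_kind = "exact", similarity = 1))
  }
  cand <- table$entries
  if (!is.null(group)) {
    cand <- cand[cand$group == group, , drop = FALSE]
  }
  if (nrow(cand) == 0L) {
    canasta_error("canasta_unresolved_food",
                  sprintf("no candidates for '%s' in group '%s'", name, group),
                  food_name = name)
  }
  sims <- vapply(normalize_food_name(cand$name), token_set_similarity,
                 numeric(1), a = norm)
  best <- max(sims)
  if (best < floor) {
    canasta_error("canasta_unresolved_food",
                  sprintf("no composition entry similar to '%s' (best %.2f < floor %.2f)",
                          name, best, floor),
                  food_name = name)
  }
  codes <- sort(cand$code[sims >= best - 1e-12])
  list(code = codes[1], match_kind = "similarity", similarity = best)
}

#' Nutrients contributed by a given mass of a food
#'
#' Linear per-100 g scaling: grams of protein, fat and carbohydrate plus the
#' reference table's energy value for the mass.
#'
#' @param entry one-row data frame (or list) with the per-100 g fields.
#' @param mass_g mass in grams, finite and >= 0.
#' @return list with `protein_g`, `fat_g`, `carb_g`, `table_energy_kcal`.
#' @export
nutrients_for_mass <- function(entry, mass_g) {
  if (!is.numeric(mass_g) || length(mass_g) != 1L || !is.finite(mass_g) || mass_g < 0) {
    canasta_error("canasta_domain_error", "mass_g must be a finite number >= 0")
  }
  f <- mass_g / 100
  list(
    protein_g = entry$protein_g_100g * f,
    fat_g = entry$fat_g_100g * f,
    carb_g = entry$carb_g_100g * f,
    table_energy_kcal = entry$energy_kcal_100g * f
  )
}
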
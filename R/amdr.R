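# AMDR standards and deficit/adequate/excess classification of caloric
# distributions.

MACROS <- c("protein", "fat", "carb")

#' Construct an AMDR standard
#'
#' An Acceptable Macronutrient Distribution Range standard is a named set of
#' `[low, high]` percent-of-total-energy bounds, one per macronutrient.
#'
#' @param name standard name (e.g. `"INCAP"`).
#' @param bounds named list mapping `protein`, `fat`, `carb` to numeric
#'   `c(low, high)` with `0 <= low < high <= 100`.
#' @return an `amdr_standard` object.
#' @export
amdr_standard <- function(name, bounds) {
  if (!all(MACROS %in% names(bounds))) {
    canasta_error("canasta_validation_error",
                  sprintf("AMDR '%s' must bound all of: %s", name,
                          paste(MACROS, collapse = ", ")))
  }
  for (m in MACROS) {
    b <- as.numeric(bounds[[m]])
    if (length(b) != 2L || anyNA(b) || b[1] < 0 || b[2] > 100 || b[1] >= b[2]) {
      canasta_error("canasta_validation_error",
                    sprintf("AMDR '%s': %s bounds must satisfy 0 <= low < high <= 100", name, m))
    }
    bounds[[m]] <- b
  }
  structure(list(name = name, bounds = bounds[MACROS]), class = "amdr_standard")
}

#' @export
print.amdr_standard <- function(x, ...) {
  b <- x$bounds
  cat(sprintf("<amdr_standard> %s: protein %g-%g%%, fat %g-%g%%, carb %g-%g%%\n",
              x$name, b$protein[1], b$protein[2], b$fat[1], b$fat[2],
              b$carb[1], b$carb[2]))
  invisible(x)
}

#' The two default AMDR standards
#'
#' INCAP (Institute of Nutrition of Central America and Panama): protein
#' 10-15%, fat 20-25%, carbohydrate 60-70% of total energy. INDECI (Peru's
#' National Institute of Civil Defense): protein 10-15%, fat 20-35%,
#' carbohydrate 50-65%.
#'
#' @return named list of two `amdr_standard` objects.
#' @export
default_amdr_standards <- function() {
  load_amdr_standards(canasta_example("amdr_standards.json"))
}

#' Load AMDR standards from a JSON file
#'
#' @param path JSON array of objects
#'   `{"name": ..., "bounds": {"protein": [10,15], "fat": [...], "carb": [...]}}`.
#' @return named list of `amdr_standard` objects.
#' @export
load_amdr_standards <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  out <- lapply(raw, function(s) amdr_standard(s$name, s$bounds))
  stats::setNames(out, vapply(out, `[[`, character(1), "name"))
}

#' Classify a caloric distribution against an AMDR standard
#'
#' Each macronutrient's percent of energy is labelled `deficit` when strictly
#' below the lower bound, `excess` when strictly above the upper bound, and
#' `adequate` otherwise (bounds inclusive: the published cutpoints are strict
#' inequalities, e.g. protein deficit `< 10%`, fat excess `> 25%`). A basket
#' is overall adequate exactly when all three macronutrients are adequate.
#'
#' @param profile a `nutrient_profile`, or any list/vector carrying
#'   `pct_protein`, `pct_fat`, `pct_carb`.
#' @param standard an `amdr_standard`.
#' @return list with `standard`, per-macronutrient labels (`protein`, `fat`,
#'   `carb`) and `overall_adequate`.
#' @export
classify_amdr <- function(profile, standard) {
  stopifnot(inherits(standard, "amdr_standard"))
  pct <- c(
    protein = as.numeric(profile[["pct_protein"]]),
    fat = as.numeric(profile[["pct_fat"]]),
    carb = as.numeric(profile[["pct_carb"]])
  )
  if (anyNA(pct) || any(pct < 0) || any(pct > 100)) {
    canasta_error("canasta_domain_error", "percentages must lie in [0, 100]")
  }
  labels <- vapply(MACROS, function(m) {
    b <- standard$bounds[[m]]
    if (pct[[m]] < b[1]) "deficit" else if (pct[[m]] > b[2]) "excess" else "adequate"
  }, character(1))
  list(
    standard = standard$name,
    protein = labels[["protein"]],
    fat = labels[["fat"]],
    carb = labels[["carb"]],
    overall_adequate = all(labels == "adequate")
  )
}

#' Classify a table of profiles under one or more standards
#'
#' @param profiles data frame from [profile_table()].
#' @param standards list of `amdr_standard` objects.
#' @return long data frame: one row per basket x standard with the three
#'   labels and `overall_adequate`.
#' @export
classification_table <- function(profiles, standards = default_amdr_standards()) {
  out <- lapply(standards, function(std) {
    labs <- t(vapply(seq_len(nrow(profiles)), function(i) {
      cl <- classify_amdr(profiles[i, ], std)
      c(cl$protein, cl$fat, cl$carb)
    }, character(3)))
    data.frame(
      municipality_id = profiles$municipality_id,
      domain = profiles$domain, budget_group = profiles$budget_group,
      standard = std$name,
      protein = labs[, 1], fat = labs[, 2], carb = labs[, 3],
      overall_adequate = labs[, 1] == "adequate" & labs[, 2] == "adequate" &
        labs[, 3] == "adequate",
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Per-stratum adequacy summary
#'
#' Counts and proportions of deficit and excess per macronutrient, and of
#' overall adequacy, by stratum and standard. Optional expansion weights
#' (`N_h / n_h` per stratum) turn sample counts into population-expanded
#' counts; proportions are weighted accordingly. With equal weights the
#' weighted and unweighted summaries coincide.
#'
#' @param classifications data frame from [classification_table()].
#' @param stratum name of the column to stratify on (e.g. `"domain"`), or
#'   `NULL` for a national summary.
#' @param weights optional named vector of expansion weights keyed by
#'   stratum level.
#' @return data frame: stratum x standard x macronutrient rows with
#'   `n`, `deficit_n`, `deficit_pct`, `excess_n`, `excess_pct`, plus
#'   `overall` rows carrying `adequate_n`/`adequate_pct`.
#' @export
adequacy_summary <- function(classifications, stratum = NULL, weights = NULL) {
  cls <- classifications
  cls$stratum <- if (is.null(stratum)) "national" else cls[[stratum]]
  empty <- setdiff(unique(cls$stratum), cls$stratum[!is.na(cls$stratum)])
  if (length(empty)) warning("omitting empty stratum: ", paste(empty, collapse = ", "))
  w <- if (is.null(weights)) {
    rep(1, nrow(cls))
  } else {
    unname(weights[cls$stratum])
  }
  cls$w <- w
  rows <- list()
  for (std in unique(cls$standard)) {
    for (s in unique(cls$stratum)) {
      sub <- cls[cls$standard == std & cls$stratum == s, , drop = FALSE]
      denom <- sum(sub$w)
      for (m in MACROS) {
        rows[[length(rows) + 1L]] <- data.frame(
          stratum = s, standard = std, macronutrient = m, n = nrow(sub),
          deficit_n = sum(sub$w[sub[[m]] == "deficit"]),
          deficit_pct = 100 * sum(sub$w[sub[[m]] == "deficit"]) / denom,
          excess_n = sum(sub$w[sub[[m]] == "excess"]),
          excess_pct = 100 * sum(sub$w[sub[[m]] == "excess"]) / denom,
          adequate_n = sum(sub$w[sub[[m]] == "adequate"]),
          adequate_pct = 100 * sum(sub$w[sub[[m]] == "adequate"]) / denom,
          stringsAsFactors = FALSE
        )
      }
      rows[[length(rows) + 1L]] <- data.frame(
        stratum = s, standard = std, macronutrient = "overall", n = nrow(sub),
        deficit_n = NA_real_, deficit_pct = NA_real_,
        excess_n = NA_real_, excess_pct = NA_real_,
        adequate_n = sum(sub$w[sub$overall_adequate]),
        adequate_pct = 100 * sum(sub$w[sub$overall_adequate]) / denom,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
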
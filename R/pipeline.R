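# End-to-end orchestration: ingest -> basket selection -> resolution ->
# inclusion/exclusion -> nutrient accounting -> AMDR classification ->
# stratified summaries, with CSV outputs and a JSON run manifest.

#' Pipeline configuration
#'
#' @param registry_path basket registry (CSV or JSON).
#' @param composition_path food-composition table CSV.
#' @param price_path market price table CSV.
#' @param standards_path AMDR standards JSON.
#' @param out_dir output directory for report tables; created if absent.
#' @param item_ceiling_kg extreme-value ceiling per item; default 100 kg.
#' @param basket_ceiling_kg extreme-value ceiling per basket; default 500 kg.
#' @param max_unresolved_frac basket exclusion threshold on the unresolved
#'   item fraction; default 0.2.
#' @param similarity_floor minimum food-name similarity; default 0.6.
#' @param densities named g/mL densities per group for volume conversion.
#' @param expansion_weights optional named stratum expansion weights
#'   (`N_h / n_h`) applied to adequacy counts.
#' @param alpha significance level for group comparisons; default 0.05.
#' @param seed integer recorded in the manifest.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(registry_path,
                            composition_path = canasta_example("composition_table.csv"),
                            price_path = canasta_example("price_table.csv"),
                            standards_path = canasta_example("amdr_standards.json"),
                            out_dir = tempfile("canasta_run_"),
                            item_ceiling_kg = 100,
                            basket_ceiling_kg = 500,
                            max_unresolved_frac = 0.2,
                            similarity_floor = 0.6,
                            densities = numeric(0),
                            expansion_weights = NULL,
                            alpha = 0.05,
                            seed = 1L) {
  stopifnot(alpha > 0, alpha < 1)
  for (p in c(registry_path, composition_path, price_path, standards_path)) {
    if (!file.exists(p)) {
      canasta_error("canasta_missing_file", sprintf("input does not exist: %s", p))
    }
  }
  structure(as.list(environment()), class = "pipeline_config")
}

stage <- function(name, expr) {
  tryCatch(expr, canasta_error = function(e) {
    canasta_error("canasta_pipeline_error",
                  sprintf("[stage %s] %s", name, conditionMessage(e)))
  })
}

#' Run the full basket-adequacy pipeline
#'
#' Stages: parse the registry; keep one basket per municipality (most
#' beneficiaries, smallest id on ties); resolve foods and masses; apply the
#' inclusion/exclusion flow; compute nutrient profiles and per-group
#' quantities; classify against every AMDR standard; summarize by geographic
#' domain and budget group with Kruskal-Wallis + Dunn letter displays.
#' Writes `profiles.csv`, `caloric_distribution_by_<stratum>.csv`,
#' `group_quantities_by_<stratum>.csv`, `adequacy_by_<stratum>.csv`,
#' `overall_adequacy.csv`, `exclusion_flow.csv`, `approximation_log.csv` and
#' `manifest.json` under `out_dir`. Re-running the same configuration
#' produces identical outputs.
#'
#' @param config a `pipeline_config`.
#' @return invisibly, a list with all in-memory results (`profiles`,
#'   `group_kg`, `classifications`, `adequacy`, `comparisons`, `flow`,
#'   `manifest`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  table <- stage("load_composition", load_composition_table(config$composition_path))
  prices <- stage("load_prices", load_price_table(config$price_path))
  standards <- stage("load_standards", load_amdr_standards(config$standards_path))
  reg <- stage("parse_registry", parse_registry(config$registry_path))

  n_municipalities <- nrow(reg$municipalities)
  if (n_municipalities == 0L) {
    flow <- data.frame(stage = "input", count = 0L)
    utils::write.csv(flow, file.path(config$out_dir, "exclusion_flow.csv"),
                     row.names = FALSE)
    writeLines("no baskets survived inclusion",
               file.path(config$out_dir, "no_baskets.txt"))
    return(invisible(list(profiles = NULL, flow = flow)))
  }

  # one basket per municipality: the most-distributed variant
  selected <- stage("select_basket", {
    keys <- split(reg$items, reg$items$municipality_id)
    chosen <- vapply(keys, select_basket, character(1))
    picked <- Map(function(df, id) df[df$basket_id == id, , drop = FALSE], keys, chosen)
    do.call(rbind, picked)
  })

  res <- stage("resolve_items",
               resolve_items(selected, table, prices,
                             similarity_floor = config$similarity_floor,
                             densities = config$densities))
  incl <- stage("inclusion_exclusion",
                apply_inclusion_exclusion(
                  res$resolved, res$unresolved,
                  item_ceiling_kg = config$item_ceiling_kg,
                  basket_ceiling_kg = config$basket_ceiling_kg,
                  max_unresolved_frac = config$max_unresolved_frac
                ))

  flow <- data.frame(
    stage = c("municipalities_in", "analyzed",
              paste0("excluded_", c("too_few_foods", "extreme_value", "unresolved_items"))),
    count = c(n_municipalities, length(incl$kept),
              sum(incl$excluded$reason == "too_few_foods"),
              sum(incl$excluded$reason == "extreme_value"),
              sum(incl$excluded$reason == "unresolved_items"))
  )
  utils::write.csv(flow, file.path(config$out_dir, "exclusion_flow.csv"), row.names = FALSE)

  if (length(incl$kept) == 0L) {
    writeLines("no baskets survived inclusion",
               file.path(config$out_dir, "no_baskets.txt"))
    manifest <- pipeline_manifest(config, flow, ok = TRUE)
    return(invisible(list(profiles = NULL, flow = flow, manifest = manifest)))
  }

  profiles <- stage("nutrient_accounting", profile_table(incl$kept, table))
  group_kg <- stage("group_quantities", group_quantity_table(incl$kept))
  cls <- stage("amdr_classification", classification_table(profiles, standards))

  utils::write.csv(profiles, file.path(config$out_dir, "profiles.csv"), row.names = FALSE)
  utils::write.csv(group_kg, file.path(config$out_dir, "group_quantities.csv"),
                   row.names = FALSE)

  # stratified comparisons (caloric distribution and group kg) and adequacy
  comparisons <- list()
  adequacy <- list()
  for (stratum in c("domain", "budget_group")) {
    comp <- stage("stratified_stats", {
      do.call(rbind, lapply(c("pct_protein", "pct_carb", "pct_fat"), function(v) {
        gc <- group_comparison(profiles[[v]], profiles[[stratum]], alpha = config$alpha)
        cbind(variable = v, gc$summary, H = gc$H, p = gc$p)
      }))
    })
    utils::write.csv(comp,
                     file.path(config$out_dir,
                               sprintf("caloric_distribution_by_%s.csv", stratum)),
                     row.names = FALSE)
    kgcomp <- stage("stratified_stats", {
      groups_present <- names(which(colSums(group_kg[FOOD_GROUPS]) > 0))
      do.call(rbind, lapply(groups_present, function(v) {
        gc <- group_comparison(group_kg[[v]], group_kg[[stratum]], alpha = config$alpha)
        cbind(variable = v, gc$summary, H = gc$H, p = gc$p)
      }))
    })
    utils::write.csv(kgcomp,
                     file.path(config$out_dir,
                               sprintf("group_quantities_by_%s.csv", stratum)),
                     row.names = FALSE)
    adeq <- stage("adequacy_summary",
                  adequacy_summary(cls, stratum = stratum,
                                   weights = config$expansion_weights))
    utils::write.csv(adeq,
                     file.path(config$out_dir, sprintf("adequacy_by_%s.csv", stratum)),
                     row.names = FALSE)
    comparisons[[stratum]] <- list(caloric = comp, quantities = kgcomp)
    adequacy[[stratum]] <- adeq
  }
  adequacy$national <- adequacy_summary(cls, stratum = NULL,
                                        weights = config$expansion_weights)
  utils::write.csv(adequacy$national,
                   file.path(config$out_dir, "adequacy_national.csv"), row.names = FALSE)

  # overall adequacy percentages per stratum and standard (figure analogues)
  overall <- adequacy_rows <- do.call(rbind, lapply(
    c("domain", "budget_group", "national"),
    function(s) cbind(stratified_by = s,
                      adequacy[[s]][adequacy[[s]]$macronutrient == "overall",
                                    c("stratum", "standard", "n", "adequate_pct")])
  ))
  utils::write.csv(overall, file.path(config$out_dir, "overall_adequacy.csv"),
                   row.names = FALSE)

  # approximation log: item-level provenance of weight/similarity approximations
  approx_log <- do.call(rbind, lapply(incl$kept, function(b) {
    cbind(municipality_id = b$municipality_id, basket_id = b$basket_id, b$items)
  }))
  utils::write.csv(approx_log, file.path(config$out_dir, "approximation_log.csv"),
                   row.names = FALSE)

  manifest <- pipeline_manifest(config, flow, ok = TRUE)
  invisible(list(
    profiles = profiles, group_kg = group_kg, classifications = cls,
    adequacy = adequacy, comparisons = comparisons, flow = flow,
    excluded = incl$excluded, kept = incl$kept, manifest = manifest
  ))
}

pipeline_manifest <- function(config, flow, ok) {
  cfg <- unclass(config)
  cfg <- cfg[!vapply(cfg, is.null, logical(1))]
  cfg_json <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)
  tmp <- tempfile()
  writeLines(cfg_json, tmp)
  manifest <- list(
    seed = config$seed,
    package_version = as.character(utils::packageVersion("canasta")),
    config = jsonlite::fromJSON(cfg_json),
    config_hash = unname(tools::md5sum(tmp)),
    flow = flow,
    flow_conserved = flow$count[flow$stage == "municipalities_in"] ==
      sum(flow$count[flow$stage != "municipalities_in"])
  )
  unlink(tmp)
  if (!isTRUE(manifest$flow_conserved)) {
    canasta_error("canasta_pipeline_error",
                  "flow conservation violated: municipalities_in != analyzed + excluded")
  }
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  manifest
}
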
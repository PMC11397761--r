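#' @keywords internal
"_PACKAGE"

# Condition helpers -------------------------------------------------------

canasta_error <- function(class, message, ...) {
  stop(structure(
    class = c(class, "canasta_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

#' Convert soles to US dollars at the program's implied exchange rate
#'
#' The budget-group equivalences of the basket program (50,000 soles for
#' US$14,000) imply an exchange rate of 0.28 USD per sol, i.e. about
#' 3.57 soles per dollar (the July 2020 rate). This helper applies that
#' rate so monetary figures can be reported in both currencies.
#'
#' @param soles numeric amount in Peruvian soles.
#' @param usd_per_sol exchange rate; default `14000 / 50000`.
#' @return amount in US dollars.
#' @examples
#' soles_to_usd(50000)      # 14000
#' soles_to_usd(213e6) / 1e6  # 59.64 million
#' @export
soles_to_usd <- function(soles, usd_per_sol = 14000 / 50000) {
  stopifnot(is.numeric(soles), is.numeric(usd_per_sol), usd_per_sol > 0)
  soles * usd_per_sol
}

# Round half away from zero (SPSS-style), used for gross sample sizes
round_half_up <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

#' Path to a packaged example data file
#'
#' Convenience wrapper around [system.file()] for the plain-text reference
#' fixtures shipped with the package: `composition_table.csv` (a synthetic
#' 40-food stand-in for the Peruvian food-composition tables, spanning the
#' ten Food Guide groups), `price_table.csv` (synthetic wholesale/retail
#' market prices per kg) and `amdr_standards.json` (INCAP and INDECI
#' macronutrient distribution ranges).
#'
#' @param file file name under `extdata/`; if missing, lists available files.
#' @return absolute path to the file.
#' @export
canasta_example <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "canasta")))
  }
  path <- system.file("extdata", file, package = "canasta")
  if (!nzchar(path)) {
    canasta_error("canasta_missing_file", sprintf("no packaged file '%s'", file))
  }
  path
}

# The ten food groups of the Peruvian Food Guide
FOOD_GROUPS <- c(
  "sugars", "meats", "cereals", "oils", "dairy",
  "legumes", "fruits", "eggs", "vegetables", "tubers"
)

GEO_DOMAINS <- c("lima_metropolitana", "resto_costa", "sierra", "selva")
BUDGET_GROUPS <- c("A", "B", "C", "D")
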
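## internal helpers shared across modules

`%||%` <- function(x, y) if (is.null(x)) y else x

## collapse runs of whitespace and trim; vectorized, NA-safe
squish <- function(x) {
  x <- gsub("[[:space:]]+", " ", x)
  trimws(x)
}

## case/whitespace-insensitive key used wherever PTs or names are matched
norm_key <- function(x) toupper(squish(x))

pv_extdata <- function(file) {
  path <- system.file("extdata", file, package = "pvsignal")
  if (!nzchar(path)) stop("packaged data file not found: ", file, call. = FALSE)
  path
}

#' Packaged country-to-region lookup
#'
#' FAERS records the reporting country as an ISO 3166-1 alpha-2 code in
#' `occr_country`; continent-level regions (Europe, North America, Asia,
#' Oceania, South America, Africa) are an analysis grouping, not a FAERS
#' field, so the mapping ships as an editable two-column CSV. Codes absent
#' from the table map to `"unknown"`.
#'
#' @param path Optional path to a replacement CSV with columns
#'   `country_code` and `region`.
#' @return A `data.table` with columns `country_code` and `region`.
#' @export
#' @examples
#' head(country_regions())
country_regions <- function(path = NULL) {
  path <- path %||% pv_extdata("country_regions.csv")
  ## na.strings = NULL so Namibia's code "NA" survives as text
  dt <- data.table::fread(path, colClasses = "character", na.strings = NULL)
  if (!all(c("country_code", "region") %in% names(dt))) {
    stop("region table needs columns country_code, region", call. = FALSE)
  }
  dt[]
}

pv_regions <- c("Europe", "North America", "Asia", "Oceania",
                "South America", "Africa", "unknown")

pv_outcome_codes <- c(
  DE = "death", LT = "life_threatening", HO = "hospitalization",
  DS = "disability", CA = "congenital_anomaly",
  RI = "required_intervention", OT = "other_serious"
)

## FAERS occp_cod -> reporter class
pv_reporter_map <- c(
  MD = "health_professional", PH = "health_professional",
  OT = "health_professional", HP = "health_professional",
  CN = "non_health_professional", LW = "non_health_professional"
)
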
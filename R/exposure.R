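## Drug-name normalization and exposure-group assignment.
## Verbatim FAERS drug names mix generics, trade names, doses and
## formulation noise ("LIPITOR 40MG FILM-COATED TABLET"); exposure is
## defined on normalized ingredients of primary-suspect drugs only.

pv_statins <- c("simvastatin", "atorvastatin", "rosuvastatin", "pravastatin",
                "fluvastatin", "lovastatin", "pitavastatin", "cerivastatin")

## formulation/dose tokens stripped before dictionary lookup
pv_drug_stopwords <- c(
  "MG", "MCG", "G", "ML", "TABLET", "TABLETS", "TAB", "TABS", "CAPSULE",
  "CAPSULES", "CAP", "CAPS", "ER", "XR", "SR", "CR", "LA", "ORAL", "FILM",
  "COATED", "FILMCOATED", "EXTENDED", "RELEASE", "DELAYED", "INJECTION",
  "SOLUTION", "SUSPENSION", "UNKNOWN", "UNK")

#' Load a drug dictionary
#'
#' The dictionary maps cleaned verbatim drug names to canonical
#' ingredients; it ships as an editable two-column tab-separated file
#' (`pattern`, `ingredient`) covering the eight statins, colchicine, and
#' their common trade names, so users can extend coverage without code
#' changes. Lookup through [normalize_name()] is case-, whitespace- and
#' punctuation-insensitive and strictly exact: no fuzzy matching.
#'
#' @param path Optional path to a replacement dictionary file.
#' @return A `drug_dictionary` object.
#' @export
#' @examples
#' d <- drug_dictionary()
#' normalize_name(c("LIPITOR 10MG", "Aspirin"), d)
drug_dictionary <- function(path = NULL) {
  path <- path %||% pv_extdata("drug_dictionary.tsv")
  dt <- data.table::fread(path, sep = "\t", colClasses = "character")
  if (!all(c("pattern", "ingredient") %in% names(dt))) {
    stop("drug dictionary needs columns pattern, ingredient", call. = FALSE)
  }
  map <- stats::setNames(dt$ingredient, norm_key(dt$pattern))
  structure(list(entries = dt, map = map), class = "drug_dictionary")
}

clean_drug_name <- function(x) {
  x <- toupper(x)
  x <- gsub("[[:punct:]]", " ", x)
  cleaned <- vapply(strsplit(squish(x), " ", fixed = TRUE), function(tok) {
    tok <- tok[!grepl("^[0-9]+([.,][0-9]+)?(MG|MCG|G|ML)?$", tok)]
    tok <- tok[!(tok %in% pv_drug_stopwords)]
    paste(tok, collapse = " ")
  }, character(1))
  cleaned
}

#' Normalize verbatim drug names to ingredients
#'
#' Cleaning is deterministic: uppercase, punctuation to spaces, removal of
#' numeral/dose/formulation tokens, whitespace collapse, then an exact
#' dictionary lookup. Names not in the dictionary return `"unknown"`.
#'
#' @param verbatim Character vector of verbatim drug name strings.
#' @param dict A [drug_dictionary()].
#' @return Character vector of canonical ingredients (`"unknown"` for
#'   misses).
#' @export
normalize_name <- function(verbatim, dict = drug_dictionary()) {
  stopifnot(inherits(dict, "drug_dictionary"))
  hit <- dict$map[clean_drug_name(verbatim)]
  unname(ifelse(is.na(hit), "unknown", hit))
}

#' Exposure-group labels recognised by the pipeline
#'
#' @param statins Character vector of statin ingredient names.
#' @return Character vector of all group labels in display order.
#' @export
exposure_labels <- function(statins = pv_statins) {
  c(paste0("statin:", statins), ">=2 statins", "colchicine",
    paste0("colchicine+statin:", statins), "colchicine+>=2 statins",
    "other")
}

#' Assign each report to one exposure group
#'
#' Exposure is defined by the set of normalized ingredients among a
#' report's suspect drugs, by default only those with role code `PS`
#' (primary suspect): colchicine together with exactly one statin gives
#' `colchicine+statin:<name>`; colchicine with two or more distinct
#' statins gives `colchicine+>=2 statins`; colchicine alone gives
#' `colchicine`; one statin alone gives `statin:<name>`; several statins
#' without colchicine give `>=2 statins`; anything else (including
#' reports whose suspect drugs are all outside the dictionary) gives
#' `other`. Assignment depends only on the ingredient set, so drug-row
#' order and repeated rows for one ingredient cannot change it.
#'
#' @param store A deduplicated `faers_store`.
#' @param dict A [drug_dictionary()].
#' @param roles Drug role codes that define exposure; `"PS"` by default.
#'   Supplying `c("PS", "SS")` widens the definition to all suspect drugs.
#' @return The store with `ingredient` filled in on `drugs` and a `group`
#'   column added to `demo`.
#' @export
assign_groups <- function(store, dict = drug_dictionary(), roles = "PS") {
  stopifnot(inherits(store, "faers_store"))
  drugs <- data.table::copy(store$drugs)
  drugs[, ingredient := normalize_name(verbatim, dict)]

  rel <- drugs[toupper(trimws(role)) %in% roles & ingredient != "unknown",
               .(primaryid, ingredient)]
  rel <- unique(rel)
  grp <- rel[, {
    statin <- sort(ingredient[ingredient %in% pv_statins])
    has_col <- "colchicine" %in% ingredient
    lab <- if (has_col && length(statin) == 1L) {
      paste0("colchicine+statin:", statin)
    } else if (has_col && length(statin) >= 2L) {
      "colchicine+>=2 statins"
    } else if (has_col) {
      "colchicine"
    } else if (length(statin) == 1L) {
      paste0("statin:", statin)
    } else if (length(statin) >= 2L) {
      ">=2 statins"
    } else {
      "other"
    }
    .(group = lab)
  }, by = primaryid]

  demo <- data.table::copy(store$demo)
  demo[, group := grp$group[match(primaryid, grp$primaryid)]]
  demo[is.na(group), group := "other"]

  out <- store
  out$demo <- demo
  out$drugs <- drugs
  out
}
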
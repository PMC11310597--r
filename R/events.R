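## Myopathy case definition via a narrow-scope SMQ-style preferred-term
## set, and the prior-disease exclusion that uses indication PTs as the
## proxy for pre-existing myopathy (spontaneous reports carry no reliable
## medical-history table).

#' Load an SMQ-style preferred-term set
#'
#' A term set is the case definition: a report is a case iff at least one
#' of its reaction PTs is in the set. The packaged default is seeded with
#' the narrow rhabdomyolysis/myopathy terms (SMQ 20000002 scope) plus
#' UK/US spelling variants; MedDRA itself is licensed, so this set is an
#' editable approximation — users holding a MedDRA license can drop in
#' the full narrow SMQ via `path`. Matching is case-insensitive exact
#' after whitespace normalization.
#'
#' @param path Optional path to a CSV with columns `pt_name`,
#'   `meddra_code`, `scope`.
#' @param scope Keep only terms of this scope (`"narrow"` or `"broad"`).
#' @param smq_code Identifier recorded in the object.
#' @return An `smq_terms` object.
#' @export
#' @examples
#' terms <- smq_terms()
#' terms$preferred_terms
smq_terms <- function(path = NULL, scope = "narrow", smq_code = "20000002") {
  path <- path %||% pv_extdata("smq_narrow_myopathy.csv")
  dt <- data.table::fread(path, colClasses = "character")
  if (!all(c("pt_name", "meddra_code") %in% names(dt))) {
    stop("term set needs columns pt_name, meddra_code", call. = FALSE)
  }
  if ("scope" %in% names(dt)) dt <- dt[dt$scope == scope]
  if (!nrow(dt)) stop("term set is empty after scope filter", call. = FALSE)
  structure(list(smq_code = smq_code, scope = scope,
                 preferred_terms = dt$pt_name,
                 keys = unique(norm_key(dt$pt_name)),
                 table = dt),
            class = "smq_terms")
}

#' Label reports as cases or non-cases of the term-set event
#'
#' @param store A deduplicated `faers_store`.
#' @param terms An [smq_terms()] set.
#' @return The store with a logical `is_case` column added to `demo` and a
#'   `matched_pts` table (`primaryid`, `pt`) of the reaction PTs that
#'   matched; a report is a case iff it has at least one matched PT.
#' @export
classify_reports <- function(store, terms = smq_terms()) {
  stopifnot(inherits(store, "faers_store"), inherits(terms, "smq_terms"))
  matched <- store$reactions[norm_key(pt) %in% terms$keys,
                             .(primaryid, pt)]
  demo <- data.table::copy(store$demo)
  demo[, is_case := primaryid %in% matched$primaryid]
  out <- store
  out$demo <- demo
  out$matched_pts <- matched
  out
}

#' Exclude reports with the event already present as an indication
#'
#' A report whose drug *indication* is itself in the term set describes a
#' patient who had the condition before treatment; keeping it would count
#' pre-existing disease as a drug-induced event. Such reports are removed
#' before any signal statistics.
#'
#' @param store A `faers_store`.
#' @param terms An [smq_terms()] set.
#' @return A list with `store` (the retained reports) and `n_excluded`.
#' @export
exclude_preexisting <- function(store, terms = smq_terms()) {
  stopifnot(inherits(store, "faers_store"), inherits(terms, "smq_terms"))
  bad <- unique(store$indications[norm_key(pt) %in% terms$keys, primaryid])
  keep_ids <- setdiff(store$demo$primaryid, bad)
  out <- store
  out$demo <- store$demo[primaryid %in% keep_ids]
  out$drugs <- store$drugs[primaryid %in% keep_ids]
  out$reactions <- store$reactions[primaryid %in% keep_ids]
  out$indications <- store$indications[primaryid %in% keep_ids]
  out$outcomes <- store$outcomes[primaryid %in% keep_ids]
  out$log <- c(store$log, list(n_excluded_preexisting = length(bad)))
  list(store = out, n_excluded = length(bad))
}
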
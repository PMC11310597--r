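## Case assembly: raw quarterly rows -> one normalized report store.
## The store (class "faers_store") is a list of keyed tables rather than a
## list of per-report objects so that million-row stores stay workable:
##   demo        one row per report (primaryid, caseid, caseversion,
##               receipt_date, age_years, sex, reporter, region)
##   drugs       primaryid, drug_seq, role, verbatim, ingredient
##   reactions   primaryid, pt
##   indications primaryid, pt
##   outcomes    primaryid, outcome

## age units -> years; DEC is treated as already-in-years per the field
## convention adopted here (see the methods vignette)
pv_age_factor <- c(DEC = 1, YR = 1, MON = 1 / 12, WK = 1 / 52.18,
                   DY = 1 / 365.25, HR = 1 / 8766)

convert_age_years <- function(age, age_cod) {
  val <- suppressWarnings(as.numeric(age))
  cod <- toupper(trimws(age_cod))
  fac <- pv_age_factor[cod]
  out <- val * as.numeric(fac)
  ## no unit code: accept as years when plausible, else unknown
  nocod <- is.na(fac) & !is.na(val)
  out[nocod] <- ifelse(val[nocod] <= 120, val[nocod], NA_real_)
  out[!is.na(out) & out < 0] <- NA_real_
  out
}

as_id_order <- function(x) {
  if (all(grepl("^[0-9]+$", x))) as.numeric(x) else x
}

empty_col_dt <- function(...) {
  cols <- c(...)
  dt <- data.table::as.data.table(
    stats::setNames(rep(list(character(0)), length(cols)), cols))
  dt
}

#' Assemble raw quarters into a normalized report store
#'
#' Joins the row-level tables of one or more quarters into a single store
#' with one demographic row per `primaryid`, converting ages to years,
#' mapping reporter occupation codes and reporting countries to analysis
#' categories, and decoding seriousness outcome codes. Malformed
#' demographics never fail the run: they degrade to `"unknown"`/`NA` and
#' are tallied in the store's `log`. Reports with no reaction rows are
#' dropped (an adverse-event report without an event is uninterpretable),
#' as are drug/reaction/indication/outcome rows whose `primaryid` has no
#' demographic row; both counts are logged.
#'
#' @param quarters A `raw_quarter` or list of them (from [read_quarter()]).
#' @param regions Country-to-region table, defaulting to the packaged one
#'   (see [country_regions()]).
#' @return An object of class `faers_store`; see source-level notes for
#'   the table layout. Not yet deduplicated — see [deduplicate()].
#' @export
assemble_reports <- function(quarters, regions = country_regions()) {
  if (inherits(quarters, "raw_quarter")) quarters <- list(quarters)
  if (!length(quarters)) stop("no quarters supplied", call. = FALSE)
  pick <- function(tb) {
    data.table::rbindlist(
      lapply(quarters, function(q) q[[tb]]), fill = TRUE)
  }
  demo <- pick("demo")
  if (!nrow(demo)) stop("no demographic rows in input", call. = FALSE)

  want <- c("primaryid", "caseid", "caseversion", "fda_dt", "age",
            "age_cod", "sex", "occp_cod", "occr_country")
  for (cc in setdiff(want, names(demo))) demo[, (cc) := ""]
  demo <- demo[, want, with = FALSE]

  ## several quarters can carry the same primaryid; keep the last seen
  demo <- demo[!duplicated(primaryid, fromLast = TRUE)]

  n_bad_age <- sum(nzchar(demo$age) &
                     is.na(convert_age_years(demo$age, demo$age_cod)))
  demo[, `:=`(
    caseversion = {
      v <- suppressWarnings(as.integer(caseversion))
      ifelse(is.na(v) | v < 1L, 1L, v)
    },
    receipt_date = suppressWarnings(as.integer(fda_dt)),
    age_years = convert_age_years(age, age_cod),
    sex = data.table::fcase(toupper(trimws(sex)) == "F", "female",
                            toupper(trimws(sex)) == "M", "male",
                            default = "unknown"),
    reporter = {
      r <- pv_reporter_map[toupper(trimws(occp_cod))]
      ifelse(is.na(r), "unknown", r)
    },
    region = {
      key <- toupper(trimws(occr_country))
      m <- regions$region[match(key, toupper(regions$country_code))]
      ifelse(is.na(m), "unknown", m)
    }
  )]
  demo[, c("fda_dt", "age", "age_cod", "occp_cod", "occr_country") := NULL]

  known <- demo$primaryid
  take <- function(dt, cols, rename = NULL) {
    if (!nrow(dt)) return(empty_col_dt(names(rename) %||% cols))
    for (cc in setdiff(cols, names(dt))) dt[, (cc) := ""]
    dt <- dt[, cols, with = FALSE]
    if (!is.null(rename)) data.table::setnames(dt, cols, names(rename))
    dt
  }
  drugs <- take(pick("drug"),
                c("primaryid", "drug_seq", "role_cod", "drugname"),
                c(primaryid = "primaryid", drug_seq = "drug_seq",
                  role = "role_cod", verbatim = "drugname"))
  reac <- take(pick("reac"), c("primaryid", "pt"))
  indi <- take(pick("indi"), c("primaryid", "indi_pt"),
               c(primaryid = "primaryid", pt = "indi_pt"))
  outc <- take(pick("outc"), c("primaryid", "outc_cod"))

  n_orphans <- sum(!(drugs$primaryid %in% known)) +
    sum(!(reac$primaryid %in% known)) +
    sum(!(indi$primaryid %in% known)) +
    sum(!(outc$primaryid %in% known))
  drugs <- drugs[primaryid %in% known]
  reac <- reac[primaryid %in% known & nzchar(trimws(pt))]
  indi <- indi[primaryid %in% known & nzchar(trimws(pt))]
  outc <- outc[primaryid %in% known]

  outc[, outcome := {
    m <- pv_outcome_codes[toupper(trimws(outc_cod))]
    as.character(ifelse(is.na(m), "unknown", m))
  }][, outc_cod := NULL]
  outc <- unique(outc)

  ## drop event-less reports
  has_event <- demo$primaryid %in% reac$primaryid
  n_no_event <- sum(!has_event)
  demo <- demo[has_event]
  keep_ids <- demo$primaryid
  drugs <- drugs[primaryid %in% keep_ids]
  indi <- indi[primaryid %in% keep_ids]
  outc <- outc[primaryid %in% keep_ids]

  store <- list(
    demo = demo, drugs = drugs, reactions = reac,
    indications = indi, outcomes = outc,
    log = list(n_reports = nrow(demo), n_no_event = n_no_event,
               n_orphan_rows = n_orphans, n_unparseable_age = n_bad_age)
  )
  structure(store, class = "faers_store")
}

#' @export
print.faers_store <- function(x, ...) {
  cat(sprintf(
    "<faers_store> %d reports, %d drug rows, %d reactions%s\n",
    nrow(x$demo), nrow(x$drugs), nrow(x$reactions),
    if (isTRUE(attr(x, "deduplicated"))) " (deduplicated)" else ""))
  invisible(x)
}

#' Deduplication policy
#'
#' @param deleted_case_ids Character vector of case ids to drop outright
#'   (FAERS "Deleted" lists; see [read_deleted_cases()]).
#' @param keep_rule Which report survives among versions of one case:
#'   `"latest_caseversion_then_latest_receipt"` (default; highest
#'   `caseversion`, ties broken by latest `receipt_date`, then highest
#'   `primaryid`) or `"latest_receipt_only"`.
#' @return A `dedup_policy` list.
#' @export
dedup_policy <- function(deleted_case_ids = character(),
                         keep_rule = c("latest_caseversion_then_latest_receipt",
                                       "latest_receipt_only")) {
  keep_rule <- match.arg(keep_rule)
  structure(list(deleted_case_ids = as.character(deleted_case_ids),
                 keep_rule = keep_rule),
            class = "dedup_policy")
}

#' Deduplicate a report store by case id
#'
#' Spontaneous-report databases receive several versions of one case
#' (follow-ups) and publish deletion lists for retracted reports; counting
#' each case once is a precondition of any disproportionality statistic.
#' Reports whose `caseid` is on the deleted list are removed; among
#' reports sharing a `caseid` exactly one survives, chosen by the policy's
#' deterministic keep rule. The result is sorted by `caseid`, so identical
#' input stores yield identical output no matter the input row order.
#'
#' @param store A `faers_store` from [assemble_reports()].
#' @param policy A [dedup_policy()].
#' @return The store restricted to surviving reports, with
#'   `attr(, "deduplicated") = TRUE` and removal counts appended to `log`.
#' @export
deduplicate <- function(store, policy = dedup_policy()) {
  stopifnot(inherits(store, "faers_store"))
  demo <- data.table::copy(store$demo)
  n0 <- nrow(demo)
  demo <- demo[!(caseid %in% policy$deleted_case_ids)]
  n_deleted <- n0 - nrow(demo)

  rd <- demo$receipt_date
  rd[is.na(rd)] <- -1L
  ord <- if (policy$keep_rule == "latest_receipt_only") {
    order(as_id_order(demo$caseid), -rd, -as_id_order(demo$primaryid))
  } else {
    order(as_id_order(demo$caseid), -demo$caseversion, -rd,
          -as_id_order(demo$primaryid))
  }
  demo <- demo[ord][!duplicated(caseid)]
  demo <- demo[order(as_id_order(caseid))]
  n_dupes <- n0 - n_deleted - nrow(demo)

  keep_ids <- demo$primaryid
  out <- list(
    demo = demo,
    drugs = store$drugs[primaryid %in% keep_ids],
    reactions = store$reactions[primaryid %in% keep_ids],
    indications = store$indications[primaryid %in% keep_ids],
    outcomes = store$outcomes[primaryid %in% keep_ids],
    log = c(store$log,
            list(n_removed_deleted = n_deleted,
                 n_removed_duplicates = n_dupes))
  )
  structure(out, class = "faers_store", deduplicated = TRUE)
}

#' Write a normalized report store to disk
#'
#' Emits one delimiter-separated file per store table plus a small JSON
#' schema manifest, so that a processed store can be shared without
#' re-running ingestion.
#'
#' @param store A `faers_store`.
#' @param dir Output directory (created if needed).
#' @param delim Field delimiter.
#' @return `dir`, invisibly.
#' @export
write_store <- function(store, dir, delim = "\t") {
  stopifnot(inherits(store, "faers_store"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (tb in c("demo", "drugs", "reactions", "indications", "outcomes")) {
    data.table::fwrite(store[[tb]], file.path(dir, paste0(tb, ".tsv")),
                       sep = delim)
  }
  manifest <- list(schema_version = "1.0",
                   tables = c("demo", "drugs", "reactions",
                              "indications", "outcomes"),
                   n_reports = nrow(store$demo),
                   deduplicated = isTRUE(attr(store, "deduplicated")))
  jsonlite::write_json(manifest, file.path(dir, "store.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Read a normalized report store written by [write_store()]
#' @param dir Directory containing the store tables.
#' @param delim Field delimiter used when writing.
#' @return A `faers_store`.
#' @export
read_store <- function(dir, delim = "\t") {
  manifest <- jsonlite::read_json(file.path(dir, "store.json"))
  out <- lapply(stats::setNames(nm = unlist(manifest$tables)), function(tb) {
    dt <- data.table::fread(file.path(dir, paste0(tb, ".tsv")), sep = delim,
                            na.strings = c("", "NA"))
    for (cc in intersect(c("primaryid", "caseid", "drug_seq"), names(dt))) {
      data.table::set(dt, j = cc, value = as.character(dt[[cc]]))
    }
    dt
  })
  out$log <- list(n_reports = nrow(out$demo))
  structure(out, class = "faers_store",
            deduplicated = isTRUE(manifest$deduplicated))
}
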
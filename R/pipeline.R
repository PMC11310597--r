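## End-to-end study pipeline: ingest -> dedup -> prior-disease exclusion
## -> exposure grouping -> case labeling -> signal statistics, emitting
## machine-readable analogues of the usual pharmacovigilance study
## deliverables (demographics table, per-drug count table, drug-level,
## PT-level and combination signal tables, and the case-flow ledger).

#' Percentage summary of a named count vector
#'
#' The elementary operation behind every demographic block: counts plus
#' percentages of the block total, percentages reported to `digits`
#' decimals so each column sums to 100 up to rounding.
#'
#' @param counts Named integer vector.
#' @param digits Decimal places for the percentage display column.
#' @return `data.table` with `category`, `n`, `pct` (full precision) and
#'   `pct_display` (rounded).
#' @export
#' @examples
#' proportion_summary(c(`<18` = 62, `18-64` = 6364, `>=65` = 9372,
#'                      unknown = 3397))
proportion_summary <- function(counts, digits = 1) {
  total <- sum(counts)
  pct <- if (total > 0) 100 * counts / total else rep(NA_real_, length(counts))
  data.table::data.table(category = names(counts), n = as.numeric(counts),
                         pct = pct, pct_display = round(pct, digits))
}

pv_age_bins <- function(age_years) {
  data.table::fcase(
    is.na(age_years), "unknown",
    age_years < 18, "<18 years",
    age_years < 65, "18 to 64 years",
    default = ">=65 years")
}

## top-level drug grouping used by the demographic tables: all statin
## exposure (single agents and >=2 statins) vs colchicine alone vs the
## combination
pv_top_group <- function(group) {
  data.table::fcase(
    startsWith(group, "colchicine+"), "Colchicine and Statins",
    group == "colchicine", "Colchicine",
    startsWith(group, "statin:") | group == ">=2 statins", "Statins",
    default = "other")
}

#' Demographic summary of myopathy vs non-myopathy cases
#'
#' For the exposed reports (every group except `other`), tabulates counts
#' and percentages by drug group, age bin, sex, reporter occupation,
#' reporting region and seriousness outcome, separately for myopathy
#' cases and non-cases. A report may carry several seriousness outcomes,
#' so the outcome block counts outcome entries (its percentages are of
#' all entries, and still sum to 100); reports without any outcome code
#' count once as `unknown`.
#'
#' @param store A `faers_store` labeled by [assign_groups()] and
#'   [classify_reports()].
#' @param digits Decimal places for percentage display.
#' @return `data.table` with columns `block`, `category`, `myopathy_n`,
#'   `myopathy_pct`, `nonmyopathy_n`, `nonmyopathy_pct` (display
#'   rounding applied to the pct columns).
#' @export
demographics_summary <- function(store, digits = 1) {
  stopifnot(inherits(store, "faers_store"))
  if (!all(c("group", "is_case") %in% names(store$demo))) {
    stop("store must be labeled by assign_groups() and classify_reports()",
         call. = FALSE)
  }
  demo <- store$demo[group != "other"]
  demo[, `:=`(top = pv_top_group(group), age_bin = pv_age_bins(age_years))]

  out_map <- store$outcomes[demo[, .(primaryid, is_case)], on = "primaryid"]
  out_map[is.na(outcome), outcome := "unknown"]

  blocks <- list(
    `Drug group` = list(var = "top",
                        levels = c("Statins", "Colchicine",
                                   "Colchicine and Statins")),
    `Age group` = list(var = "age_bin",
                       levels = c("<18 years", "18 to 64 years",
                                  ">=65 years", "unknown")),
    `Sex` = list(var = "sex", levels = c("female", "male", "unknown")),
    `Reporter occupation` = list(
      var = "reporter", levels = c("health_professional",
                                   "non_health_professional", "unknown")),
    `Reporter region` = list(var = "region", levels = pv_regions),
    `Outcomes` = list(var = "outcome",
                      levels = c(unname(pv_outcome_codes), "unknown")))

  one_side <- function(case_flag) {
    data.table::rbindlist(lapply(names(blocks), function(bn) {
      b <- blocks[[bn]]
      src <- if (b$var == "outcome") {
        out_map[is_case == case_flag][[b$var]]
      } else {
        demo[is_case == case_flag][[b$var]]
      }
      counts <- table(factor(src, levels = b$levels))
      ps <- proportion_summary(stats::setNames(as.integer(counts),
                                               names(counts)),
                               digits = digits)
      ps[, block := bn]
      ps
    }))
  }
  myo <- one_side(TRUE)
  non <- one_side(FALSE)
  data.table::data.table(
    block = myo$block, category = myo$category,
    myopathy_n = myo$n, myopathy_pct = myo$pct_display,
    nonmyopathy_n = non$n, nonmyopathy_pct = non$pct_display)
}

#' Per-drug case counts (myopathy vs non-myopathy)
#'
#' One row per exposure group at drug resolution (each single statin,
#' `>=2 statins`, colchicine, and each colchicine+statin combination),
#' with percentages over the combined exposed myopathy-case total — the
#' denominator under which per-drug shares of the case load add to 100.
#'
#' @inheritParams demographics_summary
#' @return `data.table` with `group`, `myopathy_n`, `myopathy_pct`,
#'   `nonmyopathy_n`, `nonmyopathy_pct`.
#' @export
drug_count_summary <- function(store, digits = 1) {
  stopifnot(inherits(store, "faers_store"))
  demo <- store$demo[group != "other"]
  levels <- setdiff(exposure_labels(), "other")
  myo <- table(factor(demo[is_case == TRUE, group], levels = levels))
  non <- table(factor(demo[is_case == FALSE, group], levels = levels))
  pm <- proportion_summary(stats::setNames(as.integer(myo), levels),
                           digits = digits)
  pn <- proportion_summary(stats::setNames(as.integer(non), levels),
                           digits = digits)
  data.table::data.table(
    group = levels, myopathy_n = pm$n, myopathy_pct = pm$pct_display,
    nonmyopathy_n = pn$n, nonmyopathy_pct = pn$pct_display)
}

#' Per-PT signal table for one exposure group
#'
#' One signal evaluation per preferred term, counting (report, PT) pairs.
#' PTs below the case-count threshold are kept in the table with
#' `is_signal = FALSE` and `below_threshold = TRUE`; PTs absent from the
#' store appear as `a = 0` rows.
#'
#' @param store Labeled `faers_store`.
#' @param group Exposure label(s) defining the index group.
#' @param pts Character vector of preferred terms (defaults to the
#'   packaged myopathy term set).
#' @param min_cases,z,ic_method Signal-rule settings; see
#'   [signal_result()].
#' @return `data.table`, one row per PT, with the [signal_result()]
#'   columns.
#' @export
pt_level_signals <- function(store, group, pts = smq_terms()$preferred_terms,
                             min_cases = 3L, z = stats::qnorm(0.975),
                             ic_method = "noren_credible") {
  pts <- unique(pts)
  data.table::rbindlist(lapply(pts, function(ptn) {
    tab <- build_table(store, group = group, event = ptn,
                       unit = "report_pt")
    res <- signal_result(tab, min_cases = min_cases, z = z,
                         ic_method = ic_method)
    cbind(data.table::data.table(pt = ptn), res)
  }))
}

## one signal row per (label, group-set) with report counting unit
group_level_signals <- function(store, groups, terms, min_cases, z,
                                ic_method) {
  data.table::rbindlist(lapply(names(groups), function(gn) {
    tab <- build_table(store, group = groups[[gn]], event = terms,
                       unit = "report")
    res <- signal_result(tab, min_cases = min_cases, z = z,
                         ic_method = ic_method)
    cbind(data.table::data.table(group = gn), res)
  }))
}

#' Study configuration
#'
#' @param quarters Input data: a character vector of directories/file
#'   sets for [read_quarter()], a list of `raw_quarter` objects, or
#'   `NULL` when `store` is given.
#' @param store Optionally, an already-assembled `faers_store` (skips
#'   ingestion).
#' @param drug_dictionary_path,term_set_path Optional replacement files
#'   for the packaged drug dictionary and SMQ term set.
#' @param deleted_case_path Optional deleted-case list file.
#' @param roles Drug role codes defining exposure (default `"PS"`).
#' @param comparator `"rest_of_store"` or `"explicit"`.
#' @param background `c(c, d)` counts when `comparator = "explicit"`.
#' @param min_cases,z,ic_method Signal-rule settings.
#' @param output_dir If non-`NULL`, [run_study()] writes CSV tables and a
#'   JSON run manifest there.
#' @param seed Seed recorded in the manifest (the analysis itself is
#'   deterministic).
#' @return A `study_config` list.
#' @export
study_config <- function(quarters = NULL, store = NULL,
                         drug_dictionary_path = NULL,
                         term_set_path = NULL, deleted_case_path = NULL,
                         roles = "PS",
                         comparator = c("rest_of_store", "explicit"),
                         background = NULL, min_cases = 3L,
                         z = stats::qnorm(0.975),
                         ic_method = c("noren_credible", "bate_variance"),
                         output_dir = NULL, seed = 1L) {
  structure(list(
    quarters = quarters, store = store,
    drug_dictionary_path = drug_dictionary_path,
    term_set_path = term_set_path,
    deleted_case_path = deleted_case_path,
    roles = roles, comparator = match.arg(comparator),
    background = background, min_cases = min_cases, z = z,
    ic_method = match.arg(ic_method), output_dir = output_dir,
    seed = seed), class = "study_config")
}

#' Read a study configuration from YAML
#'
#' Recognized keys mirror the arguments of [study_config()].
#'
#' @param path Path to a YAML file.
#' @return A `study_config`.
#' @export
read_study_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(study_config, y[intersect(names(y),
                                    names(formals(study_config)))])
}

#' Run the full disproportionality study
#'
#' Executes ingestion, deduplication, the pre-existing-myopathy
#' exclusion, exposure grouping, case labeling, and signal evaluation at
#' drug level, PT level, and for each colchicine+statin combination.
#' Identical inputs give identical outputs.
#'
#' @param config A [study_config()].
#' @return A `study_report` list: `case_flow`, `demographics_table`,
#'   `drug_count_table`, `drug_level_signals`, `pt_level_signals`,
#'   `combination_signals`, `annual_counts`, `store` (the final labeled
#'   store), and `meta`.
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  dict <- drug_dictionary(config$drug_dictionary_path)
  terms <- smq_terms(config$term_set_path)

  stage <- function(what, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[%s] %s", what, conditionMessage(e)), call. = FALSE)
    })
  }

  store <- if (!is.null(config$store)) {
    config$store
  } else {
    quarters <- stage("ingest", {
      if (is.character(config$quarters)) {
        lapply(config$quarters, read_quarter)
      } else {
        config$quarters
      }
    })
    stage("assemble", assemble_reports(quarters))
  }
  n_assembled <- nrow(store$demo)

  deleted <- if (!is.null(config$deleted_case_path)) {
    read_deleted_cases(config$deleted_case_path)
  } else {
    character()
  }
  store <- stage("deduplicate",
                 deduplicate(store, dedup_policy(deleted)))
  n_dedup <- nrow(store$demo)

  excl <- stage("exclude_preexisting", exclude_preexisting(store, terms))
  store <- excl$store
  n_after_excl <- nrow(store$demo)

  store <- stage("assign_groups",
                 assign_groups(store, dict, roles = config$roles))
  store <- stage("classify", classify_reports(store, terms))

  n_exposed <- store$demo[, sum(group != "other")]
  n_pairs <- nrow(unique(store$reactions[, .(primaryid,
                                             key = norm_key(pt))]))
  case_flow <- data.table::data.table(
    stage = c("assembled", "deduplicated", "after_preexisting_exclusion",
              "exposed_to_target_drugs"),
    n_reports = c(n_assembled, n_dedup, n_after_excl, n_exposed),
    unit = "report")
  case_flow <- rbind(case_flow, data.table::data.table(
    stage = "reaction_pairs_final", n_reports = n_pairs,
    unit = "report_pt"))

  sig_args <- list(min_cases = config$min_cases, z = config$z,
                   ic_method = config$ic_method)
  statin_labels <- paste0("statin:", pv_statins)
  combo_labels <- c(paste0("colchicine+statin:", pv_statins),
                    "colchicine+>=2 statins")
  drug_groups <- c(
    stats::setNames(as.list(statin_labels), statin_labels),
    list(">=2 statins" = ">=2 statins",
         "colchicine" = "colchicine",
         "colchicine+statins" = combo_labels,
         "statins (any)" = c(statin_labels, ">=2 statins")))
  present <- function(g) any(store$demo$group %in% g)
  drug_groups <- drug_groups[vapply(drug_groups, present, logical(1))]
  drug_signals <- do.call(group_level_signals,
                          c(list(store, drug_groups, terms), sig_args))

  pt_groups <- list("statins (any)" = c(statin_labels, ">=2 statins"),
                    "colchicine" = "colchicine",
                    "colchicine+statins" = combo_labels)
  pt_groups <- pt_groups[vapply(pt_groups, present, logical(1))]
  pt_signals <- data.table::rbindlist(lapply(names(pt_groups), function(gn) {
    tb <- do.call(pt_level_signals,
                  c(list(store, pt_groups[[gn]]), sig_args))
    cbind(data.table::data.table(group = gn), tb)
  }))

  combos <- stats::setNames(as.list(combo_labels), combo_labels)
  combos <- combos[vapply(combos, present, logical(1))]
  combo_signals <- do.call(group_level_signals,
                           c(list(store, combos, terms), sig_args))

  annual <- store$demo[group != "other",
                       .(n_reports = .N, n_myopathy = sum(is_case)),
                       by = .(year = receipt_date %/% 10000L)]
  data.table::setorder(annual, year)

  report <- structure(list(
    case_flow = case_flow,
    demographics_table = demographics_summary(store),
    drug_count_table = drug_count_summary(store),
    drug_level_signals = drug_signals,
    pt_level_signals = pt_signals,
    combination_signals = combo_signals,
    annual_counts = annual,
    store = store,
    meta = list(n_excluded_preexisting = excl$n_excluded,
                comparator = config$comparator,
                min_cases = config$min_cases, z = config$z,
                ic_method = config$ic_method, roles = config$roles,
                seed = config$seed)), class = "study_report")

  if (!is.null(config$output_dir)) write_study_report(report,
                                                      config$output_dir)
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report>\n")
  print(x$case_flow)
  cat(sprintf("signal tables: %d drug-level, %d PT-level, %d combination\n",
              nrow(x$drug_level_signals), nrow(x$pt_level_signals),
              nrow(x$combination_signals)))
  invisible(x)
}

#' Write study report tables to disk
#'
#' Emits one CSV per table plus `run_manifest.json` with the settings and
#' record counts of the run.
#'
#' @param report A `study_report` from [run_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_report <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tables <- c("case_flow", "demographics_table", "drug_count_table",
              "drug_level_signals", "pt_level_signals",
              "combination_signals", "annual_counts")
  for (tb in tables) {
    data.table::fwrite(report[[tb]], file.path(dir, paste0(tb, ".csv")))
  }
  jsonlite::write_json(
    c(report$meta, list(n_reports = nrow(report$store$demo),
                        written = tables)),
    file.path(dir, "run_manifest.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
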
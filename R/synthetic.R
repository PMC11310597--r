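## Seeded synthetic FAERS generator.
##
## The generative model is deliberately the simplest one under which ROR
## and IC estimate a planted effect: given a report's exposure label, each
## preferred term occurs as an independent Bernoulli event with
## probability min(1, r * p0), where p0 is the PT's background reporting
## probability and r the planted relative reporting rate (r = 1 means no
## association). Everything is drawn from one seeded RNG stream in a
## fixed order, so a given seed + config reproduces files byte for byte.

pv_background_pts <- c(
  "Nausea" = 0.06, "Headache" = 0.05, "Diarrhoea" = 0.05,
  "Dizziness" = 0.04, "Fatigue" = 0.04, "Drug ineffective" = 0.05)

pv_myopathy_pts <- c(
  "Rhabdomyolysis" = 0.010, "Myopathy" = 0.005, "Toxic myopathy" = 0.002,
  "Necrotising myositis" = 0.001, "Muscle necrosis" = 0.001,
  "Myoglobinuria" = 0.001, "Myoglobin blood increased" = 0.001)

pv_other_drugs <- c("ASPIRIN", "METFORMIN", "LISINOPRIL", "OMEPRAZOLE",
                    "IBUPROFEN", "AMLODIPINE", "LEVOTHYROXINE")

## trade-name variants used to exercise name normalization
pv_trade_names <- list(
  simvastatin = "ZOCOR", atorvastatin = "LIPITOR", rosuvastatin = "CRESTOR",
  pravastatin = "PRAVACHOL", fluvastatin = "LESCOL", lovastatin = "MEVACOR",
  pitavastatin = "LIVALO", cerivastatin = "BAYCOL", colchicine = "COLCRYS")

pv_region_countries <- list(
  "Europe" = c("FR", "DE", "GB", "IT", "ES"),
  "North America" = c("US", "US", "US", "CA"),
  "Asia" = c("JP", "CN", "KR"),
  "Oceania" = "AU", "South America" = "BR", "Africa" = "ZA",
  "unknown" = "")

default_exposure_probs <- function() {
  c("other" = 0.74,
    "statin:simvastatin" = 0.06, "statin:atorvastatin" = 0.08,
    "statin:rosuvastatin" = 0.04, "statin:pravastatin" = 0.02,
    "statin:fluvastatin" = 0.005, "statin:lovastatin" = 0.005,
    "statin:pitavastatin" = 0.003, "statin:cerivastatin" = 0.001,
    ">=2 statins" = 0.01, "colchicine" = 0.04,
    "colchicine+statin:simvastatin" = 0.010,
    "colchicine+statin:atorvastatin" = 0.012,
    "colchicine+statin:rosuvastatin" = 0.006,
    "colchicine+statin:pravastatin" = 0.003,
    "colchicine+statin:fluvastatin" = 0.001,
    "colchicine+statin:lovastatin" = 0.001,
    "colchicine+statin:pitavastatin" = 0.001,
    "colchicine+>=2 statins" = 0.002)
}

default_planted <- function() {
  data.table::data.table(
    group = c("statin:simvastatin", "colchicine",
              "colchicine+statin:simvastatin",
              "colchicine+statin:simvastatin"),
    pt = c("Rhabdomyolysis", "Myopathy", "Rhabdomyolysis",
           "Toxic myopathy"),
    r = c(12, 17, 23, 30))
}

#' Configuration of a synthetic report store
#'
#' Bundles every knob of the generator: store size, per-PT background
#' reporting probabilities, exposure-group mix, the planted
#' (group, PT) -> relative-reporting-rate map, duplicate and
#' myopathy-indication rates, demographic marginals, and the seed. The
#' defaults sketch a small FAERS-like store centred on the
#' colchicine/statin question: mostly unrelated reports, single-statin
#' and colchicine groups at a few percent each, combination groups below
#' a percent, and planted myotoxicity excesses that are strongest for the
#' combination — the structure, not the scale, of the real database.
#'
#' @param n_reports Number of unique cases to generate.
#' @param background_event_prob Named per-PT Bernoulli probabilities.
#' @param exposure_probs Named probabilities over exposure labels.
#' @param planted_associations `data.frame` with columns `group`, `pt`,
#'   `r` (relative reporting rate; `r = 1` means no association). Pairs
#'   not listed default to `r = 1`.
#' @param duplicate_rate Probability a case is emitted a second time with
#'   incremented `caseversion` and later receipt date.
#' @param indication_myopathy_rate Fraction of reports given a myopathy
#'   PT as drug *indication*, to exercise the pre-existing-disease
#'   exclusion.
#' @param polypharmacy_probs Probabilities that an `other`-group report
#'   lists 1, 2, 3 primary-suspect drugs.
#' @param age_mean,age_sd,age_unknown_rate Age marginal (years).
#' @param sex_probs,reporter_probs,region_probs,outcome_probs Named
#'   categorical marginals (outcomes are independent Bernoulli per code,
#'   so one report may carry several).
#' @param seed Integer RNG seed.
#' @return A `synthetic_truth` list.
#' @export
synthetic_truth <- function(
    n_reports = 10000,
    background_event_prob = c(pv_myopathy_pts, pv_background_pts),
    exposure_probs = default_exposure_probs(),
    planted_associations = default_planted(),
    duplicate_rate = 0.05,
    indication_myopathy_rate = 0.005,
    polypharmacy_probs = c(0.7, 0.2, 0.1),
    age_mean = 62, age_sd = 18, age_unknown_rate = 0.15,
    sex_probs = c(female = 0.45, male = 0.45, unknown = 0.10),
    reporter_probs = c(health_professional = 0.55,
                       non_health_professional = 0.35, unknown = 0.10),
    region_probs = c("Europe" = 0.25, "North America" = 0.50,
                     "Asia" = 0.10, "Oceania" = 0.02,
                     "South America" = 0.04, "Africa" = 0.01,
                     "unknown" = 0.08),
    outcome_probs = c(DE = 0.08, LT = 0.04, HO = 0.30, DS = 0.02,
                      CA = 0.001, RI = 0.003, OT = 0.25),
    seed = 20040101) {
  stopifnot(n_reports >= 1,
            all(background_event_prob >= 0 & background_event_prob <= 1),
            all(exposure_probs >= 0), duplicate_rate >= 0,
            duplicate_rate <= 1,
            all(planted_associations$r >= 0))
  planted <- data.table::as.data.table(planted_associations)
  if (nrow(planted) &&
      !all(c("group", "pt", "r") %in% names(planted))) {
    stop("planted_associations needs columns group, pt, r", call. = FALSE)
  }
  structure(list(
    n_reports = as.integer(n_reports),
    background_event_prob = background_event_prob,
    exposure_probs = exposure_probs / sum(exposure_probs),
    planted_associations = planted,
    duplicate_rate = duplicate_rate,
    indication_myopathy_rate = indication_myopathy_rate,
    polypharmacy_probs = polypharmacy_probs / sum(polypharmacy_probs),
    age_mean = age_mean, age_sd = age_sd,
    age_unknown_rate = age_unknown_rate,
    sex_probs = sex_probs, reporter_probs = reporter_probs,
    region_probs = region_probs, outcome_probs = outcome_probs,
    seed = as.integer(seed)), class = "synthetic_truth")
}

## label -> character vector of exposed ingredient names
label_ingredients <- function(label) {
  if (label == "colchicine") return("colchicine")
  if (label == ">=2 statins") return(c("simvastatin", "atorvastatin"))
  if (label == "colchicine+>=2 statins") {
    return(c("colchicine", "simvastatin", "atorvastatin"))
  }
  if (startsWith(label, "colchicine+statin:")) {
    return(c("colchicine", sub("^colchicine\\+statin:", "", label)))
  }
  if (startsWith(label, "statin:")) return(sub("^statin:", "", label))
  character(0)
}

## verbatim rendering of an ingredient: generic, trade name, or generic
## plus dose/formulation noise, chosen by a pre-drawn style code 1/2/3
render_verbatim <- function(ingredient, style) {
  trade <- pv_trade_names[[ingredient]]
  up <- toupper(ingredient)
  if (style == 2L && !is.null(trade)) return(trade)
  if (style == 3L) return(paste0(up, " 20MG TABLET"))
  up
}

#' Simulate a raw synthetic quarter in memory
#'
#' Draws a complete FAERS-dialect row store (DEMO/DRUG/REAC/INDI/OUTC)
#' from a [synthetic_truth()] configuration, together with a manifest of
#' ground truth: per planted pair the expected and realized case counts,
#' realized exposure-group sizes, the unique-case count, and the ids
#' carrying duplicate versions and myopathy indications.
#'
#' @param truth A [synthetic_truth()].
#' @return List with `quarter` (a `raw_quarter`) and `manifest`.
#' @export
simulate_reports <- function(truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  set.seed(truth$seed)
  n <- truth$n_reports
  labels <- names(truth$exposure_probs)
  lab <- sample(labels, n, replace = TRUE, prob = truth$exposure_probs)

  caseid <- sprintf("9%08d", seq_len(n))
  primaryid <- paste0(caseid, "1")

  ## demographics
  age <- round(pmin(100, pmax(1, stats::rnorm(n, truth$age_mean,
                                              truth$age_sd))))
  age_chr <- as.character(age)
  age_chr[runif(n) < truth$age_unknown_rate] <- ""
  sex_lab <- sample(names(truth$sex_probs), n, TRUE, truth$sex_probs)
  sex <- c(female = "F", male = "M", unknown = "")[sex_lab]
  rep_lab <- sample(names(truth$reporter_probs), n, TRUE,
                    truth$reporter_probs)
  occp <- c(health_professional = "MD", non_health_professional = "CN",
            unknown = "")[rep_lab]
  reg_lab <- sample(names(truth$region_probs), n, TRUE, truth$region_probs)
  country <- vapply(reg_lab, function(rg) {
    cand <- pv_region_countries[[rg]]
    cand[sample.int(length(cand), 1L)]
  }, character(1), USE.NAMES = FALSE)
  fda_dt <- as.integer(sample(2004:2022, n, TRUE) * 10000 +
                         sample(1:12, n, TRUE) * 100 + sample(1:28, n, TRUE))

  demo <- data.table::data.table(
    primaryid = primaryid, caseid = caseid, caseversion = "1",
    fda_dt = as.character(fda_dt), age = age_chr,
    age_cod = ifelse(nzchar(age_chr), "YR", ""),
    sex = sex, occp_cod = occp, occr_country = country)

  ## drugs: exposure-defining PS drugs, noise PS drugs for "other"
  drug_list <- lapply(labels, label_ingredients)
  names(drug_list) <- labels
  n_ps_other <- sample(seq_along(truth$polypharmacy_probs), n, TRUE,
                       truth$polypharmacy_probs)
  style <- sample(1:3, n, TRUE, c(0.6, 0.2, 0.2))
  ## verbatim strings precomputed per (ingredient, style)
  verb_keys <- expand.grid(ing = c(pv_statins, "colchicine"),
                           style = 1:3, stringsAsFactors = FALSE)
  verb_lookup <- stats::setNames(
    mapply(render_verbatim, verb_keys$ing, verb_keys$style),
    paste(verb_keys$ing, verb_keys$style))
  k_map <- vapply(drug_list, length, 0L)
  k_per <- k_map[lab]
  is_exposed <- k_per > 0L
  exp_pid <- rep(primaryid[is_exposed], k_per[is_exposed])
  exp_ing <- unlist(drug_list[lab[is_exposed]], use.names = FALSE)
  exp_style <- rep(style[is_exposed], k_per[is_exposed])
  exp_seq <- sequence(k_per[is_exposed])
  n_oth <- n_ps_other
  n_oth[is_exposed] <- 0L
  oth_pid <- rep(primaryid, n_oth)
  oth_nm <- pv_other_drugs[sample.int(length(pv_other_drugs),
                                      sum(n_oth), TRUE)]
  drugs <- data.table::data.table(
    primaryid = c(exp_pid, oth_pid),
    drug_seq = as.character(c(exp_seq, sequence(n_oth[n_oth > 0L]))),
    role_cod = "PS",
    drugname = c(unname(verb_lookup[paste(exp_ing, exp_style)]), oth_nm))
  data.table::setkey(drugs, primaryid)

  ## reactions: per-PT Bernoulli with planted multiplicative excess
  p0 <- truth$background_event_prob
  planted <- truth$planted_associations
  reac_cols <- lapply(names(p0), function(ptn) {
    p <- rep(p0[[ptn]], n)
    if (nrow(planted)) {
      hits <- planted[planted$pt == ptn]
      for (k in seq_len(nrow(hits))) {
        p[lab == hits$group[k]] <- min(1, hits$r[k] * p0[[ptn]])
      }
    }
    stats::rbinom(n, 1L, p) == 1L
  })
  names(reac_cols) <- names(p0)
  event_mat <- do.call(cbind, reac_cols)
  ## reports with no drawn event get one filler background PT so that
  ## every report has at least one reaction
  none <- rowSums(event_mat) == 0L
  filler <- sample(names(pv_background_pts), n, TRUE)
  reac <- data.table::rbindlist(c(
    lapply(names(p0), function(ptn) {
      data.table::data.table(primaryid = primaryid[event_mat[, ptn]],
                             pt = ptn)
    }),
    list(data.table::data.table(primaryid = primaryid[none],
                                pt = filler[none]))))
  data.table::setkey(reac, primaryid)

  ## indications: disease-appropriate, plus planted pre-existing myopathy
  indi_pt <- ifelse(startsWith(lab, "colchicine"), "Gout",
                    ifelse(lab == "other", "Hypertension",
                           "Hypercholesterolaemia"))
  pre_myo <- runif(n) < truth$indication_myopathy_rate
  indi <- data.table::data.table(primaryid = primaryid, indi_pt = indi_pt)
  indi <- rbind(indi,
                data.table::data.table(primaryid = primaryid[pre_myo],
                                       indi_pt = "Rhabdomyolysis"))

  ## outcomes: independent Bernoulli per seriousness code
  outc <- data.table::rbindlist(lapply(names(truth$outcome_probs),
                                       function(code) {
    hit <- runif(n) < truth$outcome_probs[[code]]
    data.table::data.table(primaryid = primaryid[hit], outc_cod = code)
  }))

  ## duplicate case versions: exact copies except caseversion/receipt
  dup <- runif(n) < truth$duplicate_rate
  if (any(dup)) {
    dup_pid_old <- primaryid[dup]
    dup_pid_new <- paste0(caseid[dup], "2")
    demo2 <- demo[dup]
    demo2[, `:=`(primaryid = dup_pid_new, caseversion = "2",
                 fda_dt = as.character(as.integer(fda_dt) + 10000L))]
    demo <- rbind(demo, demo2)
    copy_rows <- function(dt) {
      ext <- dt[primaryid %in% dup_pid_old]
      ext[, primaryid := dup_pid_new[match(primaryid, dup_pid_old)]]
      rbind(dt, ext)
    }
    drugs <- copy_rows(drugs)
    reac <- copy_rows(reac)
    indi <- copy_rows(indi)
    outc <- copy_rows(outc)
  }

  quarter <- structure(list(demo = demo, drug = drugs, reac = reac,
                            indi = indi, outc = outc,
                            ther = data.table::data.table(),
                            log = list()),
                       class = "raw_quarter")

  planted_stats <- if (nrow(planted)) {
    data.table::rbindlist(lapply(seq_len(nrow(planted)), function(k) {
      g <- planted$group[k]; ptn <- planted$pt[k]
      p_eff <- min(1, planted$r[k] * (p0[[ptn]] %||% 0))
      in_g <- lab == g
      data.table::data.table(
        group = g, pt = ptn, r = planted$r[k],
        expected_a = n * truth$exposure_probs[[g]] * p_eff,
        realized_a = sum(in_g & event_mat[, ptn]))
    }))
  } else {
    data.table::data.table(group = character(), pt = character(),
                           r = numeric(), expected_a = numeric(),
                           realized_a = numeric())
  }
  group_sizes <- as.list(table(lab))
  manifest <- list(
    n_unique_cases = n,
    n_demo_rows = nrow(demo),
    n_duplicate_versions = sum(dup),
    n_myopathy_indications = sum(pre_myo),
    group_sizes = group_sizes,
    planted = planted_stats,
    seed = truth$seed)
  list(quarter = quarter, manifest = manifest)
}

#' Write a synthetic quarter to disk in the ingest dialect
#'
#' Runs [simulate_reports()] and writes `DEMO/DRUG/REAC/INDI/OUTC` as
#' `"$"`-delimited files plus `manifest.json` with the ground truth.
#' Output is byte-identical across runs for a fixed configuration.
#'
#' @param truth A [synthetic_truth()].
#' @param outdir Output directory (created if needed).
#' @param delim Field delimiter.
#' @return Invisibly, a list with `paths`, `manifest`, and `truth`.
#' @export
generate_faers <- function(truth, outdir, delim = "$") {
  sim <- simulate_reports(truth)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(demo = file.path(outdir, "DEMO.txt"),
             drug = file.path(outdir, "DRUG.txt"),
             reac = file.path(outdir, "REAC.txt"),
             indi = file.path(outdir, "INDI.txt"),
             outc = file.path(outdir, "OUTC.txt"))
  for (tb in names(paths)) {
    write_faers_file(sim$quarter[[tb]], paths[[tb]], delim = delim)
  }
  manifest <- sim$manifest
  manifest$planted <- as.data.frame(manifest$planted)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(paths = paths, manifest = sim$manifest, truth = truth))
}

#' Compare pipeline estimates against planted ground truth
#'
#' For every planted (group, PT) pair, tabulates the pipeline's 2x2
#' counts (report unit, matching the generative model), the ROR and
#' 2^IC point estimates against the true relative rate `r`, whether the
#' 95\% ROR interval covers `r`, and the signal decision against the
#' truth criterion (`r > 1` and expected case count at least
#' `min_cases`).
#'
#' @param store A deduplicated, group-labeled `faers_store` (the pipeline
#'   output for generated data).
#' @param manifest The generator manifest (from [simulate_reports()] or
#'   [generate_faers()]).
#' @param min_cases Case-count threshold of the signal rule.
#' @return A `data.table` with one row per planted pair: `group`, `pt`,
#'   `true_r`, `expected_a`, `a`, `ror`, `ror_low`, `ror_high`, `ic`,
#'   `ror_covers_r`, `is_signal`, `should_signal`.
#' @export
recover_parameters <- function(store, manifest, min_cases = 3L) {
  planted <- data.table::as.data.table(manifest$planted)
  if (!nrow(planted)) {
    return(data.table::data.table(
      group = character(), pt = character(), true_r = numeric(),
      expected_a = numeric(), a = integer(), ror = numeric(),
      ror_low = numeric(), ror_high = numeric(), ic = numeric(),
      ror_covers_r = logical(), is_signal = logical(),
      should_signal = logical()))
  }
  data.table::rbindlist(lapply(seq_len(nrow(planted)), function(k) {
    tab <- build_table(store, group = planted$group[k],
                       event = planted$pt[k], unit = "report")
    res <- signal_result(tab, min_cases = min_cases)
    data.table::data.table(
      group = planted$group[k], pt = planted$pt[k],
      true_r = planted$r[k], expected_a = planted$expected_a[k],
      a = res$a, ror = res$ror, ror_low = res$ror_low,
      ror_high = res$ror_high, ic = res$ic,
      ror_covers_r = res$ror_low <= planted$r[k] &
        planted$r[k] <= res$ror_high,
      is_signal = res$is_signal,
      should_signal = planted$r[k] > 1 &
        planted$expected_a[k] >= min_cases)
  }))
}
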
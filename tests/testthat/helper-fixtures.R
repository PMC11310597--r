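# Fixture builders used across the suite. Everything is constructed in
# code; no data files are read from disk except those the tests write
# themselves into tempdirs.

# Write a minimal FAERS-dialect quarter to a tempdir and return the paths.
# `demo_rows` etc. are character vectors of "$"-joined rows (no header).
write_quarter_fixture <- function(demo_rows, drug_rows = character(),
                                  reac_rows = character(),
                                  indi_rows = character(),
                                  outc_rows = character(),
                                  dir = withr::local_tempdir(
                                    .local_envir = parent.frame())) {
  hdr <- list(
    demo = "primaryid$caseid$caseversion$fda_dt$age$age_cod$sex$occp_cod$occr_country",
    drug = "primaryid$drug_seq$role_cod$drugname",
    reac = "primaryid$pt",
    indi = "primaryid$indi_pt",
    outc = "primaryid$outc_cod")
  rows <- list(demo = demo_rows, drug = drug_rows, reac = reac_rows,
               indi = indi_rows, outc = outc_rows)
  paths <- sapply(names(hdr), function(tb) {
    p <- file.path(dir, paste0(toupper(tb), ".txt"))
    writeLines(c(hdr[[tb]], rows[[tb]]), p)
    p
  })
  paths
}

# A small assembled, deduplicated store: 4 reports covering the main
# exposure patterns.
tiny_store <- function() {
  paths <- write_quarter_fixture(
    demo_rows = c(
      "11$1$1$20200101$72$YR$F$MD$US",
      "21$2$1$20210315$6$MON$M$CN$FR",
      "31$3$1$20190601$55$YR$F$$JP",
      "41$4$1$20220101$$$$$"),
    drug_rows = c(
      "11$1$PS$COLCHICINE", "11$2$PS$SIMVASTATIN 20MG TABLET",
      "21$1$PS$LIPITOR",
      "31$1$PS$SIMVASTATIN", "31$2$PS$CRESTOR",
      "41$1$PS$ASPIRIN"),
    reac_rows = c(
      "11$Rhabdomyolysis", "11$Nausea",
      "21$Nausea",
      "31$Toxic myopathy",
      "41$Headache"),
    indi_rows = c("11$Gout", "21$Hypercholesterolaemia"),
    outc_rows = c("11$HO", "11$DE", "21$OT"))
  st <- assemble_reports(read_quarter(dirname(paths[["demo"]])))
  st <- deduplicate(st)
  st <- assign_groups(st)
  classify_reports(st)
}

# Run the pipeline stages on an in-memory synthetic quarter.
pipeline_on_quarter <- function(quarter, roles = "PS") {
  st <- assemble_reports(quarter)
  st <- deduplicate(st)
  st <- exclude_preexisting(st)$store
  st <- assign_groups(st, roles = roles)
  classify_reports(st)
}

# Brute-force 2x2 counts from the raw labeled store, written without
# build_table(): per-report logical case status from the reactions table.
brute_table_counts <- function(store, group_labels, pts) {
  keys <- toupper(trimws(gsub("[[:space:]]+", " ", pts)))
  demo <- as.data.frame(store$demo)
  reac <- as.data.frame(store$reactions)
  reac_key <- toupper(trimws(gsub("[[:space:]]+", " ", reac$pt)))
  case_ids <- unique(reac$primaryid[reac_key %in% keys])
  is_case <- demo$primaryid %in% case_ids
  in_grp <- demo$group %in% group_labels
  c(a = sum(in_grp & is_case), b = sum(in_grp & !is_case),
    c = sum(!in_grp & is_case), d = sum(!in_grp & !is_case))
}
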
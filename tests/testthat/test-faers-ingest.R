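test_that("read_quarter returns verbatim rows and counts match the files", {
  paths <- write_quarter_fixture(
    demo_rows = c("11$1$1$20200101$72$YR$F$MD$US",
                  "21$2$1$20210315$30$YR$M$CN$FR"),
    drug_rows = c("11$1$PS$COLCHICINE", "99$1$PS$ASPIRIN"),
    reac_rows = c("11$Rhabdomyolysis", "21$Nausea"))
  rq <- read_quarter(dirname(paths[["demo"]]))
  expect_s3_class(rq, "raw_quarter")
  expect_equal(nrow(rq$demo), 2L)
  expect_equal(rq$demo$age, c("72", "30"))
  # orphan DRUG row (primaryid 99 absent from DEMO) is retained at read
  expect_true("99" %in% rq$drug$primaryid)
  # ... and flagged/dropped only at assembly
  st <- assemble_reports(rq)
  expect_false("99" %in% st$drugs$primaryid)
  expect_equal(st$log$n_orphan_rows, 1L)
})

test_that("malformed lines are skipped and counted, not guessed at", {
  paths <- write_quarter_fixture(
    demo_rows = c("11$1$1$20200101$72$YR$F$MD$US",
                  "21$2$1$20210315",  # truncated record
                  "31$3$1$20190601$55$YR$F$HP$JP"),
    drug_rows = "11$1$PS$COLCHICINE",
    reac_rows = c("11$Myopathy", "31$Nausea"))
  rq <- read_quarter(dirname(paths[["demo"]]))
  expect_equal(nrow(rq$demo), 2L)
  expect_equal(unname(rq$log$demo["n_skipped"]), 1L)
})

test_that("a missing mandatory column is a format error naming the file", {
  dir <- withr::local_tempdir()
  writeLines(c("primaryid$caseversion", "11$1"),
             file.path(dir, "DEMO.txt"))
  writeLines(c("primaryid$drug_seq$role_cod$drugname", "11$1$PS$X"),
             file.path(dir, "DRUG.txt"))
  writeLines(c("primaryid$pt", "11$Nausea"), file.path(dir, "REAC.txt"))
  expect_error(read_quarter(dir), "DEMO.*caseid")
})

test_that("age units convert to years and malformed demographics degrade", {
  paths <- write_quarter_fixture(
    demo_rows = c(
      "11$1$1$20200101$72$YR$F$MD$US",    # years
      "21$2$1$20200101$6$MON$M$PH$FR",    # months
      "31$3$1$20200101$2$DEC$F$OT$DE",    # unit treated as years
      "41$4$1$20200101$52$$M$CN$GB",      # no unit, plausible years
      "51$5$1$20200101$5000$$F$LW$JP",    # no unit, implausible
      "61$6$1$20200101$8766$HR$M$$XX",    # hours
      "71$7$1$20200101$abc$YR$X$ZZ$"),    # unparseable
    drug_rows = sprintf("%d1$1$PS$COLCHICINE", 1:7),
    reac_rows = sprintf("%d1$Nausea", 1:7))
  st <- assemble_reports(read_quarter(dirname(paths[["demo"]])))
  ages <- st$demo$age_years[match(sprintf("%d1", 1:7), st$demo$primaryid)]
  expect_equal(ages, c(72, 0.5, 2, 52, NA, 1, NA))
  # both the implausible unitless age and the non-numeric age degrade
  expect_equal(st$log$n_unparseable_age, 2L)
  # reporter occupation map
  reps <- st$demo$reporter[match(sprintf("%d1", 1:7), st$demo$primaryid)]
  expect_equal(reps, c("health_professional", "health_professional",
                       "health_professional", "non_health_professional",
                       "non_health_professional", "unknown", "unknown"))
  # region map, incl. unrecognized code and empty
  regs <- st$demo$region[match(sprintf("%d1", 1:7), st$demo$primaryid)]
  expect_equal(regs, c("North America", "Europe", "Europe", "Europe",
                       "Asia", "unknown", "unknown"))
})

test_that("reports without any reaction row are dropped and logged", {
  paths <- write_quarter_fixture(
    demo_rows = c("11$1$1$20200101$70$YR$F$MD$US",
                  "21$2$1$20200101$60$YR$M$MD$US"),
    drug_rows = c("11$1$PS$COLCHICINE", "21$1$PS$COLCHICINE"),
    reac_rows = "11$Nausea")
  st <- assemble_reports(read_quarter(dirname(paths[["demo"]])))
  expect_equal(st$demo$primaryid, "11")
  expect_equal(st$log$n_no_event, 1L)
})

test_that("deduplication keeps the policy-selected version of each case", {
  paths <- write_quarter_fixture(
    demo_rows = c("111$100$1$20200101$70$YR$F$MD$US",
                  "112$100$2$20190101$70$YR$F$MD$US",  # later version, earlier receipt
                  "211$200$1$20200601$60$YR$M$MD$US",
                  "212$200$1$20210601$60$YR$M$MD$US"), # same version, later receipt
    drug_rows = c("111$1$PS$COLCHICINE", "112$1$PS$COLCHICINE",
                  "211$1$PS$ZOCOR", "212$1$PS$ZOCOR"),
    reac_rows = c("111$Nausea", "112$Nausea", "211$Myopathy",
                  "212$Myopathy"))
  st <- assemble_reports(read_quarter(dirname(paths[["demo"]])))

  kept <- deduplicate(st)
  expect_equal(kept$demo$primaryid, c("112", "212"))
  # latest_receipt_only ignores caseversion
  kept2 <- deduplicate(st, dedup_policy(keep_rule = "latest_receipt_only"))
  expect_equal(kept2$demo$primaryid, c("111", "212"))
  # deleted-case list removes the whole case
  kept3 <- deduplicate(st, dedup_policy(deleted_case_ids = "100"))
  expect_equal(kept3$demo$caseid, "200")
  # child tables follow the surviving reports
  expect_true(all(kept$reactions$primaryid %in% kept$demo$primaryid))
})

test_that("deduplication is idempotent and input-order-insensitive", {
  truth <- synthetic_truth(n_reports = 300, duplicate_rate = 0.2, seed = 42)
  sim <- simulate_reports(truth)
  st <- assemble_reports(sim$quarter)
  once <- deduplicate(st)
  twice <- deduplicate(once)
  expect_equal(twice$demo, once$demo)
  expect_equal(nrow(once$demo), sim$manifest$n_unique_cases)
  # permute input rows: surviving set unchanged
  perm <- st
  set.seed(1)
  perm$demo <- perm$demo[sample(.N)]
  expect_equal(deduplicate(perm)$demo, once$demo)
})

test_that("assemble -> write -> read round-trips a synthetic store", {
  truth <- synthetic_truth(n_reports = 500, seed = 9)
  dir <- withr::local_tempdir()
  gen <- generate_faers(truth, dir)
  rq <- read_quarter(dir)
  expect_equal(nrow(rq$demo), gen$manifest$n_demo_rows)
  st <- deduplicate(assemble_reports(rq))
  expect_equal(nrow(st$demo), 500L)

  store_dir <- withr::local_tempdir()
  write_store(st, store_dir)
  back <- read_store(store_dir)
  expect_equal(as.data.frame(back$demo), as.data.frame(st$demo))
  expect_equal(as.data.frame(back$reactions), as.data.frame(st$reactions))
  expect_equal(as.data.frame(back$drugs), as.data.frame(st$drugs))
})
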
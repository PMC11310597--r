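# Frozen expected values below were computed from the closed-form
# definitions (log-scale Wald interval for the ROR; shrunk log2
# observed/expected with the credible-interval approximation for the IC)
# evaluated independently of the implementation.

test_that("ROR point estimate and Wald interval match closed-form values", {
  r1 <- ror(contingency_table(10, 90, 100, 900))
  expect_equal(r1$ror, 1)
  expect_equal(r1$ror_low, 0.503984790123, tolerance = 1e-9)
  expect_equal(r1$ror_high, 1.98418686357, tolerance = 1e-9)
  expect_false(r1$haldane_applied)

  r2 <- ror(contingency_table(100, 900, 9900, 989100))
  expect_equal(r2$ror, 11.101010101, tolerance = 1e-9)
  expect_equal(r2$ror_low, 9.02042494773, tolerance = 1e-9)
  expect_equal(r2$ror_high, 13.6614877876, tolerance = 1e-9)
})

test_that("swapping exposure and background rows reciprocates the ROR", {
  set.seed(21)
  for (i in 1:20) {
    cells <- sample(1:500, 4)
    t1 <- contingency_table(cells[1], cells[2], cells[3], cells[4])
    t2 <- contingency_table(cells[3], cells[4], cells[1], cells[2])
    expect_equal(ror(t1)$ror, 1 / ror(t2)$ror, tolerance = 1e-12)
  }
})

test_that("zero cells trigger the Haldane correction (or an error if off)", {
  tab <- contingency_table(0, 100, 40, 1860)
  r <- ror(tab)
  expect_true(r$haldane_applied)
  expect_equal(r$ror, (0.5 * 1860.5) / (100.5 * 40.5), tolerance = 1e-12)
  expect_error(ror(tab, haldane = FALSE), "zero cell")
  # correction is not applied silently when all cells are positive
  expect_false(ror(contingency_table(1, 1, 1, 1))$haldane_applied)
})

test_that("IC equals the shrunk log2 observed-to-expected ratio", {
  # independence: a = E gives IC = 0 exactly
  i0 <- ic(contingency_table(10, 90, 90, 810))
  expect_equal(i0$expected, 10)
  expect_equal(i0$ic, 0)

  i1 <- ic(contingency_table(100, 900, 9900, 989100))
  expect_equal(i1$expected, 10)
  expect_equal(i1$ic, 3.2587342684, tolerance = 1e-9)
  expect_equal(i1$ic_low, 2.92757109428, tolerance = 1e-9)
  expect_equal(i1$ic_high, 3.49764023576, tolerance = 1e-9)

  # a = 0 is forced negative by the formula, not an error
  i2 <- ic(contingency_table(0, 100, 40, 1860))
  expect_equal(i2$expected, 2)
  expect_equal(i2$ic, log2(0.5 / 2.5))
})

test_that("the Bate-variance interval is a valid alternative", {
  tab <- contingency_table(100, 900, 9900, 989100)
  ib <- ic(tab, method = "bate_variance")
  expect_equal(ib$ic, ic(tab)$ic)  # same point estimate
  expect_lt(ib$ic_low, ib$ic)
  expect_gt(ib$ic_high, ib$ic)
  # variance shrinks with information: larger a gives a tighter interval
  ib2 <- ic(contingency_table(1000, 9000, 99000, 9891000),
            method = "bate_variance")
  expect_lt(ib2$ic_high - ib2$ic_low, ib$ic_high - ib$ic_low)
})

test_that("ROR and IC increase strictly in a with b, c, d fixed", {
  rors <- sapply(1:30, function(a)
    ror(contingency_table(a, 500, 300, 5000))$ror)
  ics <- sapply(1:30, function(a)
    ic(contingency_table(a, 500, 300, 5000))$ic)
  expect_true(all(diff(rors) > 0))
  expect_true(all(diff(ics) > 0))
})

test_that("the joint signal rule needs count, ROR bound and IC bound", {
  expect_true(evaluate_signal(3, ror_low = 1.2, ic_low = 0.1))
  expect_false(evaluate_signal(2, ror_low = 5.0, ic_low = 2.0))
  expect_false(evaluate_signal(50, ror_low = 0.9, ic_low = 0.2))
  expect_false(evaluate_signal(50, ror_low = 1.5, ic_low = -0.1))
})

test_that("build_table counts the store directly", {
  # construct a store with known composition: group X with 10 cases /
  # 90 non-cases, rest of store 100 / 900
  n <- 1100
  pid <- as.character(seq_len(n))
  demo <- data.table::data.table(
    primaryid = pid, caseid = pid, caseversion = 1L,
    receipt_date = 20200101L, age_years = 60, sex = "female",
    reporter = "unknown", region = "unknown",
    group = rep(c("statin:simvastatin", "other"), c(100, 1000)))
  is_case <- rep(c(TRUE, FALSE, TRUE, FALSE), c(10, 90, 100, 900))
  reac <- data.table::data.table(
    primaryid = pid, pt = ifelse(is_case, "Rhabdomyolysis", "Nausea"))
  store <- structure(list(demo = demo, drugs = data.table::data.table(),
                          reactions = reac,
                          indications = data.table::data.table(),
                          outcomes = data.table::data.table(), log = list()),
                     class = "faers_store")
  tab <- build_table(store, "statin:simvastatin", smq_terms())
  expect_equal(c(tab$a, tab$b, tab$c, tab$d), c(10, 90, 100, 900))

  # explicit background replaces c and d
  tab2 <- build_table(store, "statin:simvastatin", smq_terms(),
                      comparator = "explicit",
                      background = c(18847, 992746))
  expect_equal(c(tab2$c, tab2$d), c(18847, 992746))

  # a group with zero cases is a valid a = 0 table, not an error
  demo2 <- data.table::copy(demo)[group == "statin:simvastatin" &
                                    is_case, group := "other"]
  store2 <- store; store2$demo <- demo2
  tab3 <- build_table(store2, "statin:simvastatin", smq_terms())
  expect_equal(tab3$a, 0)
  # an empty index group is an error
  expect_error(build_table(store, "colchicine", smq_terms()),
               "no exposed reports")
})

test_that("module ROR/IC equal brute-force recomputation on a large store", {
  truth <- synthetic_truth(n_reports = 10000, seed = 13)
  st <- pipeline_on_quarter(simulate_reports(truth)$quarter)
  terms <- smq_terms()
  groups <- list("colchicine", "statin:simvastatin",
                 c(paste0("colchicine+statin:", c("simvastatin",
                                                  "atorvastatin"))))
  for (g in groups) {
    cnt <- brute_table_counts(st, g, terms$preferred_terms)
    tab <- build_table(st, g, terms)
    expect_identical(c(a = tab$a, b = tab$b, c = tab$c, d = tab$d), cnt)
    # brute-force sample odds ratio (with the same zero-cell handling)
    cc <- if (any(cnt == 0)) cnt + 0.5 else cnt
    expect_equal(ror(tab)$ror, (cc["a"] * cc["d"]) / (cc["b"] * cc["c"]),
                 ignore_attr = TRUE, tolerance = 1e-12)
    e <- (cnt["a"] + cnt["b"]) * (cnt["a"] + cnt["c"]) / sum(cnt)
    expect_equal(ic(tab)$ic, log2((cnt["a"] + 0.5) / (e + 0.5)),
                 ignore_attr = TRUE, tolerance = 1e-12)
  }
})
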
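test_that("a fixed seed reproduces generated files byte for byte", {
  truth <- synthetic_truth(n_reports = 400, seed = 17)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  g1 <- generate_faers(truth, d1)
  g2 <- generate_faers(truth, d2)
  for (tb in names(g1$paths)) {
    expect_identical(readLines(g1$paths[[tb]]), readLines(g2$paths[[tb]]))
  }
  expect_identical(g1$manifest, g2$manifest)
  # a different seed produces different data
  g3 <- generate_faers(synthetic_truth(n_reports = 400, seed = 18),
                       withr::local_tempdir())
  expect_false(identical(readLines(g1$paths[["reac"]]),
                         readLines(g3$paths[["reac"]])))
})

test_that("dedup recovers exactly the manifest's unique case count", {
  truth <- synthetic_truth(n_reports = 1000, duplicate_rate = 0.1,
                           seed = 23)
  sim <- simulate_reports(truth)
  expect_equal(sim$manifest$n_demo_rows,
               1000L + sim$manifest$n_duplicate_versions)
  st <- deduplicate(assemble_reports(sim$quarter))
  expect_equal(nrow(st$demo), sim$manifest$n_unique_cases)
  expect_true(all(st$demo$caseversion[st$demo$caseid %in%
    sim$quarter$demo[caseversion == "2", caseid]] == 2L))
})

test_that("generated demographic marginals track the configured ones", {
  n <- 10000
  truth <- synthetic_truth(n_reports = n, seed = 29)
  sim <- simulate_reports(truth)
  st <- deduplicate(assemble_reports(sim$quarter))
  # categorical marginals within 3 binomial standard errors
  for (mar in list(list(col = "sex", probs = truth$sex_probs),
                   list(col = "reporter", probs = truth$reporter_probs),
                   list(col = "region", probs = truth$region_probs))) {
    obs <- table(st$demo[[mar$col]])[names(mar$probs)]
    for (k in names(mar$probs)) {
      p <- mar$probs[[k]]
      se <- sqrt(p * (1 - p) / n)
      expect_lt(abs(obs[[k]] / n - p), 3 * se + 1e-9)
    }
  }
  # exposure mix recovered through the pipeline's own group assignment
  st <- assign_groups(st)
  p_combo <- sum(truth$exposure_probs[startsWith(
    names(truth$exposure_probs), "colchicine+")])
  obs_combo <- mean(startsWith(st$demo$group, "colchicine+"))
  expect_lt(abs(obs_combo - p_combo),
            3 * sqrt(p_combo * (1 - p_combo) / n))
})

test_that("a null store (r = 1 everywhere) shows no planted excess", {
  truth <- synthetic_truth(
    n_reports = 10000, duplicate_rate = 0,
    planted_associations = data.frame(
      group = "colchicine", pt = "Rhabdomyolysis", r = 1),
    seed = 31)
  sim <- simulate_reports(truth)
  st <- pipeline_on_quarter(sim$quarter)
  rc <- recover_parameters(st, sim$manifest)
  expect_equal(nrow(rc), 1L)
  expect_false(rc$should_signal)
  expect_true(rc$ror_low < 1.5 & rc$ror_high > 0.7)  # near-null estimate
})

test_that("an empty planted set yields an empty recovery report", {
  truth <- synthetic_truth(
    n_reports = 200, seed = 2,
    planted_associations = data.frame(group = character(),
                                      pt = character(), r = numeric()))
  sim <- simulate_reports(truth)
  st <- pipeline_on_quarter(sim$quarter)
  rc <- recover_parameters(st, sim$manifest)
  expect_equal(nrow(rc), 0L)
})

test_that("manifest expected counts are the model's arithmetic", {
  truth <- synthetic_truth(n_reports = 5000, seed = 37)
  sim <- simulate_reports(truth)
  pl <- sim$manifest$planted
  p0 <- truth$background_event_prob
  for (k in seq_len(nrow(pl))) {
    p_eff <- min(1, pl$r[k] * p0[[pl$pt[k]]])
    expect_equal(pl$expected_a[k],
                 5000 * truth$exposure_probs[[pl$group[k]]] * p_eff)
  }
  # realized counts are within 5 standard deviations of expectation
  expect_true(all(abs(pl$realized_a - pl$expected_a) <
                    5 * sqrt(pmax(pl$expected_a, 1))))
})
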
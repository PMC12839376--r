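test_that("generation is deterministic given a seed", {
  cfg <- generator_config(seed = 99, n_patients = 30, n_drugs = 25)
  b1 <- generate_bundle(cfg)
  b2 <- generate_bundle(cfg)
  expect_identical(b1, b2)
  b3 <- generate_bundle(generator_config(seed = 100, n_patients = 30,
                                         n_drugs = 25))
  expect_false(identical(b1$cohort$patients, b3$cohort$patients))
})

test_that("degenerate configurations behave as specified", {
  # all-major severity mix: every KB record and every event is major
  b <- generate_bundle(generator_config(
    seed = 2, n_patients = 20, n_drugs = 20,
    severity_mix = c(minor = 0, moderate = 0, major = 1, unknown = 0)))
  expect_true(all(b$kb$records$severity == "major"))
  pr <- profile_cohort(b$cohort, b$kb)
  expect_true(all(pr$interactions$severity == "major"))

  # no interactions at all
  b0 <- generate_bundle(generator_config(seed = 2, n_patients = 20,
                                         n_drugs = 20,
                                         interaction_density = 0))
  expect_equal(nrow(b0$kb$records), 0)
  s0 <- summarize_cohort(profile_cohort(b0$cohort, b0$kb))
  expect_equal(s0$prevalence_any$pct, 0)

  # all-male cohort recovers the fraction exactly
  bm <- generate_bundle(generator_config(seed = 3, n_patients = 25,
                                         n_drugs = 20, pct_male = 100))
  expect_true(all(bm$cohort$patients$sex == "male"))

  expect_error(generator_config(n_drugs = 10, med_range = c(1L, 16L)),
               "infeasible")
})

test_that("generated marginals respect the configured models", {
  b <- generate_bundle(generator_config(seed = 11))
  p <- b$cohort$patients
  nmed <- lengths(p$medications)
  expect_true(all(nmed >= 1 & nmed <= 16))
  expect_true(all(p$age >= 18 & p$age <= 100))
  expect_true(all(vapply(p$medications,
                         function(m) !anyDuplicated(m), logical(1))))
  # medications are drawn from the formulary without replacement
  expect_true(all(unlist(p$medications) %in%
                    c(ddinet:::FORMULARY[1:110])))
})

test_that("knowledge-base severity mix stays within 3-sigma multinomial bands", {
  # large formulary with uniform fabric to accumulate ~10k records
  b <- generate_bundle(generator_config(
    seed = 5, n_patients = 1, n_drugs = 210, med_range = c(1L, 2L),
    mean_medications = 2, interaction_density = 0.5, hub_affinity = 0))
  recs <- b$kb$records
  expect_gt(nrow(recs), 5000)
  probs <- c(minor = 0.44, moderate = 0.44, major = 0.12)
  for (sv in names(probs)) {
    phat <- mean(recs$severity == sv)
    band <- 3 * sqrt(probs[[sv]] * (1 - probs[[sv]]) / nrow(recs))
    expect_lt(abs(phat - probs[[sv]]), band)
  }
})

test_that("parameter recovery reproduces the generating marginals", {
  b <- generate_bundle(generator_config(seed = 0))
  rec <- parameter_recovery_report(b)
  get <- function(p) rec$recovered[rec$parameter == p]
  # CLT bound: 3 standard errors at n = 250 with the model sd ~2.73
  expect_lt(abs(get("mean_medications") - 7.7), 3 * 2.73 / sqrt(250))
  expect_lt(abs(get("pct_male") - 55.6), 3 * 100 * sqrt(0.556 * 0.444 / 250))
  expect_lt(abs(get("age_mean") - 68.3), 3 * 12.8 / sqrt(250))
})

test_that("default bundles reproduce the emergent cohort structure", {
  for (seed in c(101, 202)) {
    b <- generate_bundle(generator_config(seed = seed))
    pr <- profile_cohort(b$cohort, b$kb)
    s <- summarize_cohort(pr)
    # near-universal interaction prevalence and combinatorial scaling
    expect_gte(s$prevalence_any$pct, 90)
    expect_gt(s$correlation_meds_vs_total$r, 0.9)
    # hub-dominated, right-skewed degree distribution
    g <- suppressMessages(build_network(pr))
    deg <- colSums(adjmat(g))
    expect_gt(max(deg), 2 * mean(deg))
    # dense core against a sparse full network
    expect_gt(graph_density(top_k_subgraph(g, 25)), graph_density(g))
  }
})

test_that("bundle files round-trip through the standard readers", {
  b <- generate_bundle(generator_config(seed = 8, n_patients = 20,
                                        n_drugs = 20))
  dir <- tempfile()
  paths <- write_bundle(b, dir)
  co <- suppressMessages(suppressWarnings(
    load_cohort(paths[["cohort"]], min_medications = 1)))
  expect_identical(co$patients, b$cohort$patients)
  kb <- suppressMessages(load_knowledge_base(paths[["kb"]]))
  expect_identical(kb$records, b$kb$records)
  truth <- jsonlite::read_json(paths[["truth"]])
  expect_equal(truth$seed, 8)
})
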
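test_that("Clopper-Pearson interval matches binomial-tail bisection and handles boundaries", {
  expect_equal(unname(clopper_pearson(0, 10)["ci_low"]), 0)
  expect_equal(unname(clopper_pearson(10, 10)["ci_high"]), 100)
  ci5 <- clopper_pearson(5, 10)
  expect_lt(ci5["ci_low"], 50)
  expect_gt(ci5["ci_high"], 50)
  expect_error(clopper_pearson(1, 0), "n must be >= 1")

  # independent oracle: invert the exact binomial tail probabilities by
  # bisection (uniroot on pbinom), the defining property of the interval
  set.seed(3)
  for (rep in 1:30) {
    n <- sample(1:300, 1)
    x <- sample(0:n, 1)
    ci <- clopper_pearson(x, n) / 100
    if (x > 0) {
      lo <- uniroot(function(p) 1 - pbinom(x - 1, n, p) - 0.025,
                    c(1e-12, 1 - 1e-12), tol = 1e-12)$root
      expect_equal(unname(ci["ci_low"]), lo, tolerance = 1e-9)
    }
    if (x < n) {
      hi <- uniroot(function(p) pbinom(x, n, p) - 0.025,
                    c(1e-12, 1 - 1e-12), tol = 1e-12)$root
      expect_equal(unname(ci["ci_high"]), hi, tolerance = 1e-9)
    }
    expect_lte(ci["ci_low"], x / n + 1e-12)
    expect_gte(ci["ci_high"], x / n - 1e-12)
  }
})

test_that("Pearson correlation matches the product-moment formula and guards constants", {
  expect_equal(pearson_r(1:3, c(2, 4, 6))$r, 1)
  expect_equal(pearson_r(1:3, c(6, 4, 2))$r, -1)
  expect_warning(out <- pearson_r(1:5, rep(2, 5)), "constant input")
  expect_true(is.na(out$r))
  set.seed(4)
  x <- rnorm(100); y <- 0.4 * x + rnorm(100)
  manual <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson_r(x, y)$r, manual, tolerance = 1e-12)
})

test_that("cohort summary counts prevalence, severity and risk strata correctly", {
  kb <- knowledge_base(data.frame(
    drug_a = c("a", "a", "b", "c", "d"),
    drug_b = c("b", "c", "c", "d", "e"),
    severity = c("major", "minor", "major", "major", "moderate")))
  pats <- data.frame(
    patient_id = c("P1", "P2", "P3"), age = c(70L, 55L, 81L),
    sex = c("male", "female", "male"), residence = "rural",
    diagnosis = "hf", stringsAsFactors = FALSE)
  pats$medications <- list("x", c("a", "b"), c("a", "b", "c", "d", "e"))
  co <- new_cohort(pats)
  pr <- profile_cohort(co, kb)
  # totals: P1 0; P2 1 (major); P3 5 (3 major, 1 minor, 1 moderate)
  expect_equal(pr$profiles$total_interactions, c(0, 1, 5))
  s <- summarize_cohort(pr)
  expect_equal(s$prevalence_any$successes, 2)
  expect_equal(s$prevalence_any_major$successes, 2)
  expect_equal(s$risk_distribution$count, c(1, 1, 1))
  expect_equal(s$total_interactions, 6)
  expect_equal(sum(s$severity_distribution$pct), 100, tolerance = 0.1)
  expect_equal(s$severity_distribution$count[
    s$severity_distribution$severity == "major"], 4)

  # degenerate: nobody interacts
  empty_kb <- knowledge_base(data.frame(drug_a = character(0),
                                        drug_b = character(0),
                                        severity = character(0)))
  s0 <- summarize_cohort(profile_cohort(co, empty_kb))
  expect_equal(s0$prevalence_any$successes, 0)
  expect_equal(s0$prevalence_any$pct, 0)
  expect_true(all(s0$severity_distribution$count == 0))
})

test_that("cohort totals equal an independent recount from the long-format table", {
  b <- generate_bundle(generator_config(seed = 5, n_patients = 50,
                                        n_drugs = 30))
  pr <- profile_cohort(b$cohort, b$kb)
  s <- summarize_cohort(pr)
  long <- pr$interactions
  expect_equal(s$total_interactions, nrow(long))
  for (sv in c("minor", "moderate", "major")) {
    expect_equal(
      s$severity_distribution$count[s$severity_distribution$severity == sv],
      sum(long$severity == sv))
  }
  recount <- table(factor(long$patient_id,
                          levels = pr$profiles$patient_id))
  expect_equal(unname(as.integer(recount)), pr$profiles$total_interactions)
})

test_that("drug frequency table counts both pair positions and ranks deterministically", {
  inter <- data.frame(patient_id = c("P1", "P1"),
                      drug_a = c("a", "a"), drug_b = c("b", "c"),
                      severity = c("major", "minor"))
  ft <- drug_frequency_table(inter)
  expect_identical(ft$drug, c("a", "b", "c"))
  expect_identical(ft$count, c(2L, 1L, 1L))
  expect_equal(sum(ft$count), 2 * nrow(inter))
  expect_equal(nrow(drug_frequency_table(inter[0, ])), 0)

  b <- generate_bundle(generator_config(seed = 9, n_patients = 40,
                                        n_drugs = 25))
  pr <- profile_cohort(b$cohort, b$kb)
  ft2 <- drug_frequency_table(pr$interactions, b$cohort)
  expect_equal(sum(ft2$count), 2 * nrow(pr$interactions))
  # top-1 equals a brute-force recount argmax
  brute <- sort(table(c(pr$interactions$drug_a, pr$interactions$drug_b)),
                decreasing = TRUE)
  expect_equal(ft2$count[1], as.integer(brute[1]))
  expect_equal(ft2$male + ft2$female, ft2$count)
  expect_true(all(is.na(ft2$mf_ratio) | ft2$female > 0))
})

test_that("pair frequency table counts patients per canonical pair", {
  inter <- data.frame(patient_id = c("P1", "P2", "P2"),
                      drug_a = c("a", "a", "b"), drug_b = c("b", "b", "c"),
                      severity = c("major", "major", "minor"))
  pt <- pair_frequency_table(inter)
  expect_equal(nrow(pt), 2)
  expect_equal(pt$count[pt$drug_a == "a"], 2)
  expect_equal(pt$count[pt$drug_a == "b"], 1)
  one_each <- data.frame(patient_id = c("P1", "P2"),
                         drug_a = c("a", "c"), drug_b = c("b", "d"),
                         severity = "minor")
  expect_true(all(pair_frequency_table(one_each)$count == 1))
})

test_that("severity crosstab keeps the top drugs with consistent row sums", {
  b <- generate_bundle(generator_config(seed = 13, n_patients = 40,
                                        n_drugs = 30))
  pr <- profile_cohort(b$cohort, b$kb)
  ct <- drug_severity_crosstab(pr$interactions, top = 10)
  expect_lte(nrow(ct), 10)
  expect_equal(ct$total, ct$minor + ct$moderate + ct$major + ct$unknown)
  freq <- drug_frequency_table(pr$interactions)
  expect_identical(ct$drug, head(freq$drug, nrow(ct)))
  expect_equal(ct$total, head(freq$count, nrow(ct)))
})

test_that("stratified summaries re-aggregate exactly to cohort totals", {
  b <- generate_bundle(generator_config(seed = 21, n_patients = 60,
                                        n_drugs = 40))
  pr <- profile_cohort(b$cohort, b$kb)
  s <- summarize_cohort(pr)
  for (by in c("sex", "age_group", "both")) {
    strata <- stratify_cohort(pr, b$cohort, by = by)
    expect_equal(sum(vapply(strata, `[[`, numeric(1), "n_patients")),
                 s$n_patients)
    expect_equal(sum(vapply(strata, `[[`, numeric(1), "total_interactions")),
                 s$total_interactions)
    maj <- vapply(strata, function(st)
      st$severity_distribution$count[
        st$severity_distribution$severity == "major"], numeric(1))
    expect_equal(sum(maj), s$severity_distribution$count[
      s$severity_distribution$severity == "major"])
  }
  # single-stratum cohort: stratum summary equals cohort summary
  male_ids <- b$cohort$patients$patient_id[b$cohort$patients$sex == "male"]
  keep <- pr$profiles$patient_id %in% male_ids
  sub <- structure(list(
    profiles = pr$profiles[keep, ],
    interactions = pr$interactions[pr$interactions$patient_id %in% male_ids, ]),
    class = "ddi_profiles")
  one <- stratify_cohort(sub, b$cohort, by = "sex")
  expect_equal(names(one), "male")
  expect_equal(one$male$total_interactions,
               summarize_cohort(sub)$total_interactions)
})
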
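# Cohort-level descriptive surface: severity distribution, prevalence with
# exact confidence intervals, risk/burden strata, frequency tables, Pearson
# correlations and sex/age stratifications. Percentages are kept at full
# precision internally; rounding to 1 decimal place happens only in file
# exports and printing.

#' Clopper-Pearson exact binomial confidence interval
#'
#' Exact (Beta-quantile) interval for a binomial proportion, returned as
#' percentages. `successes = 0` gives a lower bound of exactly 0 and
#' `successes = n` an upper bound of exactly 100.
#'
#' @param successes Number of successes (0 <= successes <= n).
#' @param n Number of trials (>= 1).
#' @param level Confidence level (default 0.95).
#' @return Named numeric vector `c(ci_low, ci_high)` in percent.
#' @examples
#' clopper_pearson(246, 250)
#' @export
clopper_pearson <- function(successes, n, level = 0.95) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  stopifnot(successes >= 0, successes <= n, level > 0, level < 1)
  alpha <- 1 - level
  low <- if (successes == 0) 0 else
    stats::qbeta(alpha / 2, successes, n - successes + 1)
  high <- if (successes == n) 1 else
    stats::qbeta(1 - alpha / 2, successes + 1, n - successes)
  c(ci_low = 100 * low, ci_high = 100 * high)
}

#' Proportion estimate with exact confidence interval
#'
#' @param successes,n,level As in [clopper_pearson()].
#' @return List of class `proportion_estimate` with `successes`, `n`, `pct`,
#'   `ci_low`, `ci_high`, `level` (percent scale).
#' @export
proportion_estimate <- function(successes, n, level = 0.95) {
  ci <- clopper_pearson(successes, n, level)
  structure(list(successes = successes, n = n, pct = 100 * successes / n,
                 ci_low = unname(ci["ci_low"]), ci_high = unname(ci["ci_high"]),
                 level = level),
            class = "proportion_estimate")
}

#' @export
print.proportion_estimate <- function(x, ...) {
  cat(sprintf("%d/%d = %.1f%% (%d%% CI %.1f-%.1f, Clopper-Pearson exact)\n",
              x$successes, x$n, x$pct, round(100 * x$level),
              x$ci_low, x$ci_high))
  invisible(x)
}

#' Pearson product-moment correlation
#'
#' Thin wrapper around [stats::cor()] that reports an absent result (`NA`)
#' with a warning when either variable is constant, rather than `NaN`.
#'
#' @param x,y Numeric vectors of equal length >= 2.
#' @return List with `r` (coefficient or `NA`) and `n`.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant input: Pearson correlation undefined", call. = FALSE)
    return(list(r = NA_real_, n = length(x)))
  }
  list(r = stats::cor(x, y, method = "pearson"), n = length(x))
}

count_pct_table <- function(f, total = length(f)) {
  tab <- table(f)
  data.frame(category = names(tab), count = as.integer(tab),
             pct = if (total > 0) 100 * as.integer(tab) / total else
               rep(NA_real_, length(tab)),
             stringsAsFactors = FALSE)
}

#' Summarize a profiled cohort
#'
#' Aggregates per-patient profiles into the cohort-level descriptive
#' surface: event-level severity distribution, prevalence of any / any-major
#' interaction with exact CIs, risk and burden distributions, per-patient
#' summary statistics, and the medication-count vs interaction-burden and
#' total vs major correlations.
#'
#' @param profiles A `ddi_profiles` object from [profile_cohort()].
#' @param level Confidence level for prevalence intervals.
#' @return List of class `ddi_cohort_summary`.
#' @export
summarize_cohort <- function(profiles, level = 0.95) {
  stopifnot(inherits(profiles, "ddi_profiles"))
  pr <- profiles$profiles
  n <- nrow(pr)
  if (n < 1) stop("at least one profile required", call. = FALSE)
  total_events <- sum(pr$total_interactions)
  sev_counts <- c(minor = sum(pr$n_minor), moderate = sum(pr$n_moderate),
                  major = sum(pr$n_major), unknown = sum(pr$n_unknown))
  severity_distribution <- data.frame(
    severity = names(sev_counts), count = as.integer(sev_counts),
    pct = if (total_events > 0) 100 * sev_counts / total_events else
      rep(NA_real_, 4),
    row.names = NULL, stringsAsFactors = FALSE)
  prevalence_by_severity <- list(
    minor = proportion_estimate(sum(pr$n_minor > 0), n, level),
    moderate = proportion_estimate(sum(pr$n_moderate > 0), n, level),
    major = proportion_estimate(sum(pr$n_major > 0), n, level),
    unknown = proportion_estimate(sum(pr$n_unknown > 0), n, level))
  per_patient <- data.frame(
    measure = c("total_interactions", "major_interactions",
                "minor_interactions", "moderate_interactions"),
    mean = c(mean(pr$total_interactions), mean(pr$n_major),
             mean(pr$n_minor), mean(pr$n_moderate)),
    median = c(stats::median(pr$total_interactions), stats::median(pr$n_major),
               stats::median(pr$n_minor), stats::median(pr$n_moderate)),
    max = c(max(pr$total_interactions), max(pr$n_major),
            max(pr$n_minor), max(pr$n_moderate)),
    stringsAsFactors = FALSE)
  corr_meds <- if (n >= 2) suppressWarnings(
    pearson_r(pr$n_medications, pr$total_interactions)) else
      list(r = NA_real_, n = n)
  corr_major <- if (n >= 2) suppressWarnings(
    pearson_r(pr$total_interactions, pr$n_major)) else
      list(r = NA_real_, n = n)
  structure(list(
    n_patients = n,
    total_interactions = total_events,
    severity_distribution = severity_distribution,
    prevalence_any = proportion_estimate(sum(pr$total_interactions > 0), n,
                                         level),
    prevalence_any_major = proportion_estimate(sum(pr$n_major > 0), n, level),
    prevalence_by_severity = prevalence_by_severity,
    risk_distribution = count_pct_table(
      risk_category(pr$n_major)),
    medication_burden_distribution = count_pct_table(
      medication_burden_category(pr$n_medications)),
    interaction_burden_distribution = count_pct_table(
      interaction_burden_category(pr$total_interactions)),
    per_patient = per_patient,
    mean_major_pct_of_total = mean(pr$major_pct_of_total, na.rm = TRUE),
    correlation_meds_vs_total = corr_meds,
    correlation_total_vs_major = corr_major),
    class = "ddi_cohort_summary")
}

#' Per-drug interaction frequency table
#'
#' Counts how often each drug appears in the long-format interaction table
#' (both pair positions), so the counts sum to exactly twice the number of
#' interaction events. Ranked by count descending, ties broken
#' lexicographically. When `cohort` is supplied, per-drug sex strata and the
#' male/female count ratio are added (`NA`, not infinity, when the female
#' count is zero).
#'
#' @param interactions Long-format data frame (`patient_id`, `drug_a`,
#'   `drug_b`, `severity`).
#' @param cohort Optional `ddi_cohort` supplying `sex` per patient.
#' @return Data frame with columns `drug`, `count` (and `male`, `female`,
#'   `mf_ratio` when stratified).
#' @export
drug_frequency_table <- function(interactions, cohort = NULL) {
  if (nrow(interactions) == 0) {
    return(data.frame(drug = character(0), count = integer(0)))
  }
  drugs <- c(interactions$drug_a, interactions$drug_b)
  tab <- table(drugs)
  out <- data.frame(drug = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  if (!is.null(cohort)) {
    sex <- cohort$patients$sex[match(interactions$patient_id,
                                     cohort$patients$patient_id)]
    sex2 <- rep(sex, 2)
    male <- table(factor(drugs[sex2 == "male"], levels = out$drug))
    female <- table(factor(drugs[sex2 == "female"], levels = out$drug))
    out$male <- as.integer(male)
    out$female <- as.integer(female)
    out$mf_ratio <- ifelse(out$female > 0, out$male / out$female, NA_real_)
  }
  out <- out[order(-out$count, out$drug), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-pair interaction frequency table
#'
#' One row per distinct canonical drug pair; the count is the number of
#' patients exhibiting that pair. Ranked by count descending, ties broken
#' lexicographically on the pair.
#'
#' @param interactions Long-format interaction data frame.
#' @return Data frame with `drug_a`, `drug_b`, `severity`, `count`.
#' @export
pair_frequency_table <- function(interactions) {
  if (nrow(interactions) == 0) {
    return(data.frame(drug_a = character(0), drug_b = character(0),
                      severity = character(0), count = integer(0)))
  }
  op <- order_pair(canonicalize_drug(interactions$drug_a),
                   canonicalize_drug(interactions$drug_b))
  key <- pair_key(op$drug_a, op$drug_b)
  first <- !duplicated(key)
  out <- data.frame(drug_a = op$drug_a[first],
                    drug_b = op$drug_b[first],
                    severity = interactions$severity[first],
                    count = as.integer(table(key)[key[first]]),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$drug_a, out$drug_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Severity cross-tabulation for the most interaction-prone drugs
#'
#' Selects the `top` drugs by total interaction count (lexicographic
#' tie-break) and cross-tabulates their interaction events by severity,
#' with row percentages.
#'
#' @param interactions Long-format interaction data frame.
#' @param top Number of drugs to keep (default 15).
#' @return Data frame: `drug`, one count column per severity, `total`, and
#'   matching `pct_*` columns.
#' @export
drug_severity_crosstab <- function(interactions, top = 15) {
  freq <- drug_frequency_table(interactions)
  keep <- utils::head(freq$drug, top)
  if (length(keep) == 0) {
    return(data.frame(drug = character(0)))
  }
  long <- rbind(
    data.frame(drug = interactions$drug_a, severity = interactions$severity),
    data.frame(drug = interactions$drug_b, severity = interactions$severity))
  long <- long[long$drug %in% keep, , drop = FALSE]
  tab <- table(factor(long$drug, levels = keep),
               factor(long$severity, levels = SEVERITY_LABELS))
  out <- data.frame(drug = keep, as.data.frame.matrix(tab),
                    stringsAsFactors = FALSE)
  out$total <- rowSums(tab)
  for (s in SEVERITY_LABELS) {
    out[[paste0("pct_", s)]] <- ifelse(out$total > 0,
                                       100 * out[[s]] / out$total, NA_real_)
  }
  rownames(out) <- NULL
  out
}

#' Stratified cohort summaries
#'
#' Partitions the profiled patients by sex, age group, or both, and
#' summarizes each stratum with [summarize_cohort()]. Stratum counts always
#' re-aggregate exactly to the cohort totals.
#'
#' @param profiles A `ddi_profiles` object.
#' @param cohort The matching `ddi_cohort` (source of sex/age).
#' @param by One of `"sex"`, `"age_group"`, `"both"`.
#' @param age_cuts Passed to [age_group()].
#' @return Named list of `ddi_cohort_summary`, one per non-empty stratum.
#' @export
stratify_cohort <- function(profiles, cohort,
                            by = c("sex", "age_group", "both"),
                            age_cuts = c(50, 65, 80)) {
  by <- match.arg(by)
  stopifnot(inherits(profiles, "ddi_profiles"), inherits(cohort, "ddi_cohort"))
  p <- cohort$patients
  idx <- match(profiles$profiles$patient_id, p$patient_id)
  lab <- switch(by,
    sex = p$sex[idx],
    age_group = as.character(age_group(p$age[idx], cuts = age_cuts)),
    both = paste(p$sex[idx], age_group(p$age[idx], cuts = age_cuts),
                 sep = "/"))
  out <- lapply(split(seq_len(nrow(profiles$profiles)), lab), function(i) {
    sub <- structure(list(
      profiles = profiles$profiles[i, , drop = FALSE],
      interactions = profiles$interactions[
        profiles$interactions$patient_id %in%
          profiles$profiles$patient_id[i], , drop = FALSE]),
      class = "ddi_profiles")
    summarize_cohort(sub)
  })
  out
}

#' @export
print.ddi_cohort_summary <- function(x, ...) {
  cat("<ddi_cohort_summary> ", x$n_patients, " patient(s), ",
      x$total_interactions, " interaction event(s)\n", sep = "")
  cat(sprintf("  any interaction: %d (%.1f%%, CI %.1f-%.1f); any major: %d (%.1f%%)\n",
              x$prevalence_any$successes, x$prevalence_any$pct,
              x$prevalence_any$ci_low, x$prevalence_any$ci_high,
              x$prevalence_any_major$successes, x$prevalence_any_major$pct))
  sd <- x$severity_distribution
  cat("  severity: ",
      paste(sprintf("%s %d (%.1f%%)", sd$severity, sd$count, sd$pct),
            collapse = ", "), "\n", sep = "")
  cat(sprintf("  r(medications, total interactions) = %.3f\n",
              x$correlation_meds_vs_total$r))
  invisible(x)
}
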
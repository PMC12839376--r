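# Per-patient interaction profiling: enumerate all C(n,2) within-patient
# drug pairs, classify each against the knowledge base, and derive the
# burden and risk categories.

#' Enumerate all unordered drug pairs of a medication list
#'
#' Returns exactly n(n-1)/2 canonically ordered pairs for n distinct
#' medications, with no self-pairs and no duplicates.
#'
#' @param medications Character vector of drug names (canonicalized and
#'   de-duplicated internally).
#' @return Data frame with columns `drug_a`, `drug_b` (lexicographic within
#'   and across rows).
#' @examples
#' enumerate_pairs(c("furosemide", "spironolactone", "pantoprazole"))
#' @export
enumerate_pairs <- function(medications) {
  meds <- sort(unique(canonicalize_drug(medications)))
  n <- length(meds)
  if (n < 2) {
    return(data.frame(drug_a = character(0), drug_b = character(0),
                      stringsAsFactors = FALSE))
  }
  cmb <- utils::combn(meds, 2)
  data.frame(drug_a = cmb[1, ], drug_b = cmb[2, ], stringsAsFactors = FALSE)
}

#' Profile a single patient against a knowledge base
#'
#' Looks up every candidate pair once and tallies interactions by severity.
#' The major-interaction share of the total, `major_pct_of_total`, is `NA`
#' (absent, not zero) for a patient with no interactions.
#'
#' @param patient_id Identifier carried into the outputs.
#' @param medications Character vector of the patient's drugs.
#' @param kb A `ddi_kb` knowledge base.
#' @return List of class `patient_profile` with elements `profile` (one-row
#'   data frame of scalar measures) and `interactions` (long-format data
#'   frame `patient_id`, `drug_a`, `drug_b`, `severity`, canonically
#'   sorted).
#' @export
profile_patient <- function(patient_id, medications, kb) {
  meds <- sort(unique(canonicalize_drug(medications)))
  pairs <- enumerate_pairs(meds)
  sev <- if (nrow(pairs) > 0) kb_lookup(kb, pairs$drug_a, pairs$drug_b)
         else character(0)
  hit <- !is.na(sev)
  inter <- data.frame(patient_id = rep(patient_id, sum(hit)),
                      drug_a = pairs$drug_a[hit], drug_b = pairs$drug_b[hit],
                      severity = sev[hit], stringsAsFactors = FALSE)
  counts <- table(factor(inter$severity, levels = SEVERITY_LABELS))
  total <- nrow(inter)
  n_major <- as.integer(counts[["major"]])
  profile <- data.frame(
    patient_id = patient_id,
    n_medications = length(meds),
    candidate_pairs = nrow(pairs),
    n_minor = as.integer(counts[["minor"]]),
    n_moderate = as.integer(counts[["moderate"]]),
    n_major = n_major,
    n_unknown = as.integer(counts[["unknown"]]),
    total_interactions = total,
    major_pct_of_total = if (total > 0) 100 * n_major / total else NA_real_,
    medication_burden = as.character(medication_burden_category(length(meds))),
    interaction_burden = as.character(interaction_burden_category(total)),
    risk_category = as.character(risk_category(n_major)),
    stringsAsFactors = FALSE)
  structure(list(profile = profile, interactions = inter),
            class = "patient_profile")
}

#' Profile every patient of a cohort
#'
#' @param cohort A `ddi_cohort` object.
#' @param kb A `ddi_kb` knowledge base.
#' @return Object of class `ddi_profiles`: list with `profiles` (one row
#'   per patient) and `interactions` (long format, one row per
#'   patient-level interaction event).
#' @export
profile_cohort <- function(cohort, kb) {
  stopifnot(inherits(cohort, "ddi_cohort"), inherits(kb, "ddi_kb"))
  p <- cohort$patients
  res <- lapply(seq_len(nrow(p)), function(i) {
    profile_patient(p$patient_id[i], p$medications[[i]], kb)
  })
  profiles <- do.call(rbind, lapply(res, `[[`, "profile"))
  interactions <- do.call(rbind, lapply(res, `[[`, "interactions"))
  if (is.null(interactions)) {
    interactions <- data.frame(patient_id = character(0),
                               drug_a = character(0), drug_b = character(0),
                               severity = character(0))
  }
  rownames(profiles) <- rownames(interactions) <- NULL
  structure(list(profiles = profiles, interactions = interactions),
            class = "ddi_profiles")
}

#' Medication burden category
#'
#' 1-5 medications = low, 6-10 = medium, >= 11 = high.
#'
#' @param n Integer vector of medication counts (>= 1).
#' @return Factor with levels low/medium/high.
#' @export
medication_burden_category <- function(n) {
  stopifnot(all(n >= 1))
  lab <- ifelse(n <= 5, "low", ifelse(n <= 10, "medium", "high"))
  factor(lab, levels = c("low", "medium", "high"))
}

#' Interaction burden category
#'
#' 0-10 interactions = low, 11-30 = medium, >= 31 = high.
#'
#' @param total Integer vector of per-patient total interaction counts.
#' @return Factor with levels low/medium/high.
#' @export
interaction_burden_category <- function(total) {
  stopifnot(all(total >= 0))
  lab <- ifelse(total <= 10, "low", ifelse(total <= 30, "medium", "high"))
  factor(lab, levels = c("low", "medium", "high"))
}

#' Major-interaction risk category
#'
#' 0 major interactions = low risk, 1-2 = moderate, >= 3 = high.
#'
#' @param n_major Integer vector of per-patient major-interaction counts.
#' @return Factor with levels low/moderate/high.
#' @export
risk_category <- function(n_major) {
  stopifnot(all(n_major >= 0))
  lab <- ifelse(n_major == 0, "low", ifelse(n_major <= 2, "moderate", "high"))
  factor(lab, levels = c("low", "moderate", "high"))
}

#' @export
print.ddi_profiles <- function(x, ...) {
  pr <- x$profiles
  cat("<ddi_profiles> ", nrow(pr), " patient(s), ",
      sum(pr$total_interactions), " interaction event(s)\n", sep = "")
  cat(sprintf("  with >=1 interaction: %d (%.1f%%); with >=1 major: %d (%.1f%%)\n",
              sum(pr$total_interactions > 0),
              100 * mean(pr$total_interactions > 0),
              sum(pr$n_major > 0), 100 * mean(pr$n_major > 0)))
  invisible(x)
}
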
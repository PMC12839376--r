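# Cohort ingestion: patient records with admission medication lists.
# Inclusion rules applied on load: adult (age >= 18), at least two distinct
# pharmacologically active agents after canonicalization; rows failing a
# rule are excluded and itemized in the exclusion report.

#' Construct a cohort object
#'
#' Lower-level constructor used by [load_cohort()] and the synthetic
#' generator. Performs no exclusion; assumes medications are already
#' canonical, de-duplicated character vectors.
#'
#' @param patients Data frame with columns `patient_id`, `age`, `sex`,
#'   `residence`, `diagnosis` and a list-column `medications`.
#' @param excluded Data frame itemizing excluded input rows
#'   (`patient_id`, `reason`).
#' @param source Provenance string (file path or `"synthetic"`).
#' @param loaded_at Load timestamp; `NA` for synthetic cohorts so that
#'   regeneration from the same seed is identical.
#' @return An object of class `ddi_cohort`.
#' @export
new_cohort <- function(patients,
                       excluded = data.frame(patient_id = character(0),
                                             reason = character(0)),
                       source = NA_character_, loaded_at = Sys.time()) {
  stopifnot(is.data.frame(patients), is.list(patients$medications))
  if (anyDuplicated(patients$patient_id)) {
    stop("duplicate patient id(s): ",
         paste(unique(patients$patient_id[duplicated(patients$patient_id)]),
               collapse = ", "), call. = FALSE)
  }
  structure(list(patients = patients, excluded = excluded, source = source,
                 loaded_at = loaded_at),
            class = "ddi_cohort")
}

normalize_sex <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- rep(NA_character_, length(x))
  out[x %in% c("m", "male")] <- "male"
  out[x %in% c("f", "female")] <- "female"
  out
}

#' Load a patient cohort from CSV
#'
#' Reads a cohort file (one row per patient; `medications` is a
#' semicolon-delimited list of drug names), canonicalizes and de-duplicates
#' each medication list, and applies the inclusion rules: age >= `min_age`
#' and at least `min_medications` distinct agents. Excluded rows are
#' itemized, with one reason each, in the `excluded` element of the result.
#'
#' @param path CSV path with header columns `patient_id`, `age`, `sex`,
#'   `residence`, `diagnosis`, `medications`.
#' @param strict If `TRUE`, any exclusion (or unrecognised sex value) is an
#'   error instead of a reported exclusion.
#' @param min_age Minimum age for inclusion (default 18).
#' @param min_medications Minimum number of distinct agents (default 2; set
#'   to 1 to admit single-agent records).
#' @return A `ddi_cohort` object.
#' @export
load_cohort <- function(path, strict = FALSE, min_age = 18,
                        min_medications = 2) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8",
                         colClasses = "character")
  need <- c("patient_id", "age", "sex", "residence", "diagnosis",
            "medications")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0) {
    stop("cohort file is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  n <- nrow(raw)
  reason <- rep(NA_character_, n)
  age <- suppressWarnings(as.integer(raw$age))
  sex <- normalize_sex(raw$sex)
  meds <- vector("list", n)
  had_dupes <- logical(n)
  for (i in seq_len(n)) {
    toks <- trimws(strsplit(raw$medications[i], ";", fixed = TRUE)[[1]])
    toks <- toks[nzchar(toks)]
    if (length(toks) == 0) {
      reason[i] <- "incomplete or missing medication record"
      next
    }
    canon <- canonicalize_drug(toks)
    had_dupes[i] <- anyDuplicated(canon) > 0
    meds[[i]] <- sort(unique(canon))
  }
  ok <- is.na(reason)
  bad_age <- ok & (is.na(age) | age < min_age)
  reason[bad_age] <- ifelse(is.na(age[bad_age]), "missing or invalid age",
                            sprintf("under %d", min_age))
  ok <- is.na(reason)
  too_few <- ok & lengths(meds) < min_medications
  reason[too_few] <- "fewer than two agents"
  if (strict) {
    bad_sex <- is.na(reason) & is.na(sex)
    reason[bad_sex] <- "unrecognised sex value"
  }
  if (any(had_dupes & is.na(reason))) {
    warning("duplicate medications collapsed for patient(s): ",
            paste(raw$patient_id[had_dupes & is.na(reason)], collapse = ", "),
            call. = FALSE)
  }
  keep <- is.na(reason)
  if (strict && !all(keep)) {
    stop("strict mode: ", sum(!keep), " row(s) fail inclusion criteria, ",
         "first: ", raw$patient_id[!keep][1], " (", reason[!keep][1], ")",
         call. = FALSE)
  }
  patients <- data.frame(patient_id = raw$patient_id[keep],
                         age = age[keep],
                         sex = ifelse(is.na(sex[keep]), "unknown", sex[keep]),
                         residence = tolower(trimws(raw$residence[keep])),
                         diagnosis = trimws(raw$diagnosis[keep]),
                         stringsAsFactors = FALSE)
  patients$medications <- meds[keep]
  excluded <- data.frame(patient_id = raw$patient_id[!keep],
                         reason = reason[!keep], stringsAsFactors = FALSE)
  message("loaded cohort: ", nrow(patients), " patient(s) accepted, ",
          nrow(excluded), " excluded")
  new_cohort(patients, excluded, source = path)
}

#' Write a cohort to CSV
#'
#' Inverse of [load_cohort()]: medication lists are joined with `"; "`.
#'
#' @param cohort A `ddi_cohort` object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "ddi_cohort"))
  p <- cohort$patients
  out <- data.frame(patient_id = p$patient_id, age = p$age, sex = p$sex,
                    residence = p$residence, diagnosis = p$diagnosis,
                    medications = vapply(p$medications, paste,
                                         character(1), collapse = "; "),
                    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Assign ages to analysis age groups
#'
#' Four half-open bins `[18,50)`, `[50,65)`, `[65,80)`, `[80,Inf)` labelled
#' `"<50"`, `"50-65"`, `"65-80"`, `">80"`. The boundary ages 50, 65 and 80
#' fall into the bin they open (so 65 is `"65-80"` and 80 is `">80"`).
#' Custom cut points may be supplied.
#'
#' @param age Integer vector of ages (>= 18).
#' @param cuts Ascending numeric cut points (default `c(50, 65, 80)`).
#' @param labels Bin labels, `length(cuts) + 1` of them.
#' @return Factor of bin labels with levels in age order.
#' @examples
#' age_group(c(49, 50, 65, 80))
#' @export
age_group <- function(age, cuts = c(50, 65, 80),
                      labels = c("<50", "50-65", "65-80", ">80")) {
  stopifnot(length(labels) == length(cuts) + 1, !is.unsorted(cuts))
  idx <- findInterval(age, cuts) + 1L
  factor(labels[idx], levels = labels)
}

#' @export
print.ddi_cohort <- function(x, ...) {
  p <- x$patients
  cat("<ddi_cohort> ", nrow(p), " patient(s)",
      if (nrow(x$excluded) > 0) paste0(" (", nrow(x$excluded), " excluded)"),
      "\n", sep = "")
  if (nrow(p) > 0) {
    cat(sprintf("  age %.1f ± %.1f; %.1f%% male; %.2f medications/patient (range %d-%d)\n",
                mean(p$age), stats::sd(p$age),
                100 * mean(p$sex == "male"),
                mean(lengths(p$medications)),
                min(lengths(p$medications)), max(lengths(p$medications))))
  }
  invisible(x)
}
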
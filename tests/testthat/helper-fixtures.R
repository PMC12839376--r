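# Small in-code fixtures shared across test files.

tiny_kb <- function() {
  knowledge_base(data.frame(
    drug_a = c("spironolactone", "furosemide", "pantoprazole"),
    drug_b = c("perindopril", "spironolactone", "clopidogrel"),
    severity = c("major", "minor", "moderate"),
    stringsAsFactors = FALSE))
}

write_cohort_csv <- function(rows, path = tempfile(fileext = ".csv")) {
  header <- "patient_id,age,sex,residence,diagnosis,medications"
  writeLines(c(header, rows), path)
  path
}

# Three-patient toy cohort with hand-computable profile against tiny_kb():
#  P1 {furosemide, spironolactone, perindopril}: pairs (f,s) minor,
#     (p,s) major, (f,p) unlisted -> total 2 (1 major, 1 minor)
#  P2 {pantoprazole, clopidogrel}: (c,p) moderate -> total 1 moderate
#  P3 {atorvastatin, bisoprolol}: none -> total 0
toy_cohort <- function() {
  rows <- c(
    'P1,70,male,rural,heart failure,"furosemide; spironolactone; perindopril"',
    'P2,55,female,urban,unstable angina,"pantoprazole; clopidogrel"',
    'P3,81,male,rural,hypertension,"atorvastatin; bisoprolol"')
  suppressMessages(load_cohort(write_cohort_csv(rows)))
}
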
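# Severity vocabulary and the fixed edge-weight mapping used throughout:
# major = 3, moderate = 2, minor = 1, unknown = 0.5. "unknown" is a listed
# category for pairs whose severity the knowledge base could not grade; a
# pair absent from the knowledge base is "no interaction", never "unknown".

SEVERITY_LABELS <- c("minor", "moderate", "major", "unknown")
SEVERITY_WEIGHTS <- c(minor = 1, moderate = 2, major = 3, unknown = 0.5)

#' Severity labels recognised by the pipeline
#'
#' @return Character vector `c("minor", "moderate", "major", "unknown")`, in
#'   ascending clinical rank for the first three; `"unknown"` is unranked.
#' @export
severity_levels <- function() SEVERITY_LABELS

#' Numeric edge weight of an interaction severity
#'
#' Maps severity labels to the fixed network edge weights: major = 3,
#' moderate = 2, minor = 1, unknown = 0.5.
#'
#' @param severity Character vector of severity labels.
#' @return Numeric vector of weights.
#' @examples
#' severity_weight(c("major", "unknown"))
#' @export
severity_weight <- function(severity) {
  severity <- tolower(trimws(as.character(severity)))
  bad <- setdiff(unique(severity[!is.na(severity)]), SEVERITY_LABELS)
  if (length(bad) > 0) {
    stop("unknown severity label(s): ", paste(sQuote(bad), collapse = ", "),
         "; allowed labels are: ", paste(SEVERITY_LABELS, collapse = ", "),
         call. = FALSE)
  }
  unname(SEVERITY_WEIGHTS[severity])
}

#' Canonicalize drug names
#'
#' Lowercases, trims surrounding whitespace and collapses internal runs of
#' whitespace to single spaces, so that e.g. `"  Acetylsalicylic  ACID "` and
#' `"acetylsalicylic acid"` compare equal. Canonicalization is idempotent.
#'
#' @param name Character vector of raw drug names.
#' @return Character vector of canonical names.
#' @examples
#' canonicalize_drug("  Pantoprazole ")
#' @export
canonicalize_drug <- function(name) {
  if (!is.character(name)) name <- as.character(name)
  out <- tolower(gsub("[[:space:]]+", " ", trimws(name)))
  blank <- is.na(out) | !nzchar(out)
  if (any(blank)) {
    stop("empty or missing drug name at position(s): ",
         paste(which(blank), collapse = ", "), call. = FALSE)
  }
  out
}

# Canonical (lexicographic) ordering of an unordered drug pair, vectorized.
# Returns a data.frame with columns drug_a <= drug_b.
order_pair <- function(a, b) {
  swap <- a > b
  data.frame(drug_a = ifelse(swap, b, a),
             drug_b = ifelse(swap, a, b),
             stringsAsFactors = FALSE)
}

pair_key <- function(a, b) paste(a, b, sep = "\r")
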
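# Severity-annotated interaction knowledge base: one record per unordered
# drug pair, standing in for an online interaction checker. Closed-world:
# a pair not listed is "no interaction" (NA on lookup).

#' Construct an interaction knowledge base
#'
#' Validates and canonicalizes a table of interacting drug pairs. Names are
#' canonicalized ([canonicalize_drug()]), each pair is stored in
#' lexicographic order so (A,B) and (B,A) are the same record, self-pairs
#' are rejected, and duplicate pairs are collapsed (an error if their
#' severities conflict).
#'
#' @param records Data frame with columns `drug_a`, `drug_b`, `severity`
#'   (severity one of `severity_levels()`).
#' @return An object of class `ddi_kb` with element `records`, a data frame
#'   sorted by canonical pair.
#' @examples
#' kb <- knowledge_base(data.frame(
#'   drug_a = c("Spironolactone", "furosemide"),
#'   drug_b = c("perindopril", "Pantoprazole"),
#'   severity = c("major", "minor")))
#' kb
#' @export
knowledge_base <- function(records) {
  stopifnot(is.data.frame(records))
  need <- c("drug_a", "drug_b", "severity")
  miss <- setdiff(need, names(records))
  if (length(miss) > 0) {
    stop("knowledge base is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (nrow(records) == 0) {
    recs <- data.frame(drug_a = character(0), drug_b = character(0),
                       severity = character(0), stringsAsFactors = FALSE)
    return(structure(list(records = recs), class = "ddi_kb"))
  }
  a <- canonicalize_drug(records$drug_a)
  b <- canonicalize_drug(records$drug_b)
  sev <- tolower(trimws(as.character(records$severity)))
  bad <- setdiff(unique(sev), SEVERITY_LABELS)
  if (length(bad) > 0) {
    stop("unknown severity label(s): ", paste(sQuote(bad), collapse = ", "),
         "; allowed labels are: ", paste(SEVERITY_LABELS, collapse = ", "),
         call. = FALSE)
  }
  self <- a == b
  if (any(self)) {
    stop("self-interaction (drug paired with itself) in row(s): ",
         paste(which(self), collapse = ", "), call. = FALSE)
  }
  op <- order_pair(a, b)
  key <- pair_key(op$drug_a, op$drug_b)
  sev_by_key <- split(sev, key)
  conflict <- names(sev_by_key)[vapply(sev_by_key,
                                       function(s) length(unique(s)) > 1L,
                                       logical(1))]
  if (length(conflict) > 0) {
    k <- conflict[1]
    pair <- strsplit(k, "\r", fixed = TRUE)[[1]]
    stop("conflicting duplicate record for pair (", pair[1], ", ", pair[2],
         "): severities ", paste(unique(sev_by_key[[k]]), collapse = " vs "),
         call. = FALSE)
  }
  keep <- !duplicated(key)
  recs <- data.frame(drug_a = op$drug_a[keep], drug_b = op$drug_b[keep],
                     severity = sev[keep], stringsAsFactors = FALSE)
  recs <- recs[order(recs$drug_a, recs$drug_b), , drop = FALSE]
  rownames(recs) <- NULL
  structure(list(records = recs), class = "ddi_kb")
}

#' Load an interaction knowledge base from file
#'
#' @param path Path to a delimited file with header columns `drug_a`,
#'   `drug_b`, `severity`.
#' @param format `"auto"` (sniff delimiter from the file extension:
#'   `.tsv` tab, `.csv` comma), `"tsv"`, or `"csv"`.
#' @return A `ddi_kb` object; the record count is reported via [message()].
#' @export
load_knowledge_base <- function(path, format = c("auto", "tsv", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, tsv = "tsv", csv = "csv",
                     stop("cannot sniff knowledge-base format from extension ",
                          sQuote(ext), "; pass format = 'tsv' or 'csv'",
                          call. = FALSE))
  }
  raw <- if (format == "tsv") {
    utils::read.delim(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  }
  kb <- knowledge_base(raw)
  message("loaded knowledge base: ", nrow(kb$records), " interaction record(s), ",
          length(kb_drugs(kb)), " drug(s)")
  kb
}

#' Write a knowledge base to file
#'
#' Emits the canonical record set (lexicographic pair order) so that
#' `load_knowledge_base(write_knowledge_base(kb, f))` round-trips exactly.
#'
#' @param kb A `ddi_kb` object.
#' @param path Output path; delimiter sniffed from extension as in
#'   [load_knowledge_base()].
#' @return `path`, invisibly.
#' @export
write_knowledge_base <- function(kb, path) {
  stopifnot(inherits(kb, "ddi_kb"))
  sep <- if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
  utils::write.table(kb$records, path, sep = sep, row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Look up the severity of a drug pair
#'
#' Symmetric, closed-world lookup: `kb_lookup(kb, a, b)` equals
#' `kb_lookup(kb, b, a)`, and a pair not listed in the knowledge base
#' returns `NA` (no interaction) — never `"unknown"`, which is a listed
#' severity category in its own right.
#'
#' @param kb A `ddi_kb` object.
#' @param a,b Character vectors of drug names (recycled to equal length).
#' @return Character vector of severity labels, `NA` where no interaction
#'   is listed.
#' @export
kb_lookup <- function(kb, a, b) {
  stopifnot(inherits(kb, "ddi_kb"))
  a <- canonicalize_drug(a)
  b <- canonicalize_drug(b)
  n <- max(length(a), length(b))
  a <- rep_len(a, n); b <- rep_len(b, n)
  if (any(a == b)) {
    stop("self-pair lookup is undefined: ",
         paste(unique(a[a == b]), collapse = ", "), call. = FALSE)
  }
  op <- order_pair(a, b)
  idx <- match(pair_key(op$drug_a, op$drug_b),
               pair_key(kb$records$drug_a, kb$records$drug_b))
  kb$records$severity[idx]
}

#' Drugs mentioned in a knowledge base
#'
#' @param kb A `ddi_kb` object.
#' @return Sorted character vector of canonical drug names.
#' @export
kb_drugs <- function(kb) {
  stopifnot(inherits(kb, "ddi_kb"))
  sort(unique(c(kb$records$drug_a, kb$records$drug_b)))
}

#' @export
print.ddi_kb <- function(x, ...) {
  tab <- table(factor(x$records$severity, levels = SEVERITY_LABELS))
  cat("<ddi_kb> ", nrow(x$records), " interaction record(s) over ",
      length(kb_drugs(x)), " drug(s)\n", sep = "")
  cat("  severity: ", paste(names(tab), tab, sep = "=", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}
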
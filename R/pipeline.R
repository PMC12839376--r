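# End-to-end report: profiles a cohort against a knowledge base, writes the
# per-patient and long-format tables, the cohort summary, the network and
# its metrics (full graph and top-k hub subgraph), and a plain-text summary
# whose every number is recomputable from the emitted tables.

round_df <- function(df, digits = 1) {
  num <- vapply(df, is.numeric, logical(1)) &
    !vapply(df, is.integer, logical(1))
  df[num] <- lapply(df[num], round, digits = digits)
  df
}

write_tsv <- function(df, path, digits = 1) {
  utils::write.table(round_df(df, digits), path, sep = "\t",
                     row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  path
}

summary_as_list <- function(s) {
  pe <- function(x) list(successes = x$successes, n = x$n, pct = x$pct,
                         ci_low = x$ci_low, ci_high = x$ci_high,
                         level = x$level)
  list(n_patients = s$n_patients,
       total_interactions = s$total_interactions,
       severity_distribution = s$severity_distribution,
       prevalence_any = pe(s$prevalence_any),
       prevalence_any_major = pe(s$prevalence_any_major),
       prevalence_by_severity = lapply(s$prevalence_by_severity, pe),
       risk_distribution = s$risk_distribution,
       medication_burden_distribution = s$medication_burden_distribution,
       interaction_burden_distribution = s$interaction_burden_distribution,
       per_patient = s$per_patient,
       mean_major_pct_of_total = s$mean_major_pct_of_total,
       correlation_meds_vs_total = s$correlation_meds_vs_total,
       correlation_total_vs_major = s$correlation_total_vs_major)
}

#' Run the full interaction-analysis pipeline
#'
#' Profiles every patient, summarizes the cohort, builds the
#' severity-weighted network and its top-`top_k` hub subgraph, computes all
#' node- and graph-level metrics, and writes the complete report bundle
#' under `out_dir`: per-patient profiles, long-format interactions, summary
#' JSON, frequency/severity/risk tables, stratified summaries, edge lists,
#' GraphML, metric tables and a plain-text summary, plus a manifest with
#' the package version and input provenance.
#'
#' @param cohort A `ddi_cohort`.
#' @param kb A `ddi_kb`.
#' @param out_dir Output directory (created if needed).
#' @param top_k Hub subgraph size (default 25).
#' @param age_cuts Age-group cut points for stratified tables.
#' @return Invisibly, a list with `profiles`, `summary`, `graph`,
#'   `subgraph`, `node_metrics`, `graph_metrics`, `subgraph_metrics` and
#'   the written `files`.
#' @export
run_pipeline <- function(cohort, kb, out_dir, top_k = 25,
                         age_cuts = c(50, 65, 80)) {
  stopifnot(inherits(cohort, "ddi_cohort"), inherits(kb, "ddi_kb"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "strata"), showWarnings = FALSE)

  message("stage profile: ", nrow(cohort$patients), " patient(s)")
  profiles <- profile_cohort(cohort, kb)
  s <- summarize_cohort(profiles)
  message("stage network")
  graph <- build_network(profiles)
  sub <- if (length(graph$nodes) > 0) {
    suppressWarnings(top_k_subgraph(graph, min(top_k, length(graph$nodes))))
  } else graph
  gm <- graph_metrics(graph)
  sgm <- graph_metrics(sub)
  nm <- if (nrow(graph$edges) > 0) suppressWarnings(node_metrics(graph)) else
    data.frame(drug = character(0))
  snm <- if (nrow(sub$edges) > 0) suppressWarnings(node_metrics(sub)) else
    data.frame(drug = character(0))

  files <- c(
    profiles = write_tsv(profiles$profiles,
                         file.path(out_dir, "patient_profiles.tsv"),
                         digits = 2),
    interactions = write_tsv(profiles$interactions,
                             file.path(out_dir, "interactions.tsv")),
    severity = write_tsv(s$severity_distribution,
                         file.path(out_dir, "severity_distribution.tsv")),
    risk = write_tsv(s$risk_distribution,
                     file.path(out_dir, "risk_distribution.tsv")),
    drug_freq = write_tsv(drug_frequency_table(profiles$interactions, cohort),
                          file.path(out_dir, "drug_frequency.tsv"),
                          digits = 2),
    pair_freq = write_tsv(pair_frequency_table(profiles$interactions),
                          file.path(out_dir, "pair_frequency.tsv")),
    crosstab = write_tsv(drug_severity_crosstab(profiles$interactions),
                         file.path(out_dir, "drug_severity_top15.tsv")),
    edges = write_edge_list(graph, file.path(out_dir, "edge_list.tsv")),
    graphml = write_graphml(graph, file.path(out_dir, "network.graphml")),
    node_metrics = write_tsv(nm, file.path(out_dir, "node_metrics.tsv"),
                             digits = 6),
    sub_edges = write_edge_list(sub,
                                file.path(out_dir, "hub_edge_list.tsv")),
    sub_node_metrics = write_tsv(snm,
                                 file.path(out_dir, "hub_node_metrics.tsv"),
                                 digits = 6))

  for (by in c("sex", "age_group")) {
    strata <- stratify_cohort(profiles, cohort, by = by, age_cuts = age_cuts)
    tab <- do.call(rbind, lapply(names(strata), function(nm2) {
      st <- strata[[nm2]]
      data.frame(stratum = nm2, n_patients = st$n_patients,
                 total_interactions = st$total_interactions,
                 pct_minor = st$severity_distribution$pct[1],
                 pct_moderate = st$severity_distribution$pct[2],
                 pct_major = st$severity_distribution$pct[3],
                 stringsAsFactors = FALSE)
    }))
    files[[paste0("strata_", by)]] <-
      write_tsv(tab, file.path(out_dir, "strata", paste0(by, ".tsv")))
  }

  jsonlite::write_json(summary_as_list(s),
                       file.path(out_dir, "cohort_summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  jsonlite::write_json(list(full = gm, hub_subgraph = sgm),
                       file.path(out_dir, "graph_metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  files[["summary_json"]] <- file.path(out_dir, "cohort_summary.json")
  files[["graph_json"]] <- file.path(out_dir, "graph_metrics.json")

  txt <- c(
    "Drug-drug interaction analysis summary",
    sprintf("patients: %d", s$n_patients),
    sprintf("total interaction events: %d", s$total_interactions),
    sprintf("patients with >=1 interaction: %d (%.1f%%, %d%% CI %.1f-%.1f)",
            s$prevalence_any$successes, s$prevalence_any$pct,
            round(100 * s$prevalence_any$level),
            s$prevalence_any$ci_low, s$prevalence_any$ci_high),
    sprintf("patients with >=1 major interaction: %d (%.1f%%)",
            s$prevalence_any_major$successes, s$prevalence_any_major$pct),
    sprintf("severity distribution: %s",
            paste(sprintf("%s %d (%.1f%%)",
                          s$severity_distribution$severity,
                          s$severity_distribution$count,
                          s$severity_distribution$pct), collapse = ", ")),
    sprintf("risk strata: %s",
            paste(sprintf("%s %d (%.1f%%)", s$risk_distribution$category,
                          s$risk_distribution$count,
                          s$risk_distribution$pct), collapse = ", ")),
    sprintf("r(medications, total interactions) = %.3f",
            s$correlation_meds_vs_total$r),
    sprintf("network: %d nodes, %d edges, density %.3f, avg clustering %.3f, %d component(s)",
            gm$n_nodes, gm$n_edges, gm$density, gm$avg_clustering,
            gm$n_components),
    sprintf("hub subgraph (top %d by degree): %d edges, density %.3f, avg clustering %.3f",
            length(sub$nodes), sgm$n_edges, sgm$density, sgm$avg_clustering))
  writeLines(txt, file.path(out_dir, "summary.txt"))
  files[["summary_txt"]] <- file.path(out_dir, "summary.txt")

  manifest <- list(
    package = "ddinet",
    version = as.character(utils::packageVersion("ddinet")),
    generated_at = format(Sys.time(), tz = "UTC"),
    cohort_source = cohort$source,
    n_patients = s$n_patients,
    n_kb_records = nrow(kb$records),
    files = basename(unname(unlist(files))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)

  invisible(list(profiles = profiles, summary = s, graph = graph,
                 subgraph = sub, node_metrics = nm, graph_metrics = gm,
                 subgraph_metrics = sgm, files = files))
}
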
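#!/usr/bin/env Rscript
# Step 3: cohort-level descriptive surface. Aggregates the per-patient
# profiles into prevalence estimates with exact Clopper-Pearson intervals,
# the event-level severity distribution, burden/risk strata, per-drug and
# per-pair frequency tables, the severity crosstab for the most
# interaction-prone drugs, and sex/age stratifications.

library(ddinet)

cohort <- load_cohort("results/synthetic/cohort.csv", min_medications = 1)
kb <- load_knowledge_base("results/synthetic/knowledge_base.tsv")
profiles <- profile_cohort(cohort, kb)

s <- summarize_cohort(profiles)
print(s)
cat(sprintf("any major interaction: %.1f%% (CI %.1f-%.1f)\n",
            s$prevalence_any_major$pct, s$prevalence_any_major$ci_low,
            s$prevalence_any_major$ci_high))
cat(sprintf("r(total, major) = %.3f\n", s$correlation_total_vs_major$r))

dir.create("results/stats", showWarnings = FALSE)
out <- function(df, name) {
  write.table(df, file.path("results/stats", name), sep = "\t",
              row.names = FALSE, quote = FALSE)
}
out(s$severity_distribution, "severity_distribution.tsv")
out(s$risk_distribution, "risk_distribution.tsv")
out(s$medication_burden_distribution, "medication_burden.tsv")
out(s$interaction_burden_distribution, "interaction_burden.tsv")
out(drug_frequency_table(profiles$interactions, cohort),
    "drug_frequency.tsv")
out(pair_frequency_table(profiles$interactions), "pair_frequency.tsv")
out(drug_severity_crosstab(profiles$interactions, top = 15),
    "drug_severity_top15.tsv")

for (by in c("sex", "age_group")) {
  strata <- stratify_cohort(profiles, cohort, by = by)
  tab <- do.call(rbind, lapply(names(strata), function(nm) {
    st <- strata[[nm]]
    data.frame(stratum = nm, n_patients = st$n_patients,
               total = st$total_interactions,
               pct_minor = st$severity_distribution$pct[1],
               pct_moderate = st$severity_distribution$pct[2],
               pct_major = st$severity_distribution$pct[3])
  }))
  out(tab, paste0("strata_", by, ".tsv"))
  cat("severity by", by, ":\n")
  print(tab, digits = 3, row.names = FALSE)
}
cat("tables written to results/stats/\n")
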
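#!/usr/bin/env Rscript
# Step 2: read the cohort and knowledge base back from the standard files
# and profile every patient: enumerate all n(n-1)/2 within-patient drug
# pairs, classify each against the knowledge base, and derive the burden
# and risk categories. Writes the per-patient profile table and the
# long-format interaction table.

library(ddinet)

# admission medication counts legitimately range from 1 upward, so the
# single-agent exclusion is relaxed here (a 1-drug patient simply has
# zero candidate pairs)
cohort <- load_cohort("results/synthetic/cohort.csv", min_medications = 1)
kb <- load_knowledge_base("results/synthetic/knowledge_base.tsv")

profiles <- profile_cohort(cohort, kb)
print(profiles)

dir.create("results/profiles", showWarnings = FALSE)
write.table(profiles$profiles, "results/profiles/patient_profiles.tsv",
            sep = "\t", row.names = FALSE, quote = FALSE)
write.table(profiles$interactions, "results/profiles/interactions.tsv",
            sep = "\t", row.names = FALSE, quote = FALSE)

pr <- profiles$profiles
cat(sprintf("mean interactions/patient: %.2f (max %d)\n",
            mean(pr$total_interactions), max(pr$total_interactions)))
cat(sprintf("mean major interactions/patient: %.2f\n", mean(pr$n_major)))
cat("risk strata:", paste(names(table(pr$risk_category)),
                          table(pr$risk_category), sep = "=",
                          collapse = ", "), "\n")
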
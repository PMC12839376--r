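#!/usr/bin/env Rscript
# Step 1: generate the synthetic study cohort and interaction knowledge
# base under the default conditions (250 patients, 110-drug formulary,
# mean 7.7 medications/patient, 55.6% male, age ~ N(68.3, 12.8), severity
# mix 44/44/12, hub-skewed interaction fabric) and write them in the
# standard input formats so the rest of the workflow is indistinguishable
# from an analysis of real data.

library(ddinet)

seed <- 20260925
bundle <- generate_bundle(generator_config(seed = seed))
paths <- write_bundle(bundle, "results/synthetic")

cat("seed:", seed, "\n")
print(bundle$cohort)
print(bundle$kb)
cat("wrote:", paste(basename(paths), collapse = ", "),
    "-> results/synthetic/\n")
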
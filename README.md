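# ddinet

Drug–drug interaction (DDI) burden and network analysis for polypharmacy
cohorts.

Hospitalized cardiovascular patients routinely receive seven or more
concurrent medications, and with $n$ drugs come $n(n-1)/2$ candidate
interacting pairs — interaction burden scales combinatorially with
regimen size. ddinet is for pharmacoepidemiologists and clinical-pharmacy
researchers who want to move past one-pair-at-a-time screening: it
profiles every patient's medication list against a severity-annotated
interaction knowledge base, stratifies the cohort by burden and
major-interaction risk, and builds a severity-weighted undirected drug
network whose hubs — the drugs that disproportionately concentrate
interaction load — are identified with a full graph-metric suite.

At its core:

* **Per-patient profiling** — all $\binom{n}{2}$ pairs looked up once;
  severity counts; burden categories (1–5 / 6–10 / ≥11 medications,
  0–10 / 11–30 / ≥31 interactions) and risk strata (0 / 1–2 / ≥3 major
  interactions).
* **Cohort statistics** — severity distribution, prevalence with exact
  Clopper–Pearson 95% CIs, per-drug and per-pair frequency tables,
  severity crosstabs, Pearson correlations, sex/age stratification.
* **Network analysis** — nodes are drugs, edges are observed interacting
  pairs with summed severity weights (major = 3, moderate = 2, minor = 1,
  unknown = 0.5) across patients; degree, betweenness (Brandes),
  closeness, eigenvector centrality (power iteration), clustering,
  components, density $2m/(n(n-1))$, and the induced subgraph of the
  top-$k$ hub drugs. All metrics are implemented from scratch and
  validated against brute-force oracles and igraph.
* **Synthetic cohorts** — a seeded generator emulating a 250-patient
  cardiovascular cohort over a 110-drug formulary with a hub-skewed
  interaction fabric, so the entire pipeline is testable offline.

## Worked example

```r
library(ddinet)

bundle   <- generate_bundle(generator_config(seed = 1))
profiles <- profile_cohort(bundle$cohort, bundle$kb)
summarize_cohort(profiles)
#> <ddi_cohort_summary> 250 patient(s), 4205 interaction event(s)
#>   any interaction: 244 (97.6%, CI 94.8-99.1); any major: 192 (76.8%)
#>   severity: minor 1880 (44.7%), moderate 1709 (40.6%), major 616 (14.6%), unknown 0 (0.0%)
#>   r(medications, total interactions) = 0.918

graph <- build_network(profiles)
#> built network: 109 node(s), 697 edge(s)
top_k_subgraph(graph, 25)
#> <ddi_graph> 25 node(s), 215 edge(s), density 0.717
```

Reading: of 250 simulated patients, 244 (97.6%) have at least one
potential interaction — the exact 95% CI (94.8–99.1%) shows how tight
that prevalence estimate is at this sample size. The 4205 patient-level
interaction events split into 44.7% minor / 40.6% moderate / 14.6%
major, and the correlation of 0.918 between medication count and
interaction total is the combinatorial $n(n-1)/2$ scaling made visible.
Aggregated over patients the events collapse to 697 distinct interacting
pairs over 109 drugs; the 25 best-connected drugs alone share 215 edges
(density 0.717) — a densely saturated therapeutic core.

Real data enter through two plain-text formats: a cohort CSV
(`patient_id,age,sex,residence,diagnosis,medications`, medications
semicolon-separated) read by `load_cohort()`, and a knowledge-base
TSV/CSV (`drug_a, drug_b, severity`) read by `load_knowledge_base()`.
`run_pipeline(cohort, kb, out_dir)` writes the complete report bundle
(profile and interaction tables, summary JSON, frequency tables, edge
lists, GraphML, node/graph metrics for the full network and the hub
subgraph).

## Analysis workflow

The `analysis/` directory holds the numbered workflow the package was
built around — each script is a thin driver over the package functions
and writes its tables under `results/`:

1. `01_simulate.R` — generate the synthetic cohort + knowledge base.
2. `02_profile_patients.R` — per-patient interaction profiles.
3. `03_cohort_statistics.R` — cohort summary, frequency tables, strata.
4. `04_network_metrics.R` — network build, metric suite, hub subgraph.
5. `05_parameter_recovery.R` — generator truth vs. recovered marginals.

Run them in order from the repository root, e.g.
`Rscript analysis/01_simulate.R`.

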
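# icukg

Predicting 30-day ICU readmission from EHR-style records by enriching them
with **semantic annotations to biomedical ontologies**, assembling a
**patient knowledge graph**, and representing each ICU stay through
**knowledge-graph embeddings** fed to classical classifiers.

The package is aimed at clinical-informatics researchers who want to study
how ontology context changes EHR risk models, without needing access to
credentialed critical-care databases: a bundled simulator generates
MIMIC-schema cohorts and toy ontologies with a planted, ontology-mediated
readmission signal, so the complete pipeline runs and is testable offline.

## The method

1. **Clean and label.** Raw stays are cleaned (labels with no alphanumeric
   character are dropped), unformatted ICD9 codes are reconstructed
   (procedures gain a period after the second character, diagnoses after the
   third), patients under 18 are removed, and each stay gets a binary
   30-day readmission label from four criteria: ward transfer then ICU
   return in the same admission; ward transfer then in-hospital death;
   discharge then ICU return within 30 days; discharge then death within 30
   days (closed windows, calendar-day arithmetic).
2. **Annotate.** A stay is first a set of annotations
   `P_a = {c_1, ..., c_n}`: free-text terms are matched by lexical retrieval
   (token TF-IDF, top 6 candidates) followed by minimum-Levenshtein
   selection; coded features (LOINC-like, ICD9-like, NDC-like via a lookup
   table) resolve by direct identifier lookup.
3. **Build the KG.** `KG = {V_c, V_i, E_c, E_a}`: ontology classes `V_c`
   and their subclass edges `E_c`, one instance vertex per stay in `V_i`,
   and one annotation edge in `E_a` per distinct (stay, class) pair.
4. **Embed.** Three families: random-walk + skip-gram (500 walks per root,
   depth 4), translational TransE (`||h + r - t||`, margin ranking,
   per-epoch entity renormalization), and an axiom-corpus method trained on
   verbalized asserted + inferred subclass axioms and label words. Default
   width: 300 dimensions. A stay's vector under ontology `o` is the sum of
   its annotated class vectors, `v_po = sum_c v_c`; in the multi-ontology
   scenario the four per-ontology sums are concatenated (4 x 300 = 1200).
5. **Predict.** Patient vectors `P = {v_d + v_chart + v_po}` (one-hot
   demographics, median-imputed chart events, embedding block) are
   evaluated with LR / RF / NB / SVM under stratified five-fold
   cross-validation — AUROC, AUPRC, averaged confusion matrices, and
   Kruskal–Wallis comparisons between configurations. Snapshot moments
   (pre-ICU / in-ICU / post-ICU) restrict which feature blocks exist.

## Worked example

```r
library(icukg)
suite  <- toy_ontology_suite(seed = 7)
spec   <- cohort_spec(n_patients = 300, readmission_rate = 0.25,
                      signal_strength = 4, seed = 7)
cohort <- generate_cohort(spec, suite$ontologies, suite$ndc_table)
cohort
#> icu_cohort: 300 stays (75 readmission-positive), 4 ontologies

report <- run_experiment(cohort$stays, suite$ontologies,
                         scenario = "multi", moments = "in_icu",
                         models = c("LR", "RF"), dimension = 64,
                         seed = 7, ndc_table = suite$ndc_table)
report
#> readmission_report
#>   KG: 5815 triples, 706 subjects, 2 predicates
#>   [in_icu|1] LR: AUROC 0.649 +/- 0.057, AUPRC 0.361 +/- 0.048
#>   [in_icu|1] RF: AUROC 0.883 +/- 0.030, AUPRC 0.749 +/- 0.060
```

The KG here holds 5,815 triples over the four toy ontologies plus one
instance vertex per stay. The random forest recovers the planted signal
(mean AUROC 0.883 across the five folds); the linear model does worse on
the nonlinearly separable embedding sums. `report$confusion` holds the
averaged test-fold confusion matrix per model at the 0.5 probability
threshold, `report$metrics` the per-fold values, and — when several
configurations are run — `report$kruskal` the pairwise rank-test p-values.

A command-line front end covering `simulate`, `prep`, `annotate`,
`build-kg`, `embed` and `predict` is installed at
`system.file("cli/icukg", package = "icukg")`.

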
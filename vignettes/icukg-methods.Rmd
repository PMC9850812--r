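---
title: "Methods: ontology knowledge-graph embeddings for ICU readmission risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ontology knowledge-graph embeddings for ICU readmission risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the model

ICU readmission within 30 days of release (or death in that window) is both
a clinical risk marker and a quality-of-care indicator. Most vector-based
risk models treat EHR entries as opaque categories: two diagnoses such as
*aortic valve disease* and *coronary artery disease* share no feature even
though they are close relatives in any clinical ontology. `icukg`
operationalizes the alternative: link every usable EHR term or code to an
ontology class, let the ontology's hierarchy supply the missing context
through graph embeddings, and feed the result to ordinary classifiers.

A stay is first the set of its annotations, `P_a = {c_1, ..., c_n}`. The
patient knowledge graph is `KG = {V_c, V_i, E_c, E_a}`: class vertices
(all ontology classes), instance vertices (one per ICU stay — prediction is
per stay, not per patient), typed class–class edges (the subclass relation,
plus whatever other relations an input ontology carries), and annotation
edges connecting a stay to each class that annotates it through a single
fixed predicate. Feature-type provenance deliberately stays *outside* the
KG, in the annotation table, so the graph stays homogeneous.

Embedding methods map every vertex to a fixed-width real vector:

* **Random-walk + skip-gram.** All directed walks of at most `max_depth`
  edges are enumerated from every vertex and treated as sentences for
  skip-gram with negative sampling; roots whose enumeration exceeds
  `max_walks` contribute a seeded uniform sample. Walks follow edge
  direction — child toward parent, instance toward class — because the
  ancestor chain is what carries shared meaning in a subclass hierarchy
  (an optional bidirectional mode exists). Walks are prefix-inclusive by
  default (every prefix, including the lone root, is itself a sentence);
  a full-depth-only mode is available. Relation tokens are interleaved
  between vertex tokens by default and can be dropped.
* **TransE.** A relation is a translation: a plausible triple has small
  `||h + r - t||`. Training minimizes a margin-ranking loss between true
  triples and corrupted triples (uniform head-or-tail replacement, with
  corrupted triples that exist in the graph rejected and resampled), with
  entity vectors renormalized to the unit sphere at the end of each epoch.
  Only class and annotation edges are trained on — label strings are
  literals, not entities.
* **Axiom corpus.** Asserted class edges, the inferred transitive closure
  of the subclass relation, annotation edges, and word-split class labels
  are verbalized into sentences and fed to the same skip-gram trainer.
  Unlike the original formulation of this family, no literature-pretrained
  language model is used: the embeddings are trained on the generated
  corpus itself. This is a deliberate, named deviation — it removes an
  external binary dependency and keeps the comparison between embedding
  families about graph structure, not pretraining corpora.

A stay's vector under ontology `o` is the **sum** of its annotated class
vectors (`v_po = sum_c v_c`; the empty sum is the zero vector). Summation
makes aggregation permutation-invariant and additive, so ablating
annotations acts linearly on the representation. In the multi-ontology
scenario the per-ontology sums are **concatenated** in a fixed ontology
order — summing across ontologies would mix unrelated coordinate systems.
The prediction input is `P = {v_d + v_chart + v_po}`: one-hot demographics
(gender, ethnicity, insurance, plus age — one-hot was chosen over ordinal
coding because the categories are nominal), the numeric chart-event block,
and the embedding block. Blocks a snapshot moment does not license are
omitted entirely, not zero-filled, so the classifier never sees a spurious
"all-zero chart".

## Snapshot moments

Three prediction moments mirror the information flow of a stay: **pre-ICU**
(demographics + initial free-text diagnosis), **in-ICU** (adds labs,
prescriptions, chart events), **post-ICU** (adds final diagnoses and
procedures). Procedures are performed during the stay but are recorded only
at discharge for billing, so they belong to the post-ICU view. Stays with
no initial diagnosis are excluded from pre-ICU experiments only; they keep
their other features at later moments. The three feature sets are strictly
nested by construction.

## Readmission labelling

Four criteria, checked in a fixed order per stay: (1) transfer to a
low-level ward then ICU return within the same admission; (2) transfer to a
low-level ward then in-hospital death; (3) discharge then ICU admission
within the window; (4) discharge then death within the window. "Low-level
ward" is any transfer destination that is not an ICU ward, since ward codes
are not enumerable in general. The 30-day window is **closed** — day 30
counts — and computed on calendar-day differences of the minute-resolution
timestamps; the boundary is configurable. Criterion (2) carries no textual
window, so it is unbounded within the admission by default with an optional
`ward_death_window_days` bound; note that an in-hospital death (discharge
time equal to death time) that fails a configured bound still satisfies
criterion (4) with a day difference of zero. The next ICU admission for
criterion (3) is read from a per-stay `next_icu_intime` field or, when
absent, inferred from later stays of the same patient — the explicit field
is this package's abstraction for index-stay cohorts whose returns are not
materialized as separate rows. Labelling is a pure function of each stay's
timeline: permuting stay order permutes labels with it.

De-identified ages above 89 (recorded as about 300 by the common age-shift
convention) are normalized to 90 before the adult (>= 18) filter; this is
needed for real exports and harmless on synthetic data.

## Semantic annotation

Free-text annotation is retrieval followed by selection. The term index
holds one entry per primary label and per synonym, normalized by
case-folding, punctuation stripping and whitespace collapsing (the
normalization is part of the contract, since it decides what "exact match"
means). Retrieval scores candidates by token TF-IDF cosine and keeps the
top `k = 6`; selection picks the candidate entry with the smallest
Levenshtein distance to the normalized term. All ties — shared index texts,
equal retrieval scores, equal distances — break toward the
lexicographically smallest class identifier, which makes annotation fully
deterministic. A term sharing no token with any entry is unannotated. No
maximum-distance cutoff is applied by default (a configurable cutoff
exists). The in-process TF-IDF index replaces a search-engine dependency:
retrieval is only the candidate generator, and the decisive step is the
Levenshtein selection, which is specified exactly.

Coded features skip retrieval entirely: lab codes and (reconstructed)
ICD9-like codes resolve by identifier lookup, and drug NDC-like codes map
through a user-supplied two-column table into the drug ontology. Unmapped
codes are reported as unmatched, never silently dropped. The
`coverage_score` — the fraction of distinct terms an ontology annotates —
is the package's local surrogate for an ontology-recommender service when
ranking candidate ontologies.

## The synthetic cohort generator

The simulator emulates the *shape* of a critical-care EHR export: the
MIMIC-style table schema (written and read as CSV), free-text initial
diagnoses with a configurable fraction of dirty labels (empty or
punctuation-only strings), ICD9-like codes stored without their period,
LOINC-like lab codes, NDC-like prescription codes, a 17-feature Gaussian
chart-event block with missing-completely-at-random gaps, about 2% of
stays missing their initial diagnosis, and a class-imbalanced outcome
(default readmission rate 0.25, the field's familiar 3:1
negative-to-positive balance). Timestamps are integer minutes from a
common epoch, avoiding timezone and format ambiguity. Outcomes are
engineered in exact-prevalence mode — exactly `round(rate * n)` stays
receive a timeline satisfying one of the four criteria, drawn uniformly —
and negative stays receive deliberately adversarial timelines (late deaths
and late returns just outside the window) so the labeller is actually
exercised.

The predictive signal is planted through the ontology, mirroring the
premise that shared ancestry carries meaning: one subtree per ontology
(about 20% of classes) is designated the signal set, and positive stays
draw their feature concepts from it with odds multiplied by
`signal_strength` (default 4; strength 1 plants nothing). Chart events and
demographics carry no signal, so any recovered performance is attributable
to the annotation-embedding path.

What the simulator does **not** emulate — and what passing tests therefore
do not show about real data: realistic clinical vocabularies or code
frequency distributions, informative (non-random) missingness, temporal
dynamics within chart events, correlated comorbidity structure, multiple
stays per patient, or annotation ambiguity at the scale of real clinical
text. The pipeline's behaviour on real exports depends on those properties;
the synthetic results establish mechanical correctness and signal
recoverability, not clinical performance.

## Evaluation

Stratified k-fold cross-validation (default `k = 5`; stratification keeps
each fold's prevalence within one instance of the cohort's, which matters
at 3:1 imbalance). Four classifiers with pinned, unoptimized
hyperparameters: logistic regression (unpenalized GLM), random forest (100
probability trees, single-threaded, seeded), Gaussian naive Bayes
(training-constant columns dropped), and an RBF SVM (cost 1). The SVM
contributes decision values rather than calibrated probabilities — AUROC
and AUPRC only need a ranking, and calibration would add an unspecified
step. Confusion matrices use a fixed 0.5 probability threshold (decision
value 0 for the SVM).

AUROC is computed by the rank-sum identity (ties count one half); AUPRC by
right-continuous step interpolation with tied scores grouped. Chart-event
imputation uses training-fold medians only; an all-missing training column
falls back to zero. Configurations are compared per model and metric with
the two-sample Kruskal–Wallis test (chi-square approximation, df = 1,
tie-corrected) across fold values, with no multiple-testing correction; a
fully separated pair of five-fold samples bottoms out near p = 0.009, which
is the floor any such comparison can reach. Identical constant samples
degenerate to a warning and p = 1.

The annotation ablation keeps a per-stay uniform sample of
`ceiling(f * n)` annotations (never emptying a stay) and re-aggregates the
patient vectors from the embedding space trained on the full KG. Retraining
the space per ablation draw was considered and rejected: re-aggregation
isolates the quantity of interest — how much of the representation's
predictive content survives annotation loss — from retraining variance, and
keeps a 3-fraction x 5-seed grid tractable.

## Numerical and reproducibility choices

* Every stochastic step (label engineering, walk sampling, skip-gram and
  TransE training, fold assignment, ablation, permutation) is seeded;
  sub-seeds are derived arithmetically from the master seed and kept within
  32-bit range. Training is single-threaded, so runs are bit-reproducible.
* Skip-gram: window 5, 5 epochs, 5 negative samples, initial learning rate
  0.025 with linear decay, negative-sampling table built from unigram
  counts to the 0.75 power. These are pinned explicitly rather than left to
  a library default so that "default" is meaningful across environments.
* TransE: margin 1, learning rate 0.01, 100 epochs, L2 scoring by default,
  initialization uniform in `[-6/sqrt(d), 6/sqrt(d)]`, relations normalized
  once at initialization, entities after every epoch.
* Embedding width defaults to 300 everywhere (so the four-ontology
  concatenation is 1200); the package's synthetic benchmark configuration
  uses a 150-class general ontology, 2000 stays and 128-dimensional
  embeddings — widths in this range showed no benefit over 300 on the toy
  task, and the narrower space keeps the full benchmark (embedding,
  permutation null, ablation grid) comfortably reproducible on one CPU.
* Degenerate inputs are contracts, not surprises: empty annotation sets
  embed to zero vectors; an isolated vertex yields the lone root walk;
  single-class label vectors make the metrics error out rather than return
  a number; short ICD9 codes are returned unchanged with a flag; codes
  already containing a period pass through untouched (idempotence).

## Known limitations

Walk enumeration is exhaustive before capping, which is exact for
tree-like ontologies but can be expensive on dense multi-parent graphs;
the cap bounds the output, not the enumeration. The N-Triples reader
implements only the subset of the format the package writes (URI and plain
literal objects, no blank nodes, no datatype or language tags). OWL
semantics beyond subclass edges and labels are out of scope — "inference"
means transitive closure of the subclass relation. The four classifiers are
intentionally classical; sequence models over chart-event time series are
out of scope.
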
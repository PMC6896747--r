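---
title: "Evaluating class-imbalance strategies for citation screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating class-imbalance strategies for citation screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Screening citations for a systematic review is a binary text-classification
problem with a brutal class ratio: of the hundreds to thousands of records a
bibliographic search returns, usually fewer than one in twenty ends up
included. Classifiers trained on such data tend to favour the majority
(irrelevant) class, and a family of preprocessing remedies — resampling the
training data towards balance — is routinely recommended. `citescreen`
implements a complete, leakage-safe evaluation pipeline for that question:
it measures, review by review, how much random undersampling (RUS) and
random oversampling (ROS) at 50:50 and 35:65 minority:majority ratios change
the cross-validated AUC-ROC of four standard classifier families, and pools
those changes across reviews with a fixed-effect meta-analysis.

Everything runs on synthetic corpora shaped like real screening datasets, so
the pipeline is fully testable offline; real corpora in the package's
delimited format drop into the same functions.

## The pipeline, step by step

**Preprocessing** (`preprocess_text()`, `add_bigrams()`, `build_dtm()`).
Title and abstract are concatenated, lowercased, and every character outside
`a-z` becomes a space; tokens shorter than two letters are dropped as
punctuation artifacts. Tokens are stemmed with the classic Porter (1980)
algorithm, implemented in the package and pinned by a frozen fixture of
reference stems so stemmer drift cannot pass silently. Bigrams of adjacent
stems, joined by `_`, are appended as single tokens *after* stemming.
No stop-word removal is applied and no field weighting distinguishes title
from abstract. The resulting document-term matrix (DTM) holds raw term
frequencies in a sparse `Matrix` and is typically ~99% zeros at realistic
corpus sizes.

**Fold-wise TF-IDF with top-4% retention** (`fit_tfidf()`,
`apply_tfidf()`, `align_features()`). Within every cross-validation fold the
weighting is fitted on the training rows only: `idf(t) = ln(N/df(t))` with
no smoothing and no additive shifts, where `df` counts training documents
containing `t`. Tokens are ranked by their total TF-IDF mass over the
training rows (a scale-stable, deterministic statistic; ties break
lexicographically) and the top `ceiling(0.04 V)` of the `V` training-observed
tokens are retained, never fewer than one. The held-out fold is then
*aligned* to that vocabulary — unseen columns dropped, missing ones added as
zeros, order matched — and rescaled with the fitted idf values. Tokens that
occur only in held-out documents can never influence the fit; a test asserts
the fitted model is bit-identical when such tokens are deleted from the
corpus. No row normalisation (cosine/L2) is applied.

**Resampling** (`random_undersample()`, `random_oversample()`). Balancing
acts on the already-TF-IDF-weighted training rows only, after the fold
split — the held-out fold is never resampled. For target minority share `s`,
RUS keeps all minority rows and `floor(n_min (1-s)/s)` random majority rows;
ROS keeps everything and duplicates random minority rows with replacement up
to `ceiling(n_maj s/(1-s))`. Floor and ceiling are chosen so the achieved
minority share is never *below* the requested one; the discrepancy is at
most one part in the resampled total unless the data are already more
balanced than the target, in which case nothing is removed or added. No
synthetic interpolation (SMOTE-style) is used — the methods under study are
pure random resampling.

**Evaluation** (`cross_validate_strategy()`, `run_grid()`). Five-fold CV,
stratified by class: with as few as five positives per review,
unstratified folds could lack positives entirely and leave the AUC
undefined, so stratification is a structural necessity here rather than an
optimisation. Ten random hyperparameter draws per learner are scored by mean
fold AUC and the best draw is selected (first draw wins ties, for
determinism); the reported fold AUCs are the chosen draw's, matching the
usual random-search-with-CV reporting convention. Note this makes the
reported AUC an in-sample maximum over draws, which on null data biases the
chosen value slightly above 0.5 — a property of the design being emulated,
not a defect. AUC is the Mann-Whitney pairwise estimate with ties counted
one half, computed from ranks and verified against an all-pairs brute-force
oracle.

The four learner families delegate their solvers to established
implementations behind a uniform fit/score interface that must emit a
continuous positive-class score: linear-kernel SVM decision values
(`e1071`), k-NN neighbour vote shares (`class`), random-forest class
probabilities (`ranger`, 500 trees, single-threaded for reproducibility)
and elastic-net logistic regression probabilities (`glmnet`). Sampling
ranges for the tuned parameters are: cost `C` log-uniform on
[1e-2, 1e2]; `k` uniform on [1, min(30, n_train - 1)]; `mtry` uniform on
[1, max(2, round(2 sqrt(p)))]; `lambda` log-uniform on [1e-4, 1] with
`alpha` uniform on [0, 1]. A learner error on a fold invalidates that draw;
a cell where every draw fails is recorded as `failed` and excluded
downstream — mirroring how k-NN failures are reported as missing cells in
screening benchmarks — never silently imputed.

**Meta-analysis** (`compute_deltas()`, `pool_fixed_effect()`,
`forest_grid()`). For each review and learner, the delta-AUC of a balanced
strategy is its mean CV AUC minus the unbalanced baseline's. Its variance
treats the two CV means as independent, `(sd_b^2 + sd_0^2)/k`; fold-level
pairing would require per-fold bookkeeping the compared quantities do not
expose, and independence is the conservative default. Because near-ceiling
cells often have all five folds at AUC 1 (zero CV dispersion), the variance
is floored at `1e-6` before weighting — otherwise such cells would carry
infinite weight and the fixed-effect model would be undefined. The floor is
configurable and reported. Pooling is plain inverse-variance fixed-effect
with normal (z) 95% intervals; the implementation is closed-form and is
cross-checked in the tests against `metafor::rma(method = "FE")`. With four
learners and four balanced strategies the result is the standard 16-panel
forest grid, rendered with base graphics; the panel data table, not the
drawing, is the tested surface.

## Reproducibility model

Every random choice derives from one master seed through a deterministic
string hash: fold assignment depends on (seed, review), so all twenty
strategies of a review share identical held-out folds — the leakage and
comparability guarantee — while each (review, learner, balancing) cell gets
its own stream for resampling, hyperparameter draws and stochastic
learners, making any cell reproducible in isolation. Re-running a grid with
the same master seed reproduces every fold assignment, resample and AUC
bit-for-bit.

## What the synthetic generator emulates — and what it does not

`generate_corpus()` draws negative documents from a Zipf(1) background
vocabulary (2,000 word types by default) and positive documents from a
mixture: each word comes from a disjoint 100-type topic vocabulary with
probability `separation`, else from the background. Title and abstract
lengths are Poisson (means 10 and 120 words — compact but in the range of
real bibliographic records) with a one-word minimum. Words are synthetic
alphabetic strings chosen to be invariant under stemming, so preprocessing
is exercised without confounding the generator's distributions.
`default_study_specs()` reproduces the size profile of a 14-review
screening study — per-review document counts of 418, 209, 413, 206, 412,
832, 209, 623, 413, 1675, 209, 414, 418 and 1043 (7,494 in total) — with
positives at `floor(docs/21)`, the at-least-20:1 imbalance convention
(per-review positive fractions are a stated convention of this package;
published size profiles rarely include them).

The default `separation` of 0.6 places default pipelines in the
high-but-not-perfect AUC regime (well above 0.9 for the margin-based
learners) that screening corpora built from search-string negation exhibit,
because their classes are well separated by design. At `separation = 0` the
two classes are exchangeable by construction, giving an exact null for
calibration checks.

What the generator does *not* model: real morphology (stemming is a
near-no-op on synthetic words), stop-word structure, MeSH terms and other
metadata, citation-network or temporal structure, and topic drift within a
class. Passing tests therefore demonstrate that the pipeline's machinery —
leakage control, resampling arithmetic, selection, pooling — behaves
correctly and that signal/null regimes are recovered; they do not establish
expected AUC levels on any particular real corpus.

## Problem sizes used by the shipped checks

The package's acceptance-style tests and the `scripts/acceptance.R` report
run the complete 20-strategy grid on the four largest study-shaped reviews
scaled to a quarter of their size (418, 260, 208 and 155 documents; 7 to 19
positives each). Choosing the four *largest* reviews keeps at least seven
positives per review, so per-fold AUCs rest on enough positive-negative
pairs for the signal (≥ 0.95) and null ([0.35, 0.65]) bands to be
meaningful; the full 14-review, full-scale grid runs through exactly the
same code path and is a matter of compute, not capability.

## Design choices that were genuinely open

* **Result objects over a single fitting function.** The package follows
  the classic R modelling idiom of classed S3 results with `print`,
  `summary`, `as.data.frame` and `plot` methods (`cv_result`,
  `strategy_grid`, `pooled_estimate`, `forest_grid`), but deliberately has
  no single `fit()` entry point: the estimand is a grid of cross-validated
  comparisons, not one model, and `run_grid()` is the natural top.
* **"At least 1:20"** is implemented as a configurable
  negatives-per-positive cap (`subsample_negatives()`, default 20): corpora
  less imbalanced than the cap pass through unchanged, which matches the
  observed ratios of published screening corpora (e.g. 75:1600 ≈ 1:21.3).
* **idf dialect.** `ln(N/df)` without smoothing is the textbook form; since
  every retained token has `df ≥ 1` on its training fold, no smoothing is
  needed, and the dialect is pinned by oracle tests.
* **Ranking statistic for retention.** Total TF-IDF mass over training
  documents; document-frequency or maximum-weight rankings are defensible
  alternatives, but mass is scale-stable and makes the deterministic
  tie-break natural.
* **Hyperparameter distributions.** Log-uniform for scale-like parameters
  (`C`, `lambda`), uniform for bounded ones (`alpha`, `k`, `mtry`) — the
  standard random-search choice when a study delegates tuning to a
  toolkit's random sampler without documenting it.
* **Variance floor `1e-6`** corresponds to a CV standard deviation of about
  0.0022 on the AUC scale for both arms jointly — far below any difference
  of practical interest, so it regularises weights without distorting
  estimates.

## Known limitations

* The Porter implementation is the original 1980 algorithm; later Snowball
  revisions (e.g. the extra `bli`/`logi` rules) are intentionally absent.
* Scores are not calibrated; only rank-based evaluation (AUC) is supported.
* Fixed-effect pooling only — no random-effects model, heterogeneity
  statistics or publication-bias diagnostics, which the evaluated design
  does not use.
* k-NN vote shares take few distinct values, so its fold AUCs are coarse;
  this is faithful to the method, not a numerical issue.
* The generator's independence assumptions (words i.i.d. within a
  document) understate the burstiness of real text; sparsity and imbalance
  are matched, token co-occurrence structure is not.
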
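---
title: "Methods: longitudinal psycholinguistic screening of cognitive decline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: longitudinal psycholinguistic screening of cognitive decline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem and the model

Language production degrades early and progressively in mild cognitive
impairment (MCI) and Alzheimer's disease (AD): vocabulary narrows, syntax
simplifies, and discourse loses referential coherence. Routine clinical
notes record a patient's language repeatedly over years, so a longitudinal
note corpus carries an indirect, non-invasive signal of cognitive state.
`cognitrace` classifies patients into Normal / MCI / AD from such corpora
with a hierarchical multimodal model:

1. **Local text encoding.** Each note $d_{p,t}$ is tokenized and encoded to
   a dense vector $s_{p,t}$ by a pluggable note encoder. The default is a
   hashed embedding bag (mean of token embeddings); the adapter interface
   (`name`, `dim`, `max_length`, `encode(tokens)`) admits long-context
   transformer encoders without touching the rest of the pipeline.
2. **Temporal progression.** The time-ordered note embeddings pass through
   a 2-layer bidirectional LSTM; additive attention over the per-note
   states $u_{p,t}$ yields attention weights $\alpha_t$ (a simplex) and the
   patient vector $v_p = \sum_t \alpha_t u_{p,t}$.
3. **Concept-graph reasoning.** Clinical concepts are dictionary-matched
   per note (longest match, case-insensitive); a patient graph $G_p$
   connects concepts co-occurring in the same note or in consecutive notes.
   Three GraphSAGE-mean layers with a neighbourhood sample of 10 and a
   200-node cap propagate co-occurrence structure; mean pooling yields
   $g_p$. Diagnostic concepts named by the mask policy never enter a graph.
4. **Psycholinguistic biomarkers.** Nine deterministic note-level features
   (below) are aggregated to the patient level with the temporal attention
   weights and projected $9 \to 128 \to 64$ with ReLU layers to $f'_p$.
5. **Gated cross-modal fusion.** The four modality embeddings are projected
   to a common 512-dimensional space, attend over each other with 4-head
   attention, and are combined by a sigmoid gate over their concatenation;
   a GELU output map with layer normalization gives the fused $z_p$, and a
   softmax head gives $\hat y_p$.
6. **Objectives.** Training minimizes mean cross-entropy; an InfoNCE-style
   contrastive progression loss at temperature $\tau = 0.05$ (positives:
   same patient, visits 180-1095 days apart; negatives: different
   patients) is evaluated on the recurrent states and enters the logged
   total $\mathcal{L} = \mathcal{L}_{cls} + \lambda \mathcal{L}_{con}$.

## The nine psycholinguistic features

| feature | definition | range |
|---|---|---|
| TTR | unique case-folded types / tokens per note | (0, 1] |
| MATTR | mean TTR over sliding 50-token windows (stride 1) | (0, 1] |
| content/function ratio | content tokens / all tokens (closed function-word list) | [0, 1] |
| MLU | word tokens per clause | > 0 |
| parse depth | mean per-sentence depth proxy | >= 1 |
| subordination index | subordinate clauses / clauses | [0, 1] |
| entity overlap | shared entities of consecutive sentences / entities of the later sentence | [0, 1] |
| lexical cohesion | mean cosine of consecutive sentence embeddings | [-1, 1] |
| referential clarity | 1 - (pronouns without an antecedent within k sentences) / pronouns | [0, 1] |

Undefined values (an empty note, a single sentence, zero clauses) are NA
sentinels, excluded from aggregation with weight renormalization rather
than imputed, so degenerate notes cannot fabricate signal.

**Segmentation adapter.** The default segmenter is deterministic:
sentences split on terminal punctuation, clauses on commas/semicolons, a
clause is subordinate when it opens with a subordinating conjunction from
a closed lexicon, and sentence embeddings for cohesion are L2-normalized
bag-of-words vectors. A constituency parser can be swapped in through the
`parser` argument of `note_vector()`. Two consequences are worth naming:

* The *parse depth* proxy (1 + multi-clause + subordinate count per
  sentence) lives on a much smaller scale than true constituency depth.
  It preserves ordering between classes but its absolute values are not
  comparable to constituency-tree depths, and the synthetic generator
  therefore does not calibrate it.
* *Content vs function* words are decided by a closed stop list, and the
  ratio is defined as content/(content + function), the bounded reading
  consistent with class profiles at or below 0.5. Referential clarity uses
  "1 - ambiguity rate" (bounded) rather than an unbounded inverse count,
  with an antecedent search window of k = 2 sentences by default.

# The synthetic corpus generator

Clinical note corpora with longitudinal dementia labels are access
restricted, so the package ships a seeded generator that serves as the
test substrate. It emulates:

* three classes with class-conditional profiles for the nine features
  (per-class mean and SD), concept-domain mixtures that shift from
  independence vocabulary toward care-dependence vocabulary with severity,
  notes-per-patient drawn at mean 15.1 (SD 7.4, clamped to [3, 40]), and
  longitudinal spans of 1-6 years;
* progressive within-patient drift for MCI and AD: per-visit feature
  targets interpolate linearly from a healthier-than-class-mean start to a
  symmetric end point, so every patient's visit-average equals the class
  mean while later visits look worse than earlier ones — the trajectory
  shape is a generator definition (the profiles are cross-sectional), and
  nothing downstream depends on more than its sign;
* configurable label noise (`inject_label_noise()` flips exactly
  `round(rate * n)` patients to a different class) and distribution shift
  (`shifted_cohort()`: feature-mean deltas, note-length scaling, disjoint
  surface vocabulary).

**Calibration by construction.** Four features are realized exactly per
note: the note is assembled as template clauses over a closed lexicon with
a token budget `T = round(C * MLU_target)`, a distinct-type budget
`round(TTR_target * T)` enforced while filling slots, a subordinator
opening `round(subordination_target * C)` clauses, and exactly five
pronouns of which an apportioned number is placed in noun-free opening
sentences (ambiguous) versus after noun-bearing sentences (clear). Visit
noise is drawn from a shuffled, exactly-zero-mean normal grid and
rounding residues are apportioned corpus-wide, so class means track the
configured targets to about three decimals; the remaining five features
are emergent properties of the same token stream (the content/function
ratio is steered toward its target, MATTR, cohesion, entity overlap and
parse depth simply emerge). Because the lexicon is closed and clause
templates are punctuation-unambiguous, the heuristic segmenter parses
generated text without error — calibration tests therefore measure the
generator/extractor pair, not parser noise.

**What passing tests do not show.** Generated notes are not clinical
English: no misspellings, no telegraphic fragments, no section-specific
jargon, no label noise in the default corpus, and the class signal is
strong by design (the profile means are several patient-level standard
errors apart). Passing the calibration and separability suites shows the
machinery is correct and the pipeline leakage-free, not that comparable
accuracy would be reached on real EHR corpora.

# Training regime and hyperparameters

The representation stack is initialized with seeded Xavier weights and
kept fixed; the softmax classification head is trained with AdamW
(decoupled weight decay 0.01) on fused features standardized with
training-split statistics. This random-feature regime is the deliberate
desk-scale default: it keeps every forward component testable and
bitwise-reproducible on one CPU, and a linear head on the 512-dimensional
fused representation separates the default study conditions essentially
perfectly. Fine-tuning the full stack would require gradients through the
LSTM/GraphSAGE/fusion layers and pretrained text encoders, which is out of
scope for this implementation.

Defaults (config-exposed): temporal state 256 (2 layers), GraphSAGE 3
layers / neighbourhood 10 / 200-node cap, fusion width 512 with 4 heads,
psych projection 128 to 64, tau 0.05, lambda 0.5 (the mixing weight has no
published value; 0.5 keeps the two terms at comparable magnitude at tau =
0.05), drop-path 0.1, batch-mean cross-entropy (`loss_reduce = "sum"`
recovers the exact summed form), early stopping on validation macro F1
with patience 5. Two choices deliberately differ from a fine-tuning
setup, because one "epoch" here is a single full-batch gradient step: the
head learning rate is 0.05 (a transformer fine-tuning rate of 2e-5 would
not move a linear head in 50 steps), and early stopping only engages
after `min_epochs = 30` burn-in steps — with patience counted from step
one, a flat early validation plateau stops training before the head has
fit at all.

The contrastive term is computed on the (fixed) recurrent states, so it
is constant with respect to the head parameters; it is reported in the
logged total loss, and setting lambda to 0 reduces the objective to the
classification loss exactly.

# Evaluation protocol

* **Leakage-safe splitting.** All partitions are by patient, stratified
  by class to within one patient of the 70/15/15 targets; sentinel
  imputation and feature standardization use training-split statistics
  only; ADASYN oversampling and augmentation refuse non-train splits.
* **Monte Carlo cross-validation** resamples stratified patient-level
  partitions (desk default 50 folds; the fold count is config-reachable),
  reusing fixed fused features and retraining the head per fold.
* **Stress tests.** `permutation_label_test()` retrains on
  class-preservingly permuted labels: held-out accuracy collapses to
  about 1/3 and macro one-vs-rest AUC to about 0.5 on the balanced
  default corpus. `truncate_before_label()` restricts records to notes at
  least a configured gap before the reference date (the final note by
  default; a `diagnosis_date` labels column overrides it).
* **Temporal stability** is defined here as the population variance, over
  note-sequence prefixes, of the probability assigned to the patient's
  final predicted class, averaged over patients with at least two notes —
  an interpretation, since only "variance across visits" is specified.
* **Statistics.** DeLong's test (placement-value implementation,
  one-vs-rest per class with a Stouffer macro summary for three classes),
  the continuity-corrected McNemar test, patient-level percentile
  bootstrap intervals, and permutation p-values.
* **Cross-cohort alignment.** Orthogonal Procrustes (SVD closed form,
  optional isotropic scale) fitted on class-conditional centroid anchors
  (cross-cohort row pairing does not exist, so centroids are the anchor
  choice; documented as an interpretation) and applied globally; RBF-kernel
  MMD (median-heuristic bandwidth) is reported before and after alignment.

# Numerical choices and degenerate inputs

* Timestamp ties within a patient break by lexicographic note id; all gap
  arithmetic is in whole days.
* Neighbour sampling in the graph encoder is seeded by a hash of
  (patient id, node id), so node insertion order never changes results.
* Softmax and log-sum-exp computations subtract the maximum; probabilities
  are floored at 1e-12 inside logs.
* Empty graphs pool to a zero vector with a no-concepts flag; empty notes
  yield all-sentinel feature vectors and are excluded from aggregation;
  a patient whose every note is sentinel for a feature stays sentinel and
  is imputed with the training-split mean before projection.
* Zero discordant pairs make McNemar degenerate (p = 1, flagged); a
  single-class label vector is fatal for DeLong; rank-deficient Procrustes
  anchors fall back to the pseudo-inverse path with a warning.

# Problem sizes

The test and acceptance suites run on corpora of 10-100 patients per
class (3-40 notes each, about 100-140 tokens per note), 500 notes per
class for calibration, 20 permutation replicates, and 50-fold Monte Carlo
cross-validation as the desk default; the published protocol's
10,000-fold and 10,000-resample settings remain config-reachable.

# Known limitations

* The default encoders are untrained random-feature maps; absolute
  performance numbers on real corpora would require plugging in trained
  encoders and fitting more than the head.
* The heuristic segmenter has no true parse: parse depth and entity
  overlap are proxies, and clause boundaries rely on punctuation.
* The concept lexicon is a toy dictionary (about 60 phrases); real UMLS
  coverage requires an external dictionary in the same TSV format.
* Back-translation and masked-LM augmentation are adapter stubs; only
  synonym substitution is bundled.
* Molecular covariates are emitted for completeness but consumed by
  nothing, as their integration into the model is unspecified.
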
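# cognitrace

Patient-level screening of cognitive decline — Normal, mild cognitive
impairment (MCI), Alzheimer's disease (AD) — from longitudinal clinical
note corpora.

Language degrades early in neurodegeneration: vocabulary narrows (lower
type–token ratio), syntax simplifies (shorter clauses, less
subordination), and discourse loses referential coherence (more pronouns
without antecedents). Because clinicians document the same patient
repeatedly over years, routine notes carry a longitudinal, non-invasive
proxy for cognitive state. `cognitrace` is an R implementation of a
hierarchical multimodal classifier over such corpora, aimed at clinical
NLP researchers who need a fully testable, dependency-light desk-scale
pipeline with leakage-safe evaluation.

For each patient $p$ with time-ordered notes $d_{p,1},\dots,d_{p,T}$ the
model combines four modality embeddings:

* $s_{p,t}$ — note text embeddings from a pluggable encoder (default: a
  hashed embedding bag; transformer adapters plug in unchanged);
* $v_p = \sum_t \alpha_t u_{p,t}$ — a 2-layer bidirectional LSTM over the
  note sequence with additive temporal attention $\alpha$;
* $g_p$ — a GraphSAGE-mean encoding (3 layers, neighbourhood 10, ≤200
  nodes) of the patient's concept co-occurrence graph, built from
  dictionary-matched clinical concepts with diagnostic concepts masked;
* $f'_p$ — nine psycholinguistic biomarkers (TTR, MATTR,
  content/function ratio, MLU, parse depth, subordination index, entity
  overlap, lexical cohesion, referential clarity), attention-aggregated
  to the patient level and projected $9\to128\to64$.

The four embeddings are projected to a shared 512-dimensional space,
fused by multi-head cross-modal attention with a sigmoid gate, and
classified by a softmax head; training minimizes
$\mathcal{L} = \mathcal{L}_{cls} + \lambda\,\mathcal{L}_{contrast}$,
where the contrastive term (InfoNCE, $\tau=0.05$) pulls together
same-patient visits 6 months – 3 years apart. Restricted clinical data
are replaced by a calibrated synthetic corpus generator whose
class-conditional psycholinguistic profiles, within-patient drift and
concept-vocabulary drift are the package's study conditions; see the
methods vignette (`vignettes/cognitrace-methods.Rmd`) for the model,
calibration construction and limitations.

## Worked example

```r
library(cognitrace)

corpus <- generate_corpus(20, seed = 7)        # 20 patients per class
splits <- split_patients(corpus, seed = 7)     # stratified 70/15/15 by patient

feature_matrix(corpus[1:2])[1:3, c("patient_id", "note_id", "ttr", "mlu",
                                   "referential_clarity")]
#>      patient_id           note_id   ttr      mlu referential_clarity
#> 1 P_Normal_0001 P_Normal_0001_n01 0.682 12.57143                 0.8
#> 2 P_Normal_0001 P_Normal_0001_n02 0.738 13.55556                 1.0
#> 3 P_Normal_0001 P_Normal_0001_n03 0.700 13.33333                 1.0

model <- train_cognitrace(corpus, splits, cognitrace_config(), seed = 7)
ids <- vapply(corpus, function(r) r$patient_id, "")
heldout <- corpus[ids %in% splits$patient_id[splits$split == "test"]]
preds <- predict(model, heldout)
head(preds, 3)
#>      patient_id p_Normal p_MCI p_AD   pred
#> 1 P_Normal_0001        1     0    0 Normal
#> 2 P_Normal_0010        1     0    0 Normal
#> 3 P_Normal_0019        1     0    0 Normal

compute_metrics(preds, vapply(heldout, function(r) r$label, ""))
#> accuracy 0.778 | macro F1 0.750 | bal.acc 0.778 | AUC 0.833 | MCC 0.722 | kappa 0.667
```

Per-note feature rows show the expected class profile (Normal-range TTR
near 0.71, clauses of 12–14 tokens, high referential clarity); the
held-out metric line is what a 9-patient test split of this 60-patient
toy corpus supports — at the default study size of 100 patients per
class the held-out macro F1 is 0.95–1.0 (see the separability test in
`tests/testthat/test-acceptance.R`). Explainability mirrors the model's
structure:

```r
att <- export_attention(model, heldout[[1]])
att$gates
#> gates: local=0.52 temporal=0.51 graph=0.56 psych=0.39

counterfactual_substitute(model, heldout[[length(heldout)]], corpus)
#> counterfactual P(AD): 1.000 -> 0.000
```

The counterfactual replaces an AD patient's psycholinguistic profile
with healthy Normal-class means and re-scores: the predicted AD
probability collapses, confirming the prediction is driven by the
linguistic biomarkers rather than other modalities.

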
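# Attribution and counterfactual tooling: temporal/modality attention
# export, permutation-based feature importance, and healthy-baseline
# substitution. All outputs are pure functions of (model, input, seed).

#' Export attention and gate allocation for one patient
#'
#' @param model A `cognitrace_model`.
#' @param record A patient record.
#' @return List: `temporal` (data.frame note_id, alpha), `gates`
#'   (per-modality gate values), `modality_attention` (per-head attention
#'   mass of each modality query over the modality set), `prediction`.
#' @export
export_attention <- function(model, record) {
  cfg <- model$config
  S <- do.call(rbind, lapply(record$notes, encode_note, encoder = model$params$encoder))
  mods <- variant_modalities(cfg$variant)
  te <- temporal_encode(S, model$params$temporal)
  bundle <- list(local = colMeans(S))
  if ("temporal" %in% mods) bundle$temporal <- te$v
  if ("graph" %in% mods) {
    g <- build_patient_graph(record, policy = mask_policy(),
                             max_nodes = cfg$max_nodes)
    bundle$graph <- as.numeric(encode_graph(g, model$params$graph))
  }
  if ("psych" %in% mods) {
    vecs <- do.call(rbind, lapply(record$notes, note_vector))
    f_p <- aggregate_patient(vecs, te$alpha)
    bundle$psych <- project_psych(f_p, model$params$psych,
                                  impute = model$impute_means)
  }
  fz <- fuse(bundle, model$params$fusion, training = FALSE)
  pred <- classify(model_standardize(model, matrix(fz$z, nrow = 1L)), model$head)
  list(
    temporal = data.frame(
      note_id = vapply(record$notes, function(n) n$note_id, character(1)),
      alpha = te$alpha),
    gates = fz$gates[fz$present],
    modality_attention = fz$attn[!vapply(fz$attn, is.null, logical(1))],
    prediction = stats::setNames(as.numeric(pred$probs), CLASSES)
  )
}

#' Permutation importance of a psycholinguistic feature
#'
#' Shuffles one patient-level feature column across patients, re-runs the
#' psych projection and fusion, and reports the macro-F1 drop relative to
#' the intact features, averaged over shuffles.
#'
#' @param model A `cognitrace_model`.
#' @param records Evaluation records (held-out patients).
#' @param feature Feature name (one of the nine) .
#' @param n_shuffles Number of shuffles (default 10).
#' @param seed Integer seed.
#' @return List `importance` (mean macro-F1 drop), `per_shuffle`,
#'   `baseline_f1`.
#' @export
feature_importance <- function(model, records, feature, n_shuffles = 10L,
                               seed = 1L) {
  stopifnot(feature %in% PSYCH_FEATURES)
  labs <- unname(corpus_labels(records))
  feats <- compute_patient_features(records, model$params, model$config,
                                    impute_means = model$impute_means)
  base_f1 <- macro_f1(predict(model, records, features = feats)$pred, labs)
  psych <- feats$psych_raw
  if (is.null(psych)) stopf("variant '%s' has no psycholinguistic modality",
                            model$config$variant)
  drops <- withr::with_seed(seed, {
    vapply(seq_len(n_shuffles), function(b) {
      perm <- psych
      perm[, feature] <- perm[sample.int(nrow(perm)), feature]
      Z <- rescore_with_psych(model, records, feats, perm)
      cl <- classify(model_standardize(model, Z), model$head)
      base_f1 - macro_f1(CLASSES[max.col(cl$probs)], labs)
    }, numeric(1))
  })
  list(importance = mean(drops), per_shuffle = drops, baseline_f1 = base_f1)
}

# Recompute fused embeddings with a substituted patient-level psych matrix,
# leaving all other modalities untouched.
rescore_with_psych <- function(model, records, feats, psych_matrix) {
  cfg <- model$config
  mods <- variant_modalities(cfg$variant)
  Z <- matrix(0, length(records), cfg$fusion_dim)
  for (i in seq_along(records)) {
    rec <- records[[i]]
    S <- do.call(rbind, lapply(rec$notes, encode_note, encoder = model$params$encoder))
    bundle <- list(local = colMeans(S))
    if ("temporal" %in% mods) bundle$temporal <- feats$u[[i]] |>
        (\(u) as.numeric(crossprod(u, feats$alpha[[i]])))()
    if ("graph" %in% mods) {
      g <- build_patient_graph(rec, policy = mask_policy(),
                               max_nodes = cfg$max_nodes)
      bundle$graph <- as.numeric(encode_graph(g, model$params$graph))
    }
    bundle$psych <- project_psych(psych_matrix[i, ], model$params$psych,
                                  impute = model$impute_means)
    Z[i, ] <- fuse(bundle, model$params$fusion, training = FALSE)$z
  }
  Z
}

#' Counterfactual healthy-baseline substitution
#'
#' Replaces a patient's psycholinguistic profile with the healthy baseline
#' (Normal-class feature means, by default estimated from supplied
#' reference records) and reports the predicted AD probability before and
#' after. Non-psycholinguistic modalities are untouched.
#'
#' @param model A `cognitrace_model`.
#' @param record Patient record to perturb.
#' @param healthy_profile Length-9 baseline vector, or reference records
#'   from which Normal-class means are computed.
#' @return List `p_ad_before`, `p_ad_after`, `delta`, `probs_before`,
#'   `probs_after`.
#' @export
counterfactual_substitute <- function(model, record, healthy_profile) {
  if (is.list(healthy_profile) && !is.numeric(healthy_profile)) {
    normals <- Filter(function(r) r$label == "Normal", healthy_profile)
    if (length(normals) == 0) stopf("no Normal-class reference records supplied")
    healthy_profile <- colMeans(patient_psych_matrix(normals), na.rm = TRUE)
  }
  feats <- compute_patient_features(list(record), model$params, model$config,
                                    impute_means = model$impute_means)
  before <- classify(model_standardize(model, feats$Z), model$head)$probs[1, ]
  perm <- matrix(as.numeric(healthy_profile), nrow = 1,
                 dimnames = list(NULL, PSYCH_FEATURES))
  Z_after <- rescore_with_psych(model, list(record), feats, perm)
  after <- classify(model_standardize(model, Z_after), model$head)$probs[1, ]
  list(p_ad_before = unname(before["AD"]), p_ad_after = unname(after["AD"]),
       delta = unname(after["AD"] - before["AD"]),
       probs_before = before, probs_after = after)
}
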
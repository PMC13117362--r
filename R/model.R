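# The assembled hybrid classifier.
#
# The representation stack (embedding-bag note encoder, bidirectional LSTM
# with temporal attention, GraphSAGE concept-graph encoder, psycholinguistic
# projection, gated cross-modal fusion) is built once from seeded Xavier
# initialization and kept fixed while the softmax classification head is
# trained with AdamW — a random-feature training regime sized for a single
# CPU. The contrastive progression objective is evaluated on the recurrent
# note states and enters the logged total loss with weight lambda. Ablation
# variants (text-only, +temporal, +graph, full) are instantiated from the
# config alone and share splits, preprocessing and seeds.

#' Model configuration
#'
#' Desk-scale defaults; Table-like hyperparameters of the original
#' architecture (temporal state 256, 3 GraphSAGE layers with neighbourhood
#' 10 and a 200-node cap, fusion width 512, psych projection 128 -> 64,
#' contrastive temperature 0.05, weight decay 0.01, early-stopping patience
#' 5) are kept; the head learning rate defaults to 0.05, appropriate for
#' fitting a linear head rather than fine-tuning a transformer stack.
#'
#' @param variant One of `"full"`, `"transformer_only"`, `"bilstm"`,
#'   `"gnn"`, `"no_psych"`.
#' @param ... Overrides for any default field.
#' @return A `cognitrace_config` list.
#' @export
cognitrace_config <- function(variant = "full", ...) {
  cfg <- list(
    variant = variant,
    embed_dim = 32L, vocab_size = 4096L, max_length = 4096L,
    lstm_hidden = 256L, lstm_layers = 2L,
    graph_dim_in = 16L, graph_dim = 32L, graph_layers = 3L,
    neighborhood = 10L, max_nodes = 200L,
    psych_dims = c(128L, 64L),
    fusion_dim = 512L, n_heads = 4L,
    tau = 0.05, lambda = 0.5, p_drop = 0.1,
    lr = 0.05, weight_decay = 0.01,
    epochs = 50L, patience = 5L, min_epochs = 30L,
    loss_reduce = "mean"
  )
  dots <- list(...)
  cfg[names(dots)] <- dots
  variants <- c("full", "transformer_only", "bilstm", "gnn", "no_psych")
  if (!cfg$variant %in% variants) {
    stopf("unknown variant '%s' (use one of %s)", cfg$variant,
          paste(variants, collapse = ", "))
  }
  structure(cfg, class = "cognitrace_config")
}

variant_modalities <- function(variant) {
  switch(variant,
         transformer_only = "local",
         bilstm = c("local", "temporal"),
         gnn = c("local", "graph"),
         no_psych = c("local", "temporal", "graph"),
         full = MODALITIES)
}

#' Build all representation-stack parameters
#'
#' @param config [cognitrace_config()].
#' @param seed Integer seed (distinct sub-seeds are derived per component).
#' @return A `cognitrace_params` list.
#' @export
build_model_params <- function(config = cognitrace_config(), seed = 1L) {
  encoder <- embedding_bag_encoder(dim = config$embed_dim,
                                   vocab_size = config$vocab_size,
                                   max_length = config$max_length,
                                   seed = derive_seed(seed, "encoder"))
  temporal <- temporal_params(config$embed_dim, hidden = config$lstm_hidden,
                              n_layers = config$lstm_layers,
                              seed = derive_seed(seed, "temporal"))
  graph <- graph_encoder_params(dim_in = config$graph_dim_in,
                                dim_hidden = config$graph_dim,
                                n_layers = config$graph_layers,
                                neighborhood = config$neighborhood,
                                max_nodes = config$max_nodes,
                                seed = derive_seed(seed, "graph"))
  psych <- psych_projection_params(dim_in = length(PSYCH_FEATURES),
                                   dims = config$psych_dims,
                                   seed = derive_seed(seed, "psych"))
  dims <- c(local = config$embed_dim, temporal = config$lstm_hidden,
            graph = config$graph_dim, psych = config$psych_dims[2])
  fusion <- fusion_params(dims, d = config$fusion_dim, n_heads = config$n_heads,
                          seed = derive_seed(seed, "fusion"))
  structure(list(encoder = encoder, temporal = temporal, graph = graph,
                 psych = psych, fusion = fusion, seed = seed),
            class = "cognitrace_params")
}

#' Compute fused patient features for a corpus
#'
#' Runs the full representation stack in evaluation mode (no drop-path) and
#' returns the fused embeddings plus per-patient diagnostics (temporal
#' attention, gates, recurrent states, raw psych vectors).
#'
#' @param records Patient records.
#' @param params [build_model_params()].
#' @param config [cognitrace_config()] (its `variant` selects modalities).
#' @param lexicon Concept lexicon (bundled default).
#' @param policy Mask policy used to keep diagnostic concepts out of
#'   graphs.
#' @param impute_means Per-feature values replacing psych sentinels
#'   (defaults to the column means over this corpus).
#' @return A `cognitrace_features` list: `Z` (patients x fusion_dim),
#'   `pids`, `psych_raw`, `u` (per patient), `alpha`, `gates`.
#' @export
compute_patient_features <- function(records, params,
                                     config = cognitrace_config(),
                                     lexicon = NULL, policy = mask_policy(),
                                     impute_means = NULL) {
  lexicon <- lexicon %||% read_concept_lexicon()
  mods <- variant_modalities(config$variant)
  n <- length(records)
  pids <- vapply(records, function(r) r$patient_id, character(1))

  psych_raw <- if ("psych" %in% mods) patient_psych_matrix(records) else NULL
  if (!is.null(psych_raw)) {
    if (is.null(impute_means)) {
      impute_means <- colMeans(psych_raw, na.rm = TRUE)
      impute_means[is.na(impute_means)] <- 0
    }
  }

  Z <- matrix(0, n, config$fusion_dim)
  u_list <- vector("list", n); alpha_list <- vector("list", n)
  gates <- matrix(NA_real_, n, length(MODALITIES),
                  dimnames = list(NULL, MODALITIES))
  for (i in seq_len(n)) {
    rec <- records[[i]]
    S <- do.call(rbind, lapply(rec$notes, encode_note, encoder = params$encoder))
    bundle <- list(local = colMeans(S))
    te <- NULL
    if ("temporal" %in% mods || "psych" %in% mods) {
      te <- temporal_encode(S, params$temporal)
      u_list[[i]] <- te$u; alpha_list[[i]] <- te$alpha
    }
    if ("temporal" %in% mods) bundle$temporal <- te$v
    if ("graph" %in% mods) {
      g <- build_patient_graph(rec, lexicon = lexicon, policy = policy,
                               max_nodes = config$max_nodes)
      bundle$graph <- as.numeric(encode_graph(g, params$graph))
    }
    if ("psych" %in% mods) {
      # note-level vectors aggregated under the temporal attention weights
      vecs <- do.call(rbind, lapply(rec$notes, note_vector))
      f_p <- aggregate_patient(vecs, te$alpha)
      bundle$psych <- project_psych(f_p, params$psych, impute = impute_means)
    }
    fz <- fuse(bundle, params$fusion, training = FALSE)
    Z[i, ] <- fz$z
    gates[i, ] <- fz$gates
  }
  structure(list(Z = Z, pids = pids, psych_raw = psych_raw,
                 impute_means = impute_means, u = u_list, alpha = alpha_list,
                 gates = gates, variant = config$variant),
            class = "cognitrace_features")
}

# ---------------------------------------------------------------------------
# Head training (AdamW on softmax cross-entropy)

onehot <- function(labels) {
  Y <- matrix(0, length(labels), length(CLASSES),
              dimnames = list(NULL, CLASSES))
  Y[cbind(seq_along(labels), match(labels, CLASSES))] <- 1
  Y
}

#' Fit the softmax classification head
#'
#' Full-batch AdamW on the mean cross-entropy (decoupled weight decay),
#' early-stopped on validation macro F1 with the configured patience. The
#' contrastive term is evaluated on the supplied recurrent states and
#' enters the logged total loss.
#'
#' @param Z Training feature matrix.
#' @param labels Training labels.
#' @param Z_val,labels_val Validation set (required; early stopping).
#' @param config [cognitrace_config()].
#' @param l_contrast Contrastive loss value for the logged objective.
#' @param seed Integer seed (head initialization).
#' @return List `head`, `history` (per-epoch losses and validation macro
#'   F1), `best_epoch`.
#' @export
fit_head <- function(Z, labels, Z_val, labels_val,
                     config = cognitrace_config(), l_contrast = 0, seed = 1L) {
  if (is.null(Z_val) || nrow(Z_val) == 0) stopf("validation set is empty")
  head <- classifier_head(ncol(Z), length(CLASSES),
                          seed = derive_seed(seed, "head"))
  Y <- onehot(labels)
  n <- nrow(Z)
  mW <- head$W * 0; vW <- mW; mb <- head$b * 0; vb <- mb
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  best_f1 <- -Inf; best <- head; best_epoch <- 0L; wait <- 0L
  hist <- vector("list", config$epochs)
  for (ep in seq_len(config$epochs)) {
    P <- softmax_rows(sweep(Z %*% head$W, 2L, head$b, `+`))
    l_cls <- classification_loss(P, Y, reduce = config$loss_reduce)
    G <- (P - Y) / n
    gW <- crossprod(Z, G)
    gb <- colSums(G)
    mW <- b1 * mW + (1 - b1) * gW; vW <- b2 * vW + (1 - b2) * gW^2
    mb <- b1 * mb + (1 - b1) * gb; vb <- b2 * vb + (1 - b2) * gb^2
    c1 <- 1 - b1^ep; c2 <- 1 - b2^ep
    head$W <- head$W - config$lr * ((mW / c1) / (sqrt(vW / c2) + eps) +
                                      config$weight_decay * head$W)
    head$b <- head$b - config$lr * (mb / c1) / (sqrt(vb / c2) + eps)

    Pv <- softmax_rows(sweep(Z_val %*% head$W, 2L, head$b, `+`))
    val_f1 <- macro_f1(CLASSES[max.col(Pv)], labels_val)
    lt <- total_loss(l_cls, l_contrast, config$lambda)
    hist[[ep]] <- data.frame(epoch = ep, l_cls = l_cls,
                             l_contrast = l_contrast, l_total = lt$l_total,
                             val_macro_f1 = val_f1)
    if (val_f1 > best_f1 + 1e-12) {
      best_f1 <- val_f1; best <- head; best_epoch <- ep; wait <- 0L
    } else {
      wait <- wait + 1L
      # one epoch is a single full-batch gradient step here, so patience
      # only engages after a burn-in of min_epochs steps
      if (ep >= (config$min_epochs %||% 0L) && wait >= config$patience) break
    }
  }
  list(head = best, history = do.call(rbind, hist), best_epoch = best_epoch)
}

#' Train the hybrid classifier
#'
#' Computes fused features for the train and validation splits (sentinel
#' imputation uses training-split means only), evaluates the contrastive
#' progression loss on training recurrent states, and fits the
#' classification head with early stopping on validation macro F1.
#'
#' @param records Full corpus (list of patient records).
#' @param splits [split_patients()] assignment; required; leakage-checked.
#' @param config [cognitrace_config()].
#' @param seed Integer seed for all stochastic components.
#' @param features Optional precomputed [compute_patient_features()] result
#'   for the *whole* corpus (reused across retrainings whose labels change
#'   but whose inputs do not).
#' @param labels Optional label override (named by patient id), e.g. for
#'   permutation stress tests.
#' @return A `cognitrace_model`.
#' @export
train_cognitrace <- function(records, splits, config = cognitrace_config(),
                             seed = 1L, features = NULL, labels = NULL) {
  ids <- vapply(records, function(r) r$patient_id, character(1))
  sp <- splits$split[match(ids, splits$patient_id)]
  if (anyNA(sp)) stopf("split assignment missing for %d patients", sum(is.na(sp)))
  if (anyDuplicated(splits$patient_id)) stopf("patient assigned to multiple splits")
  if (sum(sp == "val") == 0) stopf("validation set is empty")
  labs <- if (is.null(labels)) corpus_labels(records) else labels[ids]

  params <- build_model_params(config, seed = seed)
  if (is.null(features)) {
    # impute from training patients only, then reuse for all splits
    tr_psych <- if ("psych" %in% variant_modalities(config$variant)) {
      pm <- patient_psych_matrix(records[sp == "train"])
      cm <- colMeans(pm, na.rm = TRUE); cm[is.na(cm)] <- 0; cm
    } else NULL
    features <- compute_patient_features(records, params, config,
                                         impute_means = tr_psych)
  }
  tr <- sp == "train"; va <- sp == "val"

  l_con <- 0
  if (config$lambda > 0) {
    pairs <- sample_progression_pairs(records[tr],
                                      seed = derive_seed(seed, "pairs"))
    l_con <- contrastive_from_pairs(features, records[tr], pairs, config$tau)
  }
  # standardize fused features with training-split statistics only
  Ztr <- features$Z[tr, , drop = FALSE]
  scaler <- list(center = colMeans(Ztr),
                 scale = pmax(apply(Ztr, 2L, sd), 1e-8))
  std <- function(Z) sweep(sweep(Z, 2L, scaler$center), 2L, scaler$scale, `/`)
  fit <- fit_head(std(Ztr), labs[tr],
                  std(features$Z[va, , drop = FALSE]), labs[va],
                  config = config, l_contrast = l_con,
                  seed = seed)
  structure(list(params = params, head = fit$head, config = config,
                 history = fit$history, best_epoch = fit$best_epoch,
                 impute_means = features$impute_means, scaler = scaler,
                 l_contrast = l_con, seed = seed,
                 train_ids = ids[tr]),
            class = "cognitrace_model")
}

# Contrastive loss over sampled progression pairs using the recurrent
# note states stored in the feature object.
contrastive_from_pairs <- function(features, train_records, pairs, tau) {
  pos <- pairs$positives
  if (nrow(pos) == 0) return(0)
  losses <- numeric(0)
  neg <- pairs$negatives
  for (i in seq_len(nrow(pos))) {
    up <- features$u[[which(features$pids == pos$patient_id[i])]]
    if (is.null(up)) next
    anchor <- up[pos$t_anchor[i], ]
    positive <- up[pos$t_pos[i], ]
    uq <- features$u[[which(features$pids == neg$patient_b[i])]]
    negatives <- uq[seq_len(min(3L, nrow(uq))), , drop = FALSE]
    cands <- rbind(positive, negatives)
    losses <- c(losses, contrastive_loss(matrix(anchor, 1), cands, 1L, tau))
  }
  if (length(losses) == 0) 0 else mean(losses)
}

# Apply the model's training-split feature scaler.
model_standardize <- function(model, Z) {
  if (is.null(model$scaler)) return(Z)
  sweep(sweep(Z, 2L, model$scaler$center), 2L, model$scaler$scale, `/`)
}

#' Predict cognitive state for patients
#'
#' @param object A `cognitrace_model`.
#' @param records Patient records to score.
#' @param features Optional precomputed features for `records`.
#' @param ... Unused.
#' @return Data frame: `patient_id`, class probabilities, `pred`.
#' @export
predict.cognitrace_model <- function(object, records, features = NULL, ...) {
  if (is.null(features)) {
    features <- compute_patient_features(records, object$params, object$config,
                                         impute_means = object$impute_means)
  }
  cl <- classify(model_standardize(object, features$Z), object$head)
  out <- data.frame(patient_id = features$pids, cl$probs)
  names(out)[2:4] <- paste0("p_", CLASSES)
  out$pred <- CLASSES[max.col(cl$probs)]
  out
}
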
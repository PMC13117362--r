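# Cross-modal fusion, classification head and training objectives.
#
# Modalities: `local` (pooled note-text embedding), `temporal` (attention-
# pooled recurrent state), `graph` (pooled concept-graph embedding) and
# `psych` (projected psycholinguistic vector). Present modalities are
# projected to a common 512-dimensional space, attended with multi-head
# cross-modal attention, and combined through a sigmoid gate over the
# concatenation; the fused vector is a GELU-activated linear map of the
# gated concatenation, layer-normalized.

MODALITIES <- c("local", "temporal", "graph", "psych")

#' Psycholinguistic projection parameters (9 -> 128 -> 64, ReLU)
#'
#' @param dim_in Input feature count (9).
#' @param dims Hidden and output sizes (default `c(128, 64)`).
#' @param seed Integer seed.
#' @export
psych_projection_params <- function(dim_in = 9L, dims = c(128L, 64L), seed = 1L) {
  withr::with_seed(seed, {
    list(W1 = xavier_matrix(dim_in, dims[1]), b1 = numeric(dims[1]),
         W2 = xavier_matrix(dims[1], dims[2]), b2 = numeric(dims[2]))
  })
}

#' Project a psycholinguistic vector to its dense embedding
#'
#' Two ReLU layers; sentinel (NA) entries are fatal unless an imputation
#' vector (typically training-split feature means) is supplied.
#'
#' @param f Numeric length-9 feature vector.
#' @param params [psych_projection_params()].
#' @param impute Optional per-feature fallback values for NA entries.
#' @return Dense embedding (default length 64).
#' @export
project_psych <- function(f, params, impute = NULL) {
  f <- as.numeric(f)
  if (anyNA(f)) {
    if (is.null(impute)) stopf("sentinel feature values need an imputation policy")
    f[is.na(f)] <- as.numeric(impute)[is.na(f)]
  }
  h1 <- relu(as.numeric(crossprod(params$W1, f)) + params$b1)
  relu(as.numeric(crossprod(params$W2, h1)) + params$b2)
}

#' Fusion parameters
#'
#' Modality-specific projections into the common space, multi-head
#' cross-modal attention, the sigmoid gate and the output map.
#'
#' @param dims Named vector of input dims per modality.
#' @param d Common latent dimension (default 512).
#' @param n_heads Attention heads (default 4).
#' @param seed Integer seed.
#' @export
fusion_params <- function(dims, d = 512L, n_heads = 4L, seed = 1L) {
  stopifnot(d %% n_heads == 0L)
  withr::with_seed(seed, {
    proj <- lapply(dims, function(di) xavier_matrix(di, d))
    names(proj) <- names(dims)
    list(proj = proj, d = d, n_heads = n_heads,
         Wq = xavier_matrix(d, d), Wk = xavier_matrix(d, d),
         Wv = xavier_matrix(d, d),
         Wg = xavier_matrix(length(dims) * d, length(dims)),
         bg = numeric(length(dims)),
         Wz = xavier_matrix(length(dims) * d, d), bz = numeric(d))
  })
}

layer_norm <- function(x, eps = 1e-5) {
  (x - mean(x)) / sqrt(var(x) * (length(x) - 1) / length(x) + eps)
}

#' Fuse modality embeddings into a patient representation
#'
#' Each present modality is projected to the common space and attends over
#' the full set of present modalities with multi-head attention; the
#' attended vectors are concatenated (absent modalities contribute zeros
#' and a zeroed gate path), gated by a sigmoid-activated linear projection
#' of the concatenation, and passed through a GELU-activated output map
#' with layer normalization.
#'
#' @param bundle Named list with any of `local`, `temporal`, `graph`,
#'   `psych` numeric vectors (NULL = absent). At least one must be present.
#' @param params [fusion_params()].
#' @param training Apply modality-level drop-path.
#' @param p_drop Drop probability per modality during training (at least
#'   one modality always survives).
#' @return List `z` (fused vector), `gates` (per-modality, in (0,1)),
#'   `attended` (per-modality attended vectors), `attn` (per-modality head
#'   attention weights), `present` (logical flags).
#' @export
fuse <- function(bundle, params, training = FALSE, p_drop = 0.1) {
  mods <- names(params$proj)
  present <- vapply(mods, function(m) !is.null(bundle[[m]]), logical(1))
  if (!any(present)) stopf("fuse: all modalities absent")
  if (training && p_drop > 0) {
    keep <- stats::setNames(runif(length(mods)) >= p_drop, mods)
    keep[!present] <- FALSE
    if (!any(keep)) keep[which(present)[1]] <- TRUE
    present <- keep
  }
  d <- params$d; H <- params$n_heads; dk <- d %/% H
  e <- lapply(mods, function(m) {
    if (!present[[m]]) return(NULL)
    as.numeric(crossprod(params$proj[[m]], as.numeric(bundle[[m]])))
  })
  names(e) <- mods
  act_idx <- which(present)
  Emat <- do.call(rbind, e[act_idx])          # n_present x d
  Q <- Emat %*% params$Wq
  K <- Emat %*% params$Wk
  V <- Emat %*% params$Wv
  attended <- stats::setNames(vector("list", length(mods)), mods)
  attn_w <- stats::setNames(vector("list", length(mods)), mods)
  for (i in seq_along(act_idx)) {
    m <- mods[act_idx[i]]
    zm <- numeric(0); wm <- matrix(0, H, length(act_idx))
    for (h in seq_len(H)) {
      cols <- (h - 1L) * dk + seq_len(dk)
      scores <- as.numeric(K[, cols, drop = FALSE] %*% Q[i, cols]) / sqrt(dk)
      w <- softmax(scores)
      wm[h, ] <- w
      zm <- c(zm, as.numeric(crossprod(V[, cols, drop = FALSE], w)))
    }
    attended[[m]] <- zm
    attn_w[[m]] <- wm
  }
  concat <- unlist(lapply(mods, function(m) attended[[m]] %||% numeric(d)))
  gates <- sigmoid(as.numeric(crossprod(params$Wg, concat)) + params$bg)
  names(gates) <- mods
  gated <- unlist(lapply(seq_along(mods), function(i) {
    m <- mods[i]
    if (present[[m]]) gates[[i]] * attended[[m]] else numeric(d)
  }))
  z <- layer_norm(gelu(as.numeric(crossprod(params$Wz, gated)) + params$bz))
  list(z = z, gates = gates, attended = attended, attn = attn_w,
       present = present)
}

#' Classification head parameters
#'
#' @param d Fused dimension.
#' @param n_classes Number of classes (3).
#' @param seed Integer seed.
#' @export
classifier_head <- function(d = 512L, n_classes = 3L, seed = 1L) {
  withr::with_seed(seed, list(W = xavier_matrix(d, n_classes),
                              b = numeric(n_classes)))
}

#' Classify a fused embedding
#'
#' @param z Fused patient vector (or matrix, one row per patient).
#' @param head [classifier_head()].
#' @return List with `logits` and softmax `probs` over
#'   Normal/MCI/AD (rows sum to 1).
#' @export
classify <- function(z, head) {
  z <- if (is.matrix(z)) z else matrix(z, nrow = 1L)
  logits <- sweep(z %*% head$W, 2L, head$b, `+`)
  colnames(logits) <- CLASSES
  list(logits = logits, probs = softmax_rows(logits))
}

#' Mean (or sum) multiclass cross-entropy
#'
#' @param probs Matrix of predicted probabilities (rows = patients).
#' @param labels Character vector of true labels or one-hot matrix.
#' @param reduce `"mean"` (default, batch mean) or `"sum"` (the exact
#'   summed form used in closed-form checks).
#' @export
classification_loss <- function(probs, labels, reduce = c("mean", "sum")) {
  reduce <- match.arg(reduce)
  probs <- if (is.matrix(probs)) probs else matrix(probs, nrow = 1L)
  if (!is.matrix(labels)) {
    Y <- matrix(0, nrow(probs), ncol(probs))
    Y[cbind(seq_len(nrow(probs)), match(labels, CLASSES))] <- 1
  } else Y <- labels
  ll <- -sum(Y * log(pmax(probs, 1e-12)))
  if (reduce == "mean") ll / nrow(probs) else ll
}

#' Temperature-scaled contrastive progression loss
#'
#' InfoNCE over cosine similarities: for each anchor with one designated
#' positive among the candidate set, `-log softmax(sim / tau)[positive]`,
#' averaged over anchors.
#'
#' @param anchors Matrix of anchor embeddings (rows).
#' @param candidates Matrix of candidate embeddings (rows; the positive and
#'   the negatives).
#' @param positive_idx Integer vector: row of `candidates` that is the
#'   positive for each anchor.
#' @param tau Temperature (default 0.05).
#' @export
contrastive_loss <- function(anchors, candidates, positive_idx, tau = 0.05) {
  anchors <- if (is.matrix(anchors)) anchors else matrix(anchors, nrow = 1L)
  candidates <- as.matrix(candidates)
  if (length(positive_idx) != nrow(anchors) || anyNA(positive_idx)) {
    stopf("every anchor needs exactly one designated positive")
  }
  losses <- vapply(seq_len(nrow(anchors)), function(i) {
    sims <- vapply(seq_len(nrow(candidates)), function(j) {
      cosine_sim(anchors[i, ], candidates[j, ])
    }, numeric(1))
    lsm <- sims / tau - log(sum(exp(sims / tau - max(sims / tau)))) - max(sims / tau)
    -lsm[positive_idx[i]]
  }, numeric(1))
  mean(losses)
}

#' Combined training loss
#'
#' @param l_cls Classification loss.
#' @param l_contrast Contrastive loss.
#' @param lambda Mixing weight (default 0.5).
#' @return List with the two components and `l_total = l_cls +
#'   lambda * l_contrast`.
#' @export
total_loss <- function(l_cls, l_contrast, lambda = 0.5) {
  list(l_cls = l_cls, l_contrast = l_contrast, lambda = lambda,
       l_total = l_cls + lambda * l_contrast)
}

#' Sample contrastive progression pairs
#'
#' Positive pairs are same-patient note pairs whose temporal gap lies in
#' `gap_days` (default 180 to 1095 days); negatives pair notes from two
#' distinct patients. Patients with no eligible pair contribute no
#' positives (counted, not fatal).
#'
#' @param records Training-split patient records.
#' @param n_pairs Maximum positives to sample.
#' @param gap_days Length-2 inclusive day-gap interval.
#' @param seed Integer seed.
#' @return List with `positives` and `negatives` data.frames and
#'   `n_patients_without_positive`.
#' @export
sample_progression_pairs <- function(records, n_pairs = 200L,
                                     gap_days = c(180, 1095), seed = 1L) {
  pos <- list(); skipped <- 0L
  for (rec in records) {
    ts <- vapply(rec$notes, function(n) as.numeric(n$timestamp), numeric(1))
    if (length(ts) < 2) { skipped <- skipped + 1L; next }
    cand <- which(outer(ts, ts, function(a, b) b - a) >= gap_days[1] &
                    outer(ts, ts, function(a, b) b - a) <= gap_days[2],
                  arr.ind = TRUE)
    if (nrow(cand) == 0) { skipped <- skipped + 1L; next }
    pos[[length(pos) + 1L]] <- data.frame(
      patient_id = rec$patient_id, t_anchor = cand[, 1], t_pos = cand[, 2],
      gap = ts[cand[, 2]] - ts[cand[, 1]])
  }
  pos <- if (length(pos)) do.call(rbind, pos) else
    data.frame(patient_id = character(0), t_anchor = integer(0),
               t_pos = integer(0), gap = numeric(0))
  ids <- vapply(records, function(r) r$patient_id, character(1))
  withr::with_seed(seed, {
    if (nrow(pos) > n_pairs) pos <- pos[resample(seq_len(nrow(pos)), n_pairs), ]
    neg <- if (length(ids) >= 2 && nrow(pos) > 0) {
      data.frame(
        patient_a = pos$patient_id,
        patient_b = vapply(pos$patient_id, function(p) sample1(setdiff(ids, p)),
                           character(1)))
    } else data.frame(patient_a = character(0), patient_b = character(0))
  })
  rownames(pos) <- NULL
  list(positives = pos, negatives = neg, n_patients_without_positive = skipped)
}
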
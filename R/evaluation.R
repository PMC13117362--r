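# Metrics, patient-level Monte Carlo cross-validation, temporal stability,
# statistical comparisons, and cross-cohort embedding alignment.

confusion_matrix <- function(pred, truth) {
  table(factor(pred, levels = CLASSES), factor(truth, levels = CLASSES))
}

per_class_metrics <- function(cm) {
  n <- sum(cm)
  out <- lapply(seq_along(CLASSES), function(i) {
    tp <- cm[i, i]
    fp <- sum(cm[i, ]) - tp
    fn <- sum(cm[, i]) - tp
    tn <- n - tp - fp - fn
    prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    rec <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    f1 <- if (!is.na(prec) && !is.na(rec) && prec + rec > 0)
      2 * prec * rec / (prec + rec) else if (tp + fp + fn == 0) NA_real_ else 0
    spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
    denom <- sqrt((tp + fp) * (tp + fn)) * sqrt((tn + fp) * (tn + fn))
    mcc <- if (denom > 0) (tp * tn - fp * fn) / denom else NA_real_
    data.frame(class = CLASSES[i], precision = prec, recall = rec, f1 = f1,
               specificity = spec, mcc = mcc, support = sum(cm[, i]))
  })
  do.call(rbind, out)
}

macro_f1 <- function(pred, truth) {
  pc <- per_class_metrics(confusion_matrix(pred, truth))
  present <- pc$support > 0
  mean(pc$f1[present], na.rm = TRUE)
}

multiclass_mcc <- function(cm) {
  # Gorodkin's generalization of the Matthews correlation coefficient
  cm <- as.matrix(cm)
  n <- sum(cm)
  tr <- sum(diag(cm))
  rows <- rowSums(cm); cols <- colSums(cm)
  num <- tr * n - sum(rows * cols)
  den <- sqrt(n^2 - sum(rows^2)) * sqrt(n^2 - sum(cols^2))
  if (den == 0) return(NA_real_)
  num / den
}

cohens_kappa <- function(cm) {
  cm <- as.matrix(cm)
  n <- sum(cm)
  po <- sum(diag(cm)) / n
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  if (pe == 1) return(NA_real_)
  (po - pe) / (1 - pe)
}

binary_auc <- function(scores, pos) {
  # Wilcoxon rank statistic; used for macro one-vs-rest AUC
  r <- rank(scores)
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

pr_auc_binary <- function(scores, pos) {
  if (sum(pos) == 0 || sum(!pos) == 0) return(NA_real_)
  ord <- order(scores, decreasing = TRUE)
  tp <- cumsum(pos[ord]); fp <- cumsum(!pos[ord])
  prec <- tp / (tp + fp); rec <- tp / sum(pos)
  # average precision (step interpolation)
  sum(diff(c(0, rec)) * prec)
}

#' Compute the full metric report
#'
#' Accuracy, macro F1, balanced accuracy, macro one-vs-rest ROC AUC,
#' macro PR-AUC, sensitivity (macro recall), specificity (macro),
#' multiclass MCC, Cohen's kappa, and the per-class table. Classes absent
#' from the labels are excluded from macro averages with a warning.
#'
#' @param predictions Data frame from [predict.cognitrace_model()] (or any
#'   frame with `pred` and `p_<class>` columns), or a character vector of
#'   predicted labels (then AUCs are NA).
#' @param labels True labels aligned with the predictions.
#' @return A `metric_report` list with fields `accuracy`, `macro_f1`,
#'   `balanced_accuracy`, `roc_auc`, `pr_auc`, `sensitivity`,
#'   `specificity`, `mcc`, `kappa`, `per_class`, `confusion`.
#' @export
compute_metrics <- function(predictions, labels) {
  if (is.character(predictions)) {
    pred <- predictions
    probs <- NULL
  } else {
    pred <- predictions$pred
    pcols <- paste0("p_", CLASSES)
    probs <- if (all(pcols %in% names(predictions)))
      as.matrix(predictions[, pcols]) else NULL
  }
  stopifnot(length(pred) == length(labels))
  cm <- confusion_matrix(pred, labels)
  pc <- per_class_metrics(cm)
  present <- pc$support > 0
  if (!all(present)) {
    warnf("class(es) absent from labels: %s; macro averages computed over present classes",
          paste(pc$class[!present], collapse = ", "))
  }
  aucs <- pr_aucs <- rep(NA_real_, length(CLASSES))
  if (!is.null(probs)) {
    for (i in seq_along(CLASSES)) {
      if (!present[i]) next
      pos <- labels == CLASSES[i]
      aucs[i] <- binary_auc(probs[, i], pos)
      pr_aucs[i] <- pr_auc_binary(probs[, i], pos)
    }
  }
  structure(list(
    accuracy = sum(diag(cm)) / sum(cm),
    macro_f1 = mean(pc$f1[present], na.rm = TRUE),
    balanced_accuracy = mean(pc$recall[present], na.rm = TRUE),
    roc_auc = mean(aucs[present]),
    pr_auc = mean(pr_aucs[present]),
    sensitivity = mean(pc$recall[present], na.rm = TRUE),
    specificity = mean(pc$specificity[present], na.rm = TRUE),
    mcc = multiclass_mcc(cm),
    kappa = cohens_kappa(cm),
    per_class = pc, confusion = cm
  ), class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf(
    "accuracy %.3f | macro F1 %.3f | bal.acc %.3f | AUC %s | MCC %.3f | kappa %.3f\n",
    x$accuracy, x$macro_f1, x$balanced_accuracy,
    ifelse(is.na(x$roc_auc), "NA", sprintf("%.3f", x$roc_auc)), x$mcc, x$kappa))
  invisible(x)
}

#' Patient-level Monte Carlo cross-validation
#'
#' Repeatedly resamples a stratified patient-level train/validation/test
#' partition, retrains the classification head on fixed fused features, and
#' aggregates the metric report as mean and SD across folds. No patient
#' ever straddles a fold boundary (checked each fold).
#'
#' @param records Corpus.
#' @param config [cognitrace_config()].
#' @param n_folds Number of Monte Carlo folds (desk default 50).
#' @param seed Integer seed.
#' @param fractions Per-fold split fractions.
#' @param features Optional precomputed features (computed once otherwise).
#' @return List with `summary` (data.frame metric, mean, sd), `folds`
#'   (per-fold metric data.frame).
#' @export
monte_carlo_cv <- function(records, config = cognitrace_config(),
                           n_folds = 50L, seed = 1L,
                           fractions = c(0.70, 0.15, 0.15), features = NULL) {
  stopifnot(n_folds >= 2)
  params <- build_model_params(config, seed = seed)
  if (is.null(features)) {
    features <- compute_patient_features(records, params, config)
  }
  labs <- corpus_labels(records)
  rows <- vector("list", n_folds)
  for (fold in seq_len(n_folds)) {
    sp <- split_patients(records, fractions, seed = derive_seed(seed, paste0("fold", fold)))
    if (anyDuplicated(sp$patient_id)) stopf("fold %d: patient in two splits", fold)
    model <- train_cognitrace(records, sp, config, seed = seed, features = features)
    te <- sp$split == "test"
    sub <- list(Z = features$Z[te, , drop = FALSE], pids = features$pids[te])
    preds <- predict(model, records[te], features = sub)
    m <- compute_metrics(preds, unname(labs[sp$patient_id[te]]))
    rows[[fold]] <- data.frame(fold = fold, accuracy = m$accuracy,
                               macro_f1 = m$macro_f1,
                               balanced_accuracy = m$balanced_accuracy,
                               roc_auc = m$roc_auc, mcc = m$mcc,
                               kappa = m$kappa)
  }
  folds <- do.call(rbind, rows)
  mets <- setdiff(names(folds), "fold")
  summary <- data.frame(metric = mets,
                        mean = vapply(mets, function(m) mean(folds[[m]]), numeric(1)),
                        sd = vapply(mets, function(m) sd(folds[[m]]), numeric(1)))
  rownames(summary) <- NULL
  list(summary = summary, folds = folds)
}

#' Temporal stability of per-patient predictions
#'
#' For each patient, scores every prefix of the note sequence and reports
#' the population variance over prefixes of the probability assigned to the
#' patient's final predicted class; low variance indicates stable
#' longitudinal behaviour. Single-note patients are excluded and counted.
#'
#' @param model A `cognitrace_model`.
#' @param records Patient records.
#' @return A list: `per_patient` (data.frame `patient_id`, `variance`,
#'   `n_notes`), `mean_variance`, `n_excluded`.
#' @export
temporal_stability <- function(model, records) {
  rows <- list(); excluded <- 0L
  for (rec in records) {
    T_ <- length(rec$notes)
    if (T_ < 2) { excluded <- excluded + 1L; next }
    prefixes <- lapply(seq_len(T_), function(t) {
      r <- rec; r$notes <- rec$notes[seq_len(t)]; r
    })
    preds <- predict(model, prefixes)
    final_class <- preds$pred[T_]
    p <- preds[[paste0("p_", final_class)]]
    v <- mean((p - mean(p))^2)   # population variance across visits
    rows[[length(rows) + 1L]] <- data.frame(patient_id = rec$patient_id,
                                            variance = v, n_notes = T_)
  }
  per_patient <- if (length(rows)) do.call(rbind, rows) else
    data.frame(patient_id = character(0), variance = numeric(0),
               n_notes = integer(0))
  list(per_patient = per_patient,
       mean_variance = if (nrow(per_patient)) mean(per_patient$variance) else NA_real_,
       n_excluded = excluded)
}

#' Label permutation stress test
#'
#' Retrains the model on class-preservingly permuted patient labels and
#' evaluates on a held-out split; with no genuine signal left, accuracy
#' collapses to chance (about 1/3 for three balanced classes) and the
#' macro one-vs-rest AUC to about 0.5. Also reports the empirical p-value
#' of the unpermuted score in the null distribution.
#'
#' @param records Corpus.
#' @param config [cognitrace_config()].
#' @param n_perms Number of permutation replicates (desk default 20).
#' @param seed Integer seed.
#' @param features Optional precomputed features.
#' @return List with `perms` (per-replicate accuracy/macro F1/AUC),
#'   `observed` (unpermuted metrics), `p_accuracy`, `p_auc`.
#' @export
permutation_label_test <- function(records, config = cognitrace_config(),
                                   n_perms = 20L, seed = 1L, features = NULL) {
  params <- build_model_params(config, seed = seed)
  if (is.null(features)) {
    features <- compute_patient_features(records, params, config)
  }
  labs <- corpus_labels(records)
  run_once <- function(labels, split_seed) {
    sp <- split_patients(records, seed = split_seed)
    model <- train_cognitrace(records, sp, config, seed = seed,
                              features = features, labels = labels)
    te <- sp$split == "test"
    preds <- predict(model, records[te],
                     features = list(Z = features$Z[te, , drop = FALSE],
                                     pids = features$pids[te]))
    m <- compute_metrics(preds, unname(labels[sp$patient_id[te]]))
    c(accuracy = m$accuracy, macro_f1 = m$macro_f1, roc_auc = m$roc_auc)
  }
  observed <- run_once(labs, derive_seed(seed, "observed"))
  perms <- t(vapply(seq_len(n_perms), function(b) {
    pl <- withr::with_seed(derive_seed(seed, paste0("perm", b)), {
      stats::setNames(sample(unname(labs)), names(labs))
    })
    run_once(pl, derive_seed(seed, paste0("permsplit", b)))
  }, numeric(3)))
  list(perms = as.data.frame(perms), observed = observed,
       p_accuracy = (1 + sum(perms[, "accuracy"] >= observed["accuracy"])) /
         (n_perms + 1),
       p_auc = (1 + sum(perms[, "roc_auc"] >= observed["roc_auc"])) /
         (n_perms + 1))
}

# ---------------------------------------------------------------------------
# Statistical comparisons

#' DeLong test for correlated ROC curves
#'
#' Placement-value (structural component) implementation of DeLong,
#' DeLong & Clarke-Pearson. For three-class problems the labels are
#' reduced one-vs-rest per class and a macro summary is reported.
#'
#' @param scores_a,scores_b Paired scores from two classifiers (higher =
#'   more positive). Vectors for binary labels; matrices with one column
#'   per class for multiclass.
#' @param labels Binary (logical/0-1) or three-class character labels.
#' @return For binary input a list `auc_a`, `auc_b`, `z`, `p`; for
#'   multiclass a data.frame per class plus macro `z` via Stouffer's rule.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  if (is.matrix(scores_a) || length(unique(labels)) > 2) {
    scores_a <- as.matrix(scores_a); scores_b <- as.matrix(scores_b)
    rows <- lapply(seq_along(CLASSES), function(i) {
      pos <- labels == CLASSES[i]
      if (sum(pos) == 0 || sum(!pos) == 0) return(NULL)
      r <- delong_binary(scores_a[, i], scores_b[, i], pos)
      data.frame(class = CLASSES[i], auc_a = r$auc_a, auc_b = r$auc_b,
                 z = r$z, p = r$p)
    })
    rows <- do.call(rbind, Filter(Negate(is.null), rows))
    z_macro <- sum(rows$z) / sqrt(nrow(rows))
    return(list(per_class = rows, z = z_macro,
                p = 2 * pnorm(-abs(z_macro))))
  }
  pos <- as.logical(labels)
  delong_binary(scores_a, scores_b, pos)
}

delong_binary <- function(sa, sb, pos) {
  if (all(pos) || !any(pos)) stopf("DeLong test needs both classes present")
  placements <- function(s) {
    x <- s[pos]; y <- s[!pos]
    m <- length(x); n <- length(y)
    v10 <- vapply(x, function(xi) mean((xi > y) + 0.5 * (xi == y)), numeric(1))
    v01 <- vapply(y, function(yj) mean((x > yj) + 0.5 * (x == yj)), numeric(1))
    list(auc = mean(v10), v10 = v10, v01 = v01, m = m, n = n)
  }
  pa <- placements(sa); pb <- placements(sb)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  S <- s10 / pa$m + s01 / pa$n
  var_diff <- S[1, 1] + S[2, 2] - 2 * S[1, 2]
  d <- pa$auc - pb$auc
  z <- if (var_diff <= 0) { if (abs(d) < 1e-12) 0 else sign(d) * Inf }
  else d / sqrt(var_diff)
  list(auc_a = pa$auc, auc_b = pb$auc, z = z,
       p = if (is.infinite(z)) 0 else 2 * pnorm(-abs(z)))
}

#' McNemar test on paired classifier correctness
#'
#' Continuity-corrected chi-square on the discordant counts. With zero
#' discordant pairs the test is degenerate: p = 1 by convention, flagged.
#'
#' @param correct_a,correct_b Logical vectors: per-case correctness of the
#'   two classifiers.
#' @return List `b` (a right, b wrong), `c`, `chisq`, `p`, `degenerate`.
#' @export
mcnemar_test <- function(correct_a, correct_b) {
  stopifnot(length(correct_a) == length(correct_b))
  b <- sum(correct_a & !correct_b)
  cc <- sum(!correct_a & correct_b)
  if (b + cc == 0) {
    return(list(b = b, c = cc, chisq = 0, p = 1, degenerate = TRUE))
  }
  chisq <- (abs(b - cc) - 1)^2 / (b + cc)
  list(b = b, c = cc, chisq = chisq, p = pchisq(chisq, 1, lower.tail = FALSE),
       degenerate = FALSE)
}

#' Patient-level bootstrap confidence interval for a metric
#'
#' Percentile interval over patient-resampled replicates.
#'
#' @param metric_fn `function(predictions, labels) -> numeric(1)`.
#' @param predictions Prediction data.frame (rows = patients).
#' @param labels True labels.
#' @param n_boot Number of resamples (desk default 1000).
#' @param seed Integer seed.
#' @param level Confidence level.
#' @return List `estimate`, `lower`, `upper`, `level`.
#' @export
bootstrap_ci <- function(metric_fn, predictions, labels, n_boot = 1000L,
                         seed = 1L, level = 0.95) {
  est <- metric_fn(predictions, labels)
  n <- length(labels)
  reps <- withr::with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      metric_fn(predictions[idx, , drop = FALSE], labels[idx])
    }, numeric(1))
  })
  a <- (1 - level) / 2
  q <- quantile(reps, c(a, 1 - a), na.rm = TRUE, names = FALSE)
  list(estimate = est, lower = q[1], upper = q[2], level = level)
}

# ---------------------------------------------------------------------------
# Cross-cohort alignment

rbf_mmd <- function(X, Y, bandwidth = NULL) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  pd2 <- function(A, B) {
    an <- rowSums(A^2); bn <- rowSums(B^2)
    outer(an, bn, `+`) - 2 * A %*% t(B)
  }
  if (is.null(bandwidth)) {
    d2 <- pd2(rbind(X, Y), rbind(X, Y))
    med <- stats::median(d2[upper.tri(d2)])
    bandwidth <- sqrt(pmax(med, 1e-12) / 2)
  }
  k <- function(A, B) exp(-pd2(A, B) / (2 * bandwidth^2))
  mean(k(X, X)) + mean(k(Y, Y)) - 2 * mean(k(X, Y))
}

#' Orthogonal Procrustes alignment between embedding cohorts
#'
#' Fits the orthogonal transform (plus optional isotropic scaling and
#' translation) minimizing the Frobenius disparity between paired anchor
#' matrices via the SVD closed form, applies it to the full source cloud,
#' and reports the RBF-kernel maximum mean discrepancy before and after.
#' When no row pairing exists, anchors default to class-conditional
#' centroids (`source_labels`/`target_labels`).
#'
#' @param source,target Numeric matrices with matching column dimension.
#'   With `anchors = NULL` and no labels, rows are assumed paired.
#' @param source_labels,target_labels Optional class labels used to build
#'   centroid anchors.
#' @param scale Fit an isotropic scale factor (default TRUE).
#' @return List `aligned` (transformed source), `rotation`, `scale`,
#'   `translation`, `disparity` (normalized anchor residual),
#'   `mmd_before`, `mmd_after`.
#' @export
procrustes_align <- function(source, target, source_labels = NULL,
                             target_labels = NULL, scale = TRUE) {
  source <- as.matrix(source); target <- as.matrix(target)
  if (ncol(source) != ncol(target)) stopf("dimension mismatch")
  if (!is.null(source_labels)) {
    cls <- intersect(unique(source_labels), unique(target_labels))
    A <- do.call(rbind, lapply(cls, function(cl)
      colMeans(source[source_labels == cl, , drop = FALSE])))
    B <- do.call(rbind, lapply(cls, function(cl)
      colMeans(target[target_labels == cl, , drop = FALSE])))
  } else {
    if (nrow(source) != nrow(target)) stopf("unpaired rows need labels for centroid anchors")
    A <- source; B <- target
  }
  mu_a <- colMeans(A); mu_b <- colMeans(B)
  Ac <- sweep(A, 2L, mu_a); Bc <- sweep(B, 2L, mu_b)
  M <- crossprod(Ac, Bc)
  sv <- svd(M)
  if (min(dim(A)) < ncol(A)) {
    # rank-deficient anchor set: SVD still yields the minimizing rotation,
    # flag it for the caller
    warnf("anchor matrix is rank deficient; alignment uses the pseudo-inverse path")
  }
  R <- sv$u %*% t(sv$v)
  s <- if (scale) sum(sv$d) / sum(Ac^2) else 1
  translation <- mu_b - s * as.numeric(mu_a %*% R)
  fitted_anchor <- sweep(s * (Ac %*% R), 2L, mu_b, `+`)
  ss_b <- sum(Bc^2)
  disparity <- if (ss_b > 0) sum((fitted_anchor - B)^2) / ss_b else sum((fitted_anchor - B)^2)
  aligned <- sweep(s * (source %*% R), 2L, translation, `+`)
  list(aligned = aligned, rotation = R, scale = s, translation = translation,
       disparity = disparity,
       mmd_before = rbf_mmd(source, target),
       mmd_after = rbf_mmd(aligned, target))
}
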
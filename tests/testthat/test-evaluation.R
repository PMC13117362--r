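# Metric report, cross-validation, stability, statistical tests, alignment.

test_that("metric report is exact for perfect and chance predictions", {
  labs <- rep(CLASSES, each = 10)
  m <- compute_metrics(labs, labs)
  expect_equal(m$accuracy, 1)
  expect_equal(m$mcc, 1)
  expect_equal(m$kappa, 1)
  expect_equal(m$macro_f1, 1)

  # uniform-random predictions on balanced labels approach chance
  set.seed(5)
  labs2 <- rep(CLASSES, each = 1000)
  pred2 <- sample(CLASSES, 3000, replace = TRUE)
  m2 <- compute_metrics(pred2, labs2)
  expect_equal(m2$accuracy, 1 / 3, tolerance = 0.03)
  expect_equal(m2$kappa, 0, tolerance = 0.04)
})

test_that("per-class metrics match brute-force confusion arithmetic", {
  cm <- matrix(c(8, 2, 1,
                 1, 6, 2,
                 0, 1, 9), 3, 3, byrow = TRUE,
               dimnames = list(CLASSES, CLASSES))
  # rebuild label vectors from the matrix and score them
  pred <- rep(rep(CLASSES, 3), times = as.vector(t(cm)))
  truth <- rep(CLASSES, times = rowSums(t(cm)))
  # ... simpler: expand cell by cell
  pred <- character(0); truth <- character(0)
  for (i in 1:3) for (j in 1:3) {
    pred <- c(pred, rep(CLASSES[i], cm[i, j]))
    truth <- c(truth, rep(CLASSES[j], cm[i, j]))
  }
  rep_ <- compute_metrics(pred, truth)
  expect_equal(unname(as.matrix(rep_$confusion)), unname(cm))
  # hand-computed per-class F1 for Normal: tp 8, fp 3, fn 1
  expect_equal(rep_$per_class$f1[1], 2 * (8 / 11) * (8 / 9) / (8 / 11 + 8 / 9))
  # macro F1 is the unweighted mean of per-class F1
  expect_equal(rep_$macro_f1, mean(rep_$per_class$f1), tolerance = 1e-12)
  # balanced accuracy = mean recall
  expect_equal(rep_$balanced_accuracy, mean(rep_$per_class$recall))
})

test_that("MCC and kappa agree with indicator-vector oracles exhaustively", {
  # independent oracles: MCC from summed indicator covariances, kappa from
  # raw agreement probabilities
  mcc_oracle <- function(cm) {
    pred <- integer(0); truth <- integer(0)
    for (i in 1:3) for (j in 1:3) {
      pred <- c(pred, rep(i, cm[i, j]))
      truth <- c(truth, rep(j, cm[i, j]))
    }
    X <- cbind(pred == 1, pred == 2, pred == 3) + 0
    Y <- cbind(truth == 1, truth == 2, truth == 3) + 0
    cxy <- sum(diag(stats::cov(X, Y)))
    den <- sqrt(sum(diag(stats::cov(X, X)))) * sqrt(sum(diag(stats::cov(Y, Y))))
    if (!is.finite(den) || den == 0) NA_real_ else cxy / den
  }
  kappa_oracle <- function(cm) {
    n <- sum(cm)
    po <- sum(diag(cm)) / n
    pe <- sum((rowSums(cm) / n) * (colSums(cm) / n))
    if (pe == 1) NA_real_ else (po - pe) / (1 - pe)
  }
  # random spot checks on larger tables (the exhaustive small-table sweep
  # lives in the acceptance suite)
  set.seed(1)
  for (r in 1:200) {
    cm <- matrix(sample(0:5, 9, replace = TRUE), 3, 3)
    if (sum(cm) < 2) next
    got <- multiclass_mcc(cm); want <- mcc_oracle(cm)
    expect_equal(is.na(got), is.na(want))
    if (!is.na(got)) expect_equal(got, want, tolerance = 1e-9)
    expect_equal(cohens_kappa(cm), kappa_oracle(cm), tolerance = 1e-12)
  }
})

test_that("Monte Carlo CV is deterministic with disjoint stratified folds", {
  corpus <- fixture_corpus_small()
  ft <- fixture_features_small()
  cv1 <- suppressMessages(monte_carlo_cv(corpus, cognitrace_config(),
                                         n_folds = 3, seed = 6, features = ft))
  cv2 <- suppressMessages(monte_carlo_cv(corpus, cognitrace_config(),
                                         n_folds = 3, seed = 6, features = ft))
  expect_identical(cv1$summary, cv2$summary)
  expect_equal(nrow(cv1$folds), 3)
  expect_true(all(c("accuracy", "macro_f1", "roc_auc") %in% cv1$summary$metric))
})

test_that("temporal stability is the prefix-probability variance", {
  m <- fixture_model_small()
  corpus <- fixture_corpus_small()
  st <- temporal_stability(m, corpus[1:3])
  expect_equal(nrow(st$per_patient), 3)
  expect_true(all(st$per_patient$variance >= 0))
  # recompute one patient by hand from its prefix predictions
  rec <- corpus[[2]]
  T_ <- length(rec$notes)
  prefixes <- lapply(seq_len(T_), function(t) {
    r <- rec; r$notes <- rec$notes[seq_len(t)]; r
  })
  preds <- predict(m, prefixes)
  p <- preds[[paste0("p_", preds$pred[T_])]]
  expect_equal(st$per_patient$variance[2], mean((p - mean(p))^2),
               tolerance = 1e-12)
  # population variance closed form: probs (0.5, 0.7) -> 0.01
  expect_equal(mean((c(0.5, 0.7) - 0.6)^2), 0.01)
  # single-note patients are excluded and counted
  one <- rec; one$notes <- rec$notes[1]
  st1 <- temporal_stability(m, list(one))
  expect_equal(st1$n_excluded, 1L)
  expect_equal(nrow(st1$per_patient), 0)
})

test_that("DeLong matches the placement oracle and pROC", {
  # identical classifiers: Z = 0, p = 1
  s <- c(0.9, 0.35, 0.3, 0.2, 0.6, 0.4)
  y <- c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE)
  r0 <- delong_test(s, s, y)
  expect_equal(r0$z, 0)
  expect_equal(r0$p, 1)
  # swapping the classifiers negates Z
  s2 <- c(0.7, 0.6, 0.5, 0.1, 0.9, 0.3)
  r1 <- delong_test(s, s2, y)
  r2 <- delong_test(s2, s, y)
  expect_equal(r1$z, -r2$z, tolerance = 1e-12)
  expect_equal(r1$p, r2$p, tolerance = 1e-12)
  # 6-case fixture against pROC's DeLong implementation
  mk_roc <- function(sc) pROC::roc(y, sc, quiet = TRUE, direction = "<",
                                   levels = c(FALSE, TRUE))
  rp <- pROC::roc.test(mk_roc(s), mk_roc(s2), method = "delong")
  expect_equal(abs(r1$z), abs(unname(rp$statistic)), tolerance = 1e-9)
  expect_equal(r1$p, rp$p.value, tolerance = 1e-9)
  # brute-force placement-value oracle on the same fixture
  pos <- which(y); neg <- which(!y)
  auc_brute <- function(sc) {
    mean(outer(sc[pos], sc[neg], function(a, b) (a > b) + 0.5 * (a == b)))
  }
  expect_equal(delong_test(s, s2, y)$auc_a, auc_brute(s), tolerance = 1e-12)
  expect_equal(delong_test(s, s2, y)$auc_b, auc_brute(s2), tolerance = 1e-12)
  expect_error(delong_test(s, s2, rep(TRUE, 6)), "both classes")
})

test_that("McNemar uses the continuity-corrected discordant formula", {
  # b = c: statistic with correction is (0 - 1)^2 / (b + c)
  a <- c(rep(TRUE, 5), rep(FALSE, 5), rep(TRUE, 10))
  b <- c(rep(FALSE, 5), rep(TRUE, 5), rep(TRUE, 10))
  r <- mcnemar_test(a, b)
  expect_equal(r$chisq, 1 / 10)
  # b = 10, c = 0 -> 8.1
  a2 <- c(rep(TRUE, 10), rep(TRUE, 5))
  b2 <- c(rep(FALSE, 10), rep(TRUE, 5))
  expect_equal(mcnemar_test(a2, b2)$chisq, 8.1)
  # agreement with stats::mcnemar.test on an asymmetric discordant table
  a3 <- c(rep(TRUE, 7), rep(FALSE, 3), rep(TRUE, 5))
  b3 <- c(rep(FALSE, 7), rep(TRUE, 3), rep(TRUE, 5))
  expect_equal(mcnemar_test(a3, b3)$p,
               stats::mcnemar.test(table(a3, b3))$p.value, tolerance = 1e-12)
  # no disagreements: degenerate, p = 1
  r0 <- mcnemar_test(c(TRUE, FALSE), c(TRUE, FALSE))
  expect_true(r0$degenerate)
  expect_equal(r0$p, 1)
})

test_that("bootstrap intervals behave at the boundaries and cover", {
  acc <- function(pred, labs) mean(pred$pred == labs)
  pred <- data.frame(pred = rep("AD", 20))
  labs <- rep("AD", 20)
  ci <- bootstrap_ci(acc, pred, labs, n_boot = 100, seed = 2)
  expect_equal(ci$lower, ci$upper)   # constant metric, zero width
  expect_equal(ci$estimate, 1)

  set.seed(9)
  pred2 <- data.frame(pred = sample(CLASSES, 60, replace = TRUE))
  labs2 <- sample(CLASSES, 60, replace = TRUE)
  ci2 <- bootstrap_ci(acc, pred2, labs2, n_boot = 300, seed = 3)
  expect_true(ci2$lower <= ci2$estimate && ci2$estimate <= ci2$upper)

  # coverage study: a 95% interval for a Bernoulli mean covers ~95%
  true_p <- 0.7
  cover <- vapply(1:200, function(i) {
    y <- stats::rbinom(60, 1, true_p)
    prd <- data.frame(pred = ifelse(y == 1, "AD", "MCI"))
    ci <- bootstrap_ci(acc, prd, rep("AD", 60), n_boot = 200, seed = i)
    ci$lower <= true_p && true_p <= ci$upper
  }, logical(1))
  expect_gte(mean(cover), 0.85)
  expect_lte(mean(cover), 1.0)
})

test_that("Procrustes alignment recovers rotations and reduces MMD", {
  set.seed(12)
  X <- matrix(rnorm(100), 20, 5)
  # a random rotation via QR
  Q <- qr.Q(qr(matrix(rnorm(25), 5, 5)))
  Y <- X %*% Q
  al <- procrustes_align(X, Y, scale = FALSE)
  expect_lt(al$disparity, 1e-12)
  expect_lt(al$mmd_after, 1e-6)
  expect_equal(al$aligned, Y, tolerance = 1e-8)
  # identity fixed point
  al_id <- procrustes_align(X, X)
  expect_equal(al_id$rotation, diag(5), tolerance = 1e-8)
  expect_equal(al_id$scale, 1, tolerance = 1e-8)
  # disparity matches vegan's closed-form orthogonal Procrustes
  Y2 <- matrix(rnorm(100), 20, 5)
  al2 <- procrustes_align(X, Y2, scale = TRUE)
  vg <- vegan::procrustes(Y2, X, symmetric = FALSE)
  expect_equal(al2$rotation, vg$rotation, tolerance = 1e-8)
  expect_equal(al2$scale, vg$scale, tolerance = 1e-8)
  # post-alignment MMD never exceeds pre-alignment MMD on rotated cohorts
  expect_lte(al$mmd_after, al$mmd_before + 1e-12)
  expect_error(procrustes_align(X, Y2[, 1:3]), "dimension")
})

test_that("centroid-anchored alignment uses class labels", {
  set.seed(13)
  X <- matrix(rnorm(60 * 4), 60, 4)
  labs <- rep(CLASSES, each = 20)
  shift <- matrix(rep(c(1, -1, 0.5, 0), each = 60), 60, 4)
  Y <- (X + shift)[sample(60), ]
  labs_y <- labs
  al <- suppressWarnings(
    procrustes_align(X, Y, source_labels = labs, target_labels = labs_y))
  expect_equal(dim(al$aligned), dim(X))
  expect_true(is.finite(al$disparity))
})
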
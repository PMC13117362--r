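# Psych projection, gated cross-modal fusion, classifier and losses.

test_that("psych projection implements the two-layer ReLU map", {
  params <- psych_projection_params(seed = 9)
  # zero input through zero-bias layers stays zero
  expect_equal(project_psych(rep(0, 9), params), rep(0, 64))
  # output dimension before the modality projection is 64
  expect_length(project_psych(runif(9), params), 64)
  # sentinel without imputation is fatal; with imputation it falls back
  f <- c(NA, runif(8))
  expect_error(project_psych(f, params), "imputation")
  imp <- rep(0.5, 9)
  expect_equal(project_psych(f, params, impute = imp),
               project_psych(c(0.5, f[-1]), params))

  # hand 2 -> 3 -> 2 toy case against manual matrix arithmetic
  toy <- list(W1 = matrix(c(1, 0, -1, 2, 0.5, 0), 2, 3),
              b1 = c(0.1, -0.2, 0), W2 = matrix(1:6 / 10, 3, 2), b2 = c(0, 1))
  x <- c(0.4, -0.3)
  h1 <- pmax(as.numeric(crossprod(toy$W1, x)) + toy$b1, 0)
  expected <- pmax(as.numeric(crossprod(toy$W2, h1)) + toy$b2, 0)
  expect_equal(project_psych(x, toy), expected)
})

test_that("fusion gates stay in (0,1) and eval mode is deterministic", {
  dims <- c(local = 4, temporal = 6, graph = 3, psych = 5)
  params <- fusion_params(dims, d = 8, n_heads = 2, seed = 11)
  bundle <- list(local = rnorm(4), temporal = rnorm(6), graph = rnorm(3),
                 psych = rnorm(5))
  f1 <- fuse(bundle, params, training = FALSE)
  f2 <- fuse(bundle, params, training = FALSE)
  expect_identical(f1$z, f2$z)
  expect_true(all(f1$gates > 0 & f1$gates < 1))
  expect_length(f1$z, 8)
  # modality attention masses are simplex-valued per head
  for (m in names(f1$attn)) {
    if (is.null(f1$attn[[m]])) next
    expect_equal(rowSums(f1$attn[[m]]), rep(1, 2), tolerance = 1e-9)
  }

  # a single present modality still fuses, with a gate in (0,1)
  fo <- fuse(list(local = rnorm(4)), params)
  expect_true(fo$gates["local"] > 0 && fo$gates["local"] < 1)
  expect_false(any(fo$present[c("temporal", "graph", "psych")]))
  expect_error(fuse(list(), params), "absent")

  # drop-path always leaves at least one survivor
  withr::with_seed(3, {
    for (i in 1:50) {
      fd <- fuse(bundle, params, training = TRUE, p_drop = 0.9)
      expect_gte(sum(fd$present), 1)
    }
  })
})

test_that("single-head attention over two modalities matches a manual oracle", {
  dims <- c(local = 3, temporal = 3)
  params <- fusion_params(dims, d = 4, n_heads = 1, seed = 13)
  params$proj$graph <- NULL; params$proj$psych <- NULL
  bundle <- list(local = c(1, -0.5, 0.25), temporal = c(0.3, 0.8, -1))
  fz <- fuse(bundle, params)

  e_loc <- as.numeric(crossprod(params$proj$local, bundle$local))
  e_tmp <- as.numeric(crossprod(params$proj$temporal, bundle$temporal))
  E <- rbind(e_loc, e_tmp)
  Q <- E %*% params$Wq; K <- E %*% params$Wk; V <- E %*% params$Wv
  for (i in 1:2) {
    sc <- as.numeric(K %*% Q[i, ]) / sqrt(4)
    w <- exp(sc - max(sc)) / sum(exp(sc - max(sc)))
    expect_equal(fz$attended[[c("local", "temporal")[i]]],
                 as.numeric(crossprod(V, w)), tolerance = 1e-12)
  }
})

test_that("classifier produces calibrated softmax probabilities", {
  head <- list(W = matrix(0, 4, 3), b = rep(0, 3))
  out <- classify(c(1, 2, 3, 4), head)
  expect_equal(as.numeric(out$probs), rep(1 / 3, 3))
  # a dominant logit saturates its class
  head$b <- c(50, 0, 0)
  expect_gt(classify(rep(0, 4), head)$probs[1, 1], 0.999999)
  # probabilities always sum to one on fuzzed inputs
  set.seed(17)
  headr <- classifier_head(6, seed = 2)
  Z <- matrix(rnorm(60, sd = 5), 10, 6)
  expect_equal(unname(rowSums(classify(Z, headr)$probs)), rep(1, 10),
               tolerance = 1e-6)
})

test_that("losses match their closed forms", {
  # uniform predictions give ln 3 regardless of labels
  P <- matrix(1 / 3, 5, 3)
  expect_equal(classification_loss(P, c("Normal", "MCI", "AD", "AD", "MCI")),
               log(3), tolerance = 1e-12)
  # perfect one-hot predictions give ~0
  Y <- onehot(c("Normal", "MCI", "AD"))
  expect_lt(classification_loss(pmin(pmax(Y, 1e-12), 1), c("Normal", "MCI", "AD")),
            1e-10)
  # hand case
  expect_equal(classification_loss(matrix(c(0.7, 0.2, 0.1), 1), "Normal"),
               -log(0.7), tolerance = 1e-12)
  # sum reduction is n times the mean
  expect_equal(classification_loss(P, rep("AD", 5), reduce = "sum"),
               5 * log(3), tolerance = 1e-12)

  # contrastive: equal similarities over N = 4 candidates -> ln 4
  anch <- matrix(c(1, 0), 1)
  cands <- matrix(rep(c(1, 0), 4), 4, byrow = TRUE)
  expect_equal(contrastive_loss(anch, cands, 1L, tau = 0.05), log(4),
               tolerance = 1e-9)
  # saturated positive vs opposite negatives -> ~0 at tau = 0.05
  cands2 <- rbind(c(1, 0), c(-1, 0), c(-1, 0))
  expect_lt(contrastive_loss(anch, cands2, 1L, tau = 0.05), 1e-10)
  # hand oracle: sims (0.9, 0.2, -0.5), tau 0.05
  sims <- c(0.9, 0.2, -0.5)
  expected <- -(sims[1] / 0.05 - log(sum(exp(sims / 0.05))))
  a <- c(1, 0)
  mkvec <- function(s) c(s, sqrt(1 - s^2))
  cands3 <- rbind(mkvec(0.9), mkvec(0.2), mkvec(-0.5))
  expect_equal(contrastive_loss(matrix(a, 1), cands3, 1L, tau = 0.05),
               expected, tolerance = 1e-9)
  expect_error(contrastive_loss(anch, cands, NA), "positive")

  # total loss identity and the lambda = 0 degenerate case
  tl <- total_loss(1.25, 2.5, lambda = 0.5)
  expect_equal(tl$l_total, 1.25 + 0.5 * 2.5)
  expect_equal(total_loss(1.25, 99, lambda = 0)$l_total, 1.25)
})

test_that("progression pairs respect the 6-month to 3-year gap rule", {
  base <- as.Date("2015-01-01")
  mkrec <- function(pid, days) {
    notes <- lapply(seq_along(days), function(t) {
      mknote("patient was alert.", id = sprintf("%s_n%d", pid, t), pid = pid,
             ts = base + days[t])
    })
    patient_record(pid, notes, "Normal")
  }
  recs <- list(mkrec("a", c(0, 400)), mkrec("b", c(0, 30)),
               mkrec("c", c(0, 200, 1500)))
  pairs <- sample_progression_pairs(recs, seed = 4)
  expect_true(all(pairs$positives$gap >= 180 & pairs$positives$gap <= 1095))
  expect_true("a" %in% pairs$positives$patient_id)
  # patient b (gap 30 days) contributes no positives
  expect_false("b" %in% pairs$positives$patient_id)
  expect_equal(pairs$n_patients_without_positive, 1L)
  # negatives always span two distinct patients
  expect_true(all(pairs$negatives$patient_a != pairs$negatives$patient_b))
})
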
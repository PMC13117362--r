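# Concept extraction, graph construction and the GraphSAGE encoder.

test_that("concept extraction is longest-match and mask-aware", {
  lex <- read_concept_lexicon()
  hits <- extract_concepts(mknote("memory loss and disorientation today"), lex)
  expect_equal(sort(unique(hits$phrase)), c("disorientation", "memory loss"))
  expect_equal(nrow(hits), 2)

  none <- extract_concepts(mknote("the garden was quiet"), lex)
  expect_equal(nrow(none), 0)

  pol <- mask_policy()
  masked <- extract_concepts(mknote("known alzheimer disease with memory loss"),
                             lex, policy = pol)
  expect_false(any(masked$concept_id %in% pol$concept_ids))
  expect_equal(attr(masked, "n_masked"), 1L)

  expect_error(extract_concepts(mknote("x"), lex[0, ]), "empty")
})

test_that("graph edges combine same-note and temporal co-occurrence", {
  lex <- read_concept_lexicon()
  cid <- function(p) lex$concept_id[match(p, lex$phrase)]
  mk <- function(texts, pid = "g1") {
    notes <- lapply(seq_along(texts), function(t) {
      mknote(texts[[t]], id = sprintf("%s_n%d", pid, t), pid = pid,
             ts = as.Date("2015-01-01") + 30 * t)
    })
    patient_record(pid, notes, "MCI")
  }
  # both concepts in one note -> weight 1
  g <- build_patient_graph(mk("memory loss and disorientation."), lexicon = lex)
  expect_equal(nrow(g$edges), 1)
  expect_equal(g$edges$weight, 1)
  # concepts only in consecutive notes -> temporal edge, weight 1
  g2 <- build_patient_graph(mk(c("memory loss today.", "disorientation today.")),
                            lexicon = lex)
  expect_equal(g2$edges$weight, 1)
  # same-note + temporal accumulate on one undirected edge
  g3 <- build_patient_graph(
    mk(c("memory loss and disorientation.", "disorientation again.",
         "memory loss again.")), lexicon = lex)
  e <- g3$edges
  expect_equal(e$weight[e$a == cid("disorientation") | e$b == cid("disorientation")],
               1 + 2)  # one same-note pair + two consecutive-note pairs
  # no self loops, positive weights
  expect_false(any(g3$edges$a == g3$edges$b))
  expect_true(all(g3$edges$weight > 0))
})

test_that("graphs are capped at the most frequent concepts", {
  big_lex <- data.frame(phrase = sprintf("symptom%03d", 1:250),
                        concept_id = sprintf("CX%03d", 1:250),
                        is_diagnostic = 0, domain = "cognition")
  texts <- vapply(1:25, function(t) {
    paste(sprintf("symptom%03d", ((t - 1) * 10 + 1):(t * 10)), collapse = " and ")
  }, character(1))
  notes <- lapply(seq_along(texts), function(t) {
    mknote(texts[[t]], id = sprintf("c_n%02d", t), pid = "c1",
           ts = as.Date("2015-01-01") + t)
  })
  rec <- patient_record("c1", notes, "AD")
  g <- build_patient_graph(rec, lexicon = big_lex, max_nodes = 200)
  expect_equal(nrow(g$nodes), 200)
  # all concepts tie at frequency 1: lexicographically smallest ids survive
  expect_equal(g$nodes$concept_id, sort(sprintf("CX%03d", 1:200)))
})

test_that("a GraphSAGE step matches a dense brute-force oracle", {
  # isolated node with identity weights and identity activation is a fixed
  # point of the update
  g1 <- structure(list(patient_id = "p", nodes = data.frame(concept_id = "A"),
                       edges = data.frame(a = character(0), b = character(0),
                                          weight = numeric(0))),
                  class = "concept_graph")
  params <- graph_encoder_params(dim_in = 3, dim_hidden = 3, n_layers = 1, seed = 1)
  params$W[[1]] <- diag(3)
  h <- matrix(c(0.3, -1, 2), 1, 3, dimnames = list("A", NULL))
  expect_equal(graphsage_layer(h, g1, params, 1, activation = identity), h)

  # exhaustive equivalence with a dense implementation on all graphs of
  # up to 5 nodes (neighbourhood cap not binding)
  dense_step <- function(h, adj_mat, W, act) {
    n <- nrow(h)
    out <- matrix(0, n, ncol(W))
    for (v in seq_len(n)) {
      nb <- which(adj_mat[v, ] > 0)
      agg <- colMeans(h[c(v, nb), , drop = FALSE])
      out[v, ] <- act(as.numeric(crossprod(W, agg)))
    }
    rownames(out) <- rownames(h)
    out
  }
  set.seed(21)
  for (n in 2:5) {
    n_pairs <- choose(n, 2)
    combos <- if (n <= 4) seq_len(2^n_pairs) - 1 else
      sample(0:(2^n_pairs - 1), 40)
    ids <- LETTERS[seq_len(n)]
    prm <- graph_encoder_params(dim_in = 2, dim_hidden = 2, n_layers = 1,
                                seed = n)
    for (code in combos) {
      bits <- as.integer(intToBits(code))[seq_len(n_pairs)]
      adj <- matrix(0, n, n)
      adj[lower.tri(adj)] <- bits
      adj <- adj + t(adj)
      pairs <- which(lower.tri(adj) & adj > 0, arr.ind = TRUE)
      g <- structure(list(
        patient_id = "p",
        nodes = data.frame(concept_id = ids),
        edges = data.frame(a = ids[pairs[, 2]], b = ids[pairs[, 1]],
                           weight = rep(1, nrow(pairs)))),
        class = "concept_graph")
      h <- matrix(rnorm(2 * n), n, 2, dimnames = list(ids, NULL))
      expect_equal(graphsage_layer(h, g, prm, 1),
                   dense_step(h, adj, prm$W[[1]], relu),
                   tolerance = 1e-12)
    }
  }
})

test_that("neighbour sampling caps at the configured size, deterministically", {
  ids <- c("HUB", sprintf("N%02d", 1:25))
  g <- structure(list(
    patient_id = "p7",
    nodes = data.frame(concept_id = ids),
    edges = data.frame(a = "HUB", b = ids[-1], weight = 1)),
    class = "concept_graph")
  nb <- graph_adjacency(g)[["HUB"]]
  expect_length(nb, 25)
  s1 <- sample_neighbors(nb, 10, "p7", "HUB")
  s2 <- sample_neighbors(nb, 10, "p7", "HUB")
  expect_length(s1, 10)
  expect_identical(s1, s2)
})

test_that("pooling and permutation invariance", {
  h1 <- matrix(c(1, 2, 3), 1, 3)
  expect_equal(as.numeric(graph_pool(h1)), c(1, 2, 3))
  hc <- matrix(rep(c(4, 5), each = 6), 6, 2)
  expect_equal(as.numeric(graph_pool(hc)), c(4, 5))
  empty <- graph_pool(matrix(numeric(0), 0, 4), dim = 4)
  expect_equal(as.numeric(empty), rep(0, 4))
  expect_true(attr(empty, "no_concepts"))

  # permuting note order of concept mentions leaves g_p unchanged
  lex <- read_concept_lexicon()
  texts <- c("memory loss and confusion.", "poor recall and confusion.",
             "memory loss with caregiver support.")
  mkrec <- function(ord) {
    notes <- lapply(seq_along(ord), function(t) {
      mknote(texts[ord[t]], id = sprintf("perm_n%d", t), pid = "perm",
             ts = as.Date("2016-01-01") + 10 * t)
    })
    patient_record("perm", notes, "MCI")
  }
  params <- graph_encoder_params(seed = 4)
  g_a <- build_patient_graph(mkrec(1:3), lexicon = lex)
  # reversing note order preserves the (undirected) edge structure here
  g_b <- build_patient_graph(mkrec(3:1), lexicon = lex)
  expect_equal(encode_graph(g_a, params), encode_graph(g_b, params))
})

test_that("masked diagnostic concepts never appear in any graph", {
  corpus <- fixture_corpus_small()[1:6]
  pol <- mask_policy()
  for (rec in corpus) {
    g <- build_patient_graph(rec, policy = pol)
    expect_false(any(g$nodes$concept_id %in% pol$concept_ids))
  }
})
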
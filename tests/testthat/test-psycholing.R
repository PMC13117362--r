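# The nine psycholinguistic biomarkers.

test_that("type-token ratio matches hand counts and bounds", {
  expect_equal(type_token_ratio(c("patient", "is", "alert", "patient", "is", "calm")),
               4 / 6)
  expect_equal(type_token_ratio(letters[1:7]), 1.0)
  expect_equal(type_token_ratio(rep("word", 10)), 0.1)
  expect_true(is.na(type_token_ratio(character(0))))
  # case-folded comparison
  expect_equal(type_token_ratio(c("Word", "word")), 0.5)
})

test_that("adding repeated tokens never increases TTR", {
  set.seed(11)
  for (i in 1:200) {
    toks <- sample(letters, sample(3:30, 1), replace = TRUE)
    more <- c(toks, sample(toks, sample(1:5, 1), replace = TRUE))
    expect_lte(type_token_ratio(more), type_token_ratio(toks))
  }
})

test_that("MATTR reduces to TTR on short notes and averages sliding windows", {
  toks30 <- sample(rep(letters[1:10], 3))
  expect_equal(mattr(toks30, 50), type_token_ratio(toks30))
  # periodic ab sequence of length 100: every 50-window holds 2 types
  ab <- rep(c("a", "b"), 50)
  expect_equal(mattr(ab, 50), 2 / 50)
  expect_equal(mattr(c("x", "y", "x", "z"), 1), 1.0)
  # brute-force window oracle on a random sequence
  set.seed(3)
  toks <- sample(letters[1:6], 80, replace = TRUE)
  brute <- mean(vapply(1:(80 - 20 + 1), function(s) {
    length(unique(toks[s:(s + 19)])) / 20
  }, numeric(1)))
  expect_equal(mattr(toks, 20), brute, tolerance = 1e-12)
})

test_that("clause-based features match manual segmentation arithmetic", {
  seg <- segment_note("the patient ate well, because the meal was warm. she rested.")
  # clauses: 4 tokens, 5 tokens (subordinate), 2 tokens
  expect_equal(mean_length_of_utterance(seg), (4 + 5 + 2) / 3)
  expect_equal(subordination_index(seg), 1 / 3)

  one <- segment_note("the nurse described the full morning routine")
  expect_equal(mean_length_of_utterance(one), 7)
  expect_equal(subordination_index(one), 0)

  allsub <- segment_note("because he slept, although she walked.")
  expect_equal(subordination_index(allsub), 1.0)
})

test_that("lexical cohesion averages consecutive-pair cosines", {
  same <- matrix(rep(c(1, 2, 3), 4), nrow = 4, byrow = TRUE)
  expect_equal(lexical_cohesion(same), 1.0)
  orth <- rbind(c(1, 0), c(0, 1), c(1, 0))
  expect_equal(lexical_cohesion(orth), 0.0)
  # hand case: cosines 0.8 and 0.4 -> 0.6
  v1 <- c(1, 0); v2 <- c(0.8, sqrt(1 - 0.8^2))
  # third vector at cosine 0.4 from v2
  ang2 <- acos(0.8) + acos(0.4)
  v3 <- c(cos(ang2), sin(ang2))
  expect_equal(lexical_cohesion(rbind(v1, v2, v3)), 0.6, tolerance = 1e-9)
  expect_true(is.na(lexical_cohesion(matrix(1, 1, 3))))
})

test_that("referential clarity follows the antecedent-window rule", {
  # no pronouns -> 1 by convention
  expect_equal(referential_clarity(segment_note("the nurse described the plan.")), 1.0)
  # every pronoun without any antecedent -> 0
  expect_equal(referential_clarity(segment_note("he was there. she was not here.")), 0.0)
  # 3 pronouns, 1 ambiguous under k = 2: the opening pronoun has no
  # antecedent; the two later ones follow a noun-bearing sentence
  txt <- "she was not there. the nurse saw the patient. he ate well. it was warm."
  expect_equal(referential_clarity(segment_note(txt), k = 2), 2 / 3)
  # widening the window can rescue a distant antecedent
  far <- "the nurse was here. he was not there. still not there. he paused."
  expect_equal(referential_clarity(segment_note(far), k = 1), 0.5)
  expect_equal(referential_clarity(segment_note(far), k = 3), 1.0)
})

test_that("note_vector populates all nine features deterministically", {
  txt <- paste0("the patient ate breakfast, because the meal was warm. ",
                "she enjoyed the meal. the patient rested in the garden.")
  nt <- mknote(txt)
  v <- note_vector(nt)
  expect_named(v, PSYCH_FEATURES)
  toks <- tokenize_text(txt)
  expect_equal(unname(v["ttr"]), length(unique(toks)) / length(toks))
  expect_equal(unname(v["mattr"]), unname(v["ttr"]))  # short note
  expect_equal(unname(v["mlu"]), length(toks) / 4)    # 4 clauses
  expect_equal(unname(v["subordination_index"]), 1 / 4)
  expect_equal(unname(v["referential_clarity"]), 1.0) # 'she' after nouns
  expect_equal(unname(v["content_function_ratio"]),
               sum(!is_function_token(toks)) / length(toks))
  # byte-identical notes give identical vectors
  expect_identical(v, note_vector(mknote(txt)))
  # a degenerate note yields sentinels, not values
  v0 <- note_vector(mknote("..."))
  expect_true(all(is.na(v0[c("ttr", "mattr", "mlu")])))
})

test_that("features respect their declared ranges on fuzzed token streams", {
  set.seed(99)
  pool <- c(letters, PRONOUNS, SUBORDINATORS, FUNCTION_WORDS)
  for (i in 1:300) {
    toks <- sample(pool, sample(1:120, 1), replace = TRUE)
    txt <- paste(toks, collapse = " ")
    v <- note_vector(mknote(txt))
    ok <- !is.na(v)
    expect_true(all(is.finite(v[ok])))
    for (f in c("ttr", "mattr", "subordination_index", "entity_overlap",
                "referential_clarity", "content_function_ratio")) {
      if (!is.na(v[f])) expect_true(v[f] >= 0 && v[f] <= 1)
    }
    if (!is.na(v["lexical_cohesion"])) {
      expect_true(abs(v["lexical_cohesion"]) <= 1 + 1e-12)
    }
    if (!is.na(v["mlu"])) expect_gte(v["mlu"], 0)
  }
})

test_that("patient aggregation is an attention-weighted mean with sentinel handling", {
  v <- rbind(c(0.8, rep(0.5, 8)), c(0.4, rep(0.5, 8)))
  colnames(v) <- PSYCH_FEATURES
  # uniform weights over identical vectors reproduce the vector
  same <- rbind(v[1, ], v[1, ], v[1, ])
  expect_equal(aggregate_patient(same), v[1, ])
  # degenerate attention picks one note
  expect_equal(aggregate_patient(v, c(1, 0)), v[1, ])
  # weighted mean: 0.25 * 0.8 + 0.75 * 0.4 = 0.5
  expect_equal(unname(aggregate_patient(v, c(0.25, 0.75))["ttr"]), 0.5)
  # sentinels are excluded with weight renormalization
  v2 <- v; v2[1, "ttr"] <- NA
  expect_equal(unname(aggregate_patient(v2, c(0.25, 0.75))["ttr"]), 0.4)
  v3 <- v; v3[, "ttr"] <- NA
  expect_true(is.na(aggregate_patient(v3)["ttr"]))
  # invalid weights are rejected
  expect_error(aggregate_patient(v, c(0.5, 0.2)), "sum to 1")
})
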
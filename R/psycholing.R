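# The nine note-level psycholinguistic biomarkers and their patient-level
# attention-weighted aggregation.
#
# Features: lexical diversity (TTR, MATTR, content/function ratio),
# syntactic complexity (mean length of utterance, parse depth,
# subordination index) and discourse coherence (entity overlap, lexical
# cohesion, referential clarity). All are deterministic under the heuristic
# segmentation adapter. Undefined features are returned as NA sentinels and
# excluded (with weight renormalization) at aggregation time rather than
# imputed.

PSYCH_FEATURES <- c("ttr", "mattr", "content_function_ratio", "mlu",
                    "parse_depth", "subordination_index", "entity_overlap",
                    "lexical_cohesion", "referential_clarity")

#' Type-token ratio
#'
#' Unique case-folded word types divided by total tokens.
#'
#' @param tokens Character vector of word tokens.
#' @return Ratio in (0, 1], or `NA` for an empty token list.
#' @export
type_token_ratio <- function(tokens) {
  if (length(tokens) == 0) return(NA_real_)
  tokens <- tolower(tokens)
  length(unique(tokens)) / length(tokens)
}

#' Moving-average type-token ratio
#'
#' Mean TTR over all contiguous windows of exactly `window` tokens
#' (stride 1). Falls back to the plain TTR when the note is no longer than
#' the window.
#'
#' @param tokens Character vector of word tokens.
#' @param window Window length in tokens (default 50).
#' @return Ratio in (0, 1], or `NA` for an empty token list.
#' @export
mattr <- function(tokens, window = 50L) {
  stopifnot(window >= 1)
  n <- length(tokens)
  if (n == 0) return(NA_real_)
  tokens <- tolower(tokens)
  if (n <= window) return(type_token_ratio(tokens))
  # incremental distinct count over the sliding window
  counts <- new.env(hash = TRUE, parent = emptyenv())
  distinct <- 0L
  add <- function(t) {
    c0 <- counts[[t]] %||% 0L
    if (c0 == 0L) distinct <<- distinct + 1L
    counts[[t]] <- c0 + 1L
  }
  drop1 <- function(t) {
    c0 <- counts[[t]]
    if (c0 == 1L) distinct <<- distinct - 1L
    counts[[t]] <- c0 - 1L
  }
  for (i in seq_len(window)) add(tokens[i])
  total <- distinct
  n_win <- n - window + 1L
  for (s in 2:n_win) {
    drop1(tokens[s - 1L])
    add(tokens[s + window - 1L])
    total <- total + distinct
  }
  total / (n_win * window)
}

#' Mean length of utterance
#'
#' Average word tokens per clause under the supplied segmentation.
#'
#' @param seg A [segment_note()] result.
#' @return Tokens per clause, or `NA` when there are no clauses.
#' @export
mean_length_of_utterance <- function(seg) {
  n_cl <- nrow(seg$clauses)
  if (n_cl == 0) return(NA_real_)
  sum(seg$clauses$n_tokens) / n_cl
}

#' Subordination index
#'
#' Fraction of clauses flagged subordinate.
#'
#' @param seg A [segment_note()] result.
#' @return Ratio in \[0, 1\], or `NA` when there are no clauses.
#' @export
subordination_index <- function(seg) {
  n_cl <- nrow(seg$clauses)
  if (n_cl == 0) return(NA_real_)
  sum(seg$clauses$subordinate) / n_cl
}

#' Lexical cohesion between adjacent sentences
#'
#' Mean cosine similarity of consecutive sentence embeddings. The default
#' adapter embeds a sentence as its L2-normalized bag-of-words count vector;
#' pre-computed dense embeddings (one row per sentence) can be passed
#' instead.
#'
#' @param x A [segment_note()] result, or a numeric matrix of sentence
#'   embeddings (rows in sentence order).
#' @return Mean cosine in \[-1, 1\], or `NA` with fewer than two sentences.
#' @export
lexical_cohesion <- function(x) {
  if (inherits(x, "clause_segmentation")) {
    stoks <- Filter(length, x$sentence_tokens)
    if (length(stoks) < 2) return(NA_real_)
    vocab <- unique(unlist(stoks))
    emb <- t(vapply(stoks, function(tk) {
      tabulate(match(tk, vocab), nbins = length(vocab))
    }, numeric(length(vocab))))
  } else {
    emb <- as.matrix(x)
  }
  if (nrow(emb) < 2) return(NA_real_)
  sims <- vapply(seq_len(nrow(emb) - 1L), function(i) {
    cosine_sim(emb[i, ], emb[i + 1L, ])
  }, numeric(1))
  mean(sims)
}

# Entity overlap: for each consecutive sentence pair with entities in the
# later sentence, |shared entities| / |entities in later sentence|.
entity_overlap <- function(seg) {
  stoks <- seg$sentence_tokens
  if (length(stoks) < 2) return(NA_real_)
  ents <- lapply(stoks, entity_tokens)
  vals <- numeric(0)
  for (i in 2:length(ents)) {
    if (length(ents[[i]]) == 0) next
    vals <- c(vals, length(intersect(ents[[i - 1L]], ents[[i]])) / length(ents[[i]]))
  }
  if (length(vals) == 0) return(NA_real_)
  mean(vals)
}

#' Referential clarity
#'
#' One minus the fraction of pronouns that are ambiguous. A pronoun is
#' ambiguous when no candidate antecedent (content token under the entity
#' heuristic) occurs in the `k` sentences preceding the pronoun's sentence.
#' Notes without pronouns score 1 by convention.
#'
#' @param seg A [segment_note()] result.
#' @param k Antecedent search window in sentences (default 2).
#' @return Ratio in \[0, 1\].
#' @export
referential_clarity <- function(seg, k = 2L) {
  stoks <- seg$sentence_tokens
  if (length(stoks) == 0) return(1)
  ents <- lapply(stoks, entity_tokens)
  n_pron <- 0L; n_amb <- 0L
  for (si in seq_along(stoks)) {
    p <- sum(stoks[[si]] %in% PRONOUNS)
    if (p == 0) next
    n_pron <- n_pron + p
    prev <- seq_len(si - 1L)
    prev <- prev[prev >= si - k]
    has_ante <- length(prev) > 0 &&
      any(vapply(prev, function(j) length(ents[[j]]) > 0, logical(1)))
    if (!has_ante) n_amb <- n_amb + p
  }
  if (n_pron == 0) return(1)
  1 - n_amb / n_pron
}

content_function_ratio <- function(tokens) {
  if (length(tokens) == 0) return(NA_real_)
  fn <- is_function_token(tokens)
  sum(!fn) / length(tokens)
}

#' Extract the nine psycholinguistic features from a note
#'
#' @param note A [note()] object (tokens are computed from its text when not
#'   already populated).
#' @param parser Segmentation adapter: a function `text -> clause_segmentation`
#'   (default [segment_note()], the deterministic heuristic adapter).
#' @param mattr_window MATTR window length (default 50).
#' @param antecedent_window Referential-clarity search window `k` (default 2).
#' @return A named numeric vector of length 9 (NA marks undefined features).
#' @export
note_vector <- function(note, parser = segment_note, mattr_window = 50L,
                        antecedent_window = 2L) {
  tokens <- if (length(note$tokens)) note$tokens else tokenize_text(note$text)
  seg <- parser(note$text)
  depths <- sentence_depths(seg)
  c(ttr = type_token_ratio(tokens),
    mattr = mattr(tokens, mattr_window),
    content_function_ratio = content_function_ratio(tokens),
    mlu = mean_length_of_utterance(seg),
    parse_depth = if (length(depths)) mean(depths) else NA_real_,
    subordination_index = subordination_index(seg),
    entity_overlap = entity_overlap(seg),
    lexical_cohesion = lexical_cohesion(seg),
    referential_clarity = referential_clarity(seg, antecedent_window))
}

#' Attention-weighted patient-level aggregation of note vectors
#'
#' Weighted mean per feature with NA sentinels excluded and the remaining
#' weights renormalized. A feature undefined in every note stays NA at the
#' patient level.
#'
#' @param vectors Matrix (notes x 9) or list of note vectors.
#' @param weights Non-negative attention weights summing to 1, one per note.
#'   Default: uniform.
#' @return Named numeric vector of length 9.
#' @export
aggregate_patient <- function(vectors, weights = NULL) {
  if (is.list(vectors)) vectors <- do.call(rbind, vectors)
  vectors <- as.matrix(vectors)
  n <- nrow(vectors)
  if (is.null(weights)) weights <- rep(1 / n, n)
  stopifnot(length(weights) == n, all(weights >= -1e-12))
  if (abs(sum(weights) - 1) > 1e-6) stopf("attention weights must sum to 1")
  out <- vapply(seq_len(ncol(vectors)), function(j) {
    v <- vectors[, j]; ok <- !is.na(v)
    if (!any(ok) || sum(weights[ok]) == 0) return(NA_real_)
    sum(v[ok] * weights[ok]) / sum(weights[ok])
  }, numeric(1))
  stats::setNames(out, colnames(vectors) %||% PSYCH_FEATURES)
}

#' Per-note feature matrix for a corpus
#'
#' @param records List of patient records.
#' @param ... Passed to [note_vector()].
#' @return Data frame with `patient_id`, `note_id` and the nine features.
#' @export
feature_matrix <- function(records, ...) {
  rows <- lapply(records, function(rec) {
    vs <- lapply(rec$notes, note_vector, ...)
    cbind(data.frame(patient_id = rec$patient_id,
                     note_id = vapply(rec$notes, function(n) n$note_id, character(1))),
          as.data.frame(do.call(rbind, vs)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Patient-level mean psych vectors (uniform attention), used by ADASYN and
# the counterfactual baseline.
patient_psych_matrix <- function(records, ...) {
  m <- t(vapply(records, function(rec) {
    vs <- do.call(rbind, lapply(rec$notes, note_vector, ...))
    aggregate_patient(vs)
  }, numeric(length(PSYCH_FEATURES))))
  rownames(m) <- vapply(records, function(r) r$patient_id, character(1))
  colnames(m) <- PSYCH_FEATURES
  m
}
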
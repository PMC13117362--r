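# Tokenization and heuristic sentence/clause segmentation.
#
# The default linguistic adapter is fully deterministic: sentences are split
# on terminal punctuation, clauses on commas/semicolons/colons, and a clause
# is flagged subordinate when it opens with a subordinating conjunction.
# A constituency parser can be swapped in through the parser adapter argument
# of note_vector(); everything downstream only consumes the segmentation
# structure defined here.

.PLACEHOLDER_RE <- "\\[\\*\\*[^]]*\\*\\*\\]|<[a-z]+>"
.TOKEN_RE <- paste0(.PLACEHOLDER_RE, "|[A-Za-z0-9']+")

#' Tokenize text into word tokens
#'
#' Case-folding word tokenizer. PHI placeholders of the form `[**...**]` and
#' reserved angle tokens such as `<mask>` survive as single tokens;
#' punctuation is dropped.
#'
#' @param text Character scalar.
#' @return Character vector of lower-case tokens.
#' @export
tokenize_text <- function(text) {
  if (length(text) != 1L || is.na(text)) return(character(0))
  m <- gregexpr(.TOKEN_RE, text, perl = TRUE)
  tolower(regmatches(text, m)[[1]])
}

#' Segment a note into sentences and clauses
#'
#' Heuristic segmentation: sentences split on `.`, `?`, `!`; clauses split on
#' `,`, `;`, `:`. A clause is subordinate when its first token is a
#' subordinating conjunction from the closed lexicon.
#'
#' @param text Character scalar.
#' @return An object of class `clause_segmentation`: a list with a `clauses`
#'   data.frame (`sentence`, `clause`, `subordinate`, `n_tokens`), a list of
#'   token vectors per clause (`tokens`), and per-sentence token lists
#'   (`sentence_tokens`).
#' @export
segment_note <- function(text) {
  sent_raw <- strsplit(text, "[.?!]+", perl = TRUE)[[1]]
  sent_raw <- trimws(sent_raw)
  sent_raw <- sent_raw[nzchar(sent_raw)]
  rows <- list(); toks <- list(); stoks <- list()
  for (si in seq_along(sent_raw)) {
    cl_raw <- strsplit(sent_raw[[si]], "[,;:]+", perl = TRUE)[[1]]
    cl_raw <- trimws(cl_raw)
    cl_raw <- cl_raw[nzchar(cl_raw)]
    sent_tok <- character(0)
    for (ci in seq_along(cl_raw)) {
      tk <- tokenize_text(cl_raw[[ci]])
      if (length(tk) == 0) next
      rows[[length(rows) + 1L]] <- data.frame(
        sentence = si, clause = ci,
        subordinate = tk[1] %in% SUBORDINATORS,
        n_tokens = length(tk)
      )
      toks[[length(toks) + 1L]] <- tk
      sent_tok <- c(sent_tok, tk)
    }
    stoks[[si]] <- sent_tok
  }
  clauses <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sentence = integer(0), clause = integer(0),
               subordinate = logical(0), n_tokens = integer(0))
  structure(list(clauses = clauses, tokens = toks, sentence_tokens = stoks),
            class = "clause_segmentation")
}

# Heuristic per-sentence parse depth: 1 for a flat single-clause sentence,
# +1 when the sentence is multi-clause, +1 per subordinate clause. A stand-in
# for maximum constituency depth under the deterministic adapter.
sentence_depths <- function(seg) {
  cl <- seg$clauses
  if (nrow(cl) == 0) return(numeric(0))
  vapply(split(cl, cl$sentence), function(s) {
    1 + as.numeric(nrow(s) > 1) + sum(s$subordinate)
  }, numeric(1))
}

# Entity heuristic: candidate referring expressions are content tokens
# (not function words, pronouns, subordinators, placeholders) of length >= 3.
entity_tokens <- function(tokens) {
  keep <- !is_function_token(tokens) & nchar(tokens) >= 3 &
    !grepl("^\\[\\*\\*|^<", tokens)
  unique(tokens[keep])
}
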
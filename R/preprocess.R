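# Text normalization, diagnosis masking, patient-atomic ADASYN balancing
# and (stub-gated) training-set augmentation.

#' Normalize a note
#'
#' Expands clinical abbreviations (word-boundary, case-insensitive),
#' optionally applies a spelling-normalization adapter, collapses
#' whitespace, and populates the token field. PHI placeholders such as
#' `[**NAME**]` survive as single distinct tokens. Idempotent: applying the
#' function twice gives the same note.
#'
#' @param note A [note()] object.
#' @param abbrev_table Named character vector short form -> expansion
#'   (default: the bundled clinical abbreviation table).
#' @param speller Optional adapter `function(text) -> text`; when absent the
#'   spelling step is skipped with a log notice.
#' @param quiet Suppress the adapter notice.
#' @return The normalized note with `tokens` filled and an
#'   `abbreviations_expanded` count field.
#' @export
normalize_note <- function(note, abbrev_table = default_abbreviations(),
                           speller = NULL, quiet = FALSE) {
  n_exp <- 0L
  expand <- function(text) {
    for (short in names(abbrev_table)[order(-nchar(names(abbrev_table)))]) {
      re <- paste0("(?<![A-Za-z])", gsub("([][{}()+*^$|\\\\?./])", "\\\\\\1", short),
                   "(?![A-Za-z])")
      m <- gregexpr(re, text, perl = TRUE, ignore.case = TRUE)[[1]]
      hits <- sum(m > 0)
      if (hits > 0) {
        n_exp <<- n_exp + hits
        text <- gsub(re, abbrev_table[[short]], text, perl = TRUE, ignore.case = TRUE)
      }
    }
    text
  }
  squeeze <- function(text) trimws(gsub("\\s+", " ", text))
  apply_all <- function(text) {
    text <- expand(text)
    if (!is.null(speller)) text <- speller(text)
    squeeze(text)
  }
  if (is.null(speller) && !quiet && !isTRUE(note$normalized)) {
    message("normalize_note: no speller adapter configured; spelling step skipped")
  }
  note$sections <- lapply(note$sections, apply_all)
  n_exp <- 0L  # count expansions once, over the canonical full text
  note$text <- apply_all(note$text)
  note$tokens <- tokenize_text(note$text)
  note$abbreviations_expanded <- n_exp
  note$normalized <- TRUE
  note
}

#' Construct a diagnosis masking policy
#'
#' @param terms Character vector of diagnosis surface strings to mask
#'   (default: the bundled lexicon of dementia-related terms).
#' @param concept_ids Concept ids to drop at graph construction time
#'   (default: the diagnostic rows of the bundled concept lexicon).
#' @param replacement Single reserved token that replaces each match; must
#'   not itself appear in the term lexicon.
#' @return A `mask_policy` list.
#' @export
mask_policy <- function(terms = default_mask_terms(),
                        concept_ids = NULL,
                        replacement = "<mask>") {
  if (length(terms) == 0) stopf("mask policy needs a non-empty term lexicon")
  if (any(tolower(terms) == tolower(replacement))) {
    stopf("replacement token must be absent from the term lexicon")
  }
  if (is.null(concept_ids)) {
    lex <- read_concept_lexicon()
    concept_ids <- unique(lex$concept_id[lex$is_diagnostic == 1])
  }
  structure(list(terms = terms, concept_ids = concept_ids,
                 replacement = replacement),
            class = "mask_policy")
}

#' Mask diagnostic language in a note
#'
#' Replaces every case-insensitive occurrence of a policy term with the
#' reserved mask token, longest match first and left to right, so a longer
#' term containing a shorter one yields a single mask token.
#'
#' @param note A [note()] object.
#' @param policy A [mask_policy()].
#' @return The masked note; the `masked_terms` field counts replacements.
#' @export
mask_diagnostic_language <- function(note, policy = mask_policy()) {
  n_masked <- 0L
  mask_text <- function(text) {
    for (term in policy$terms[order(-nchar(policy$terms))]) {
      re <- paste0("(?<![A-Za-z])",
                   gsub("([][{}()+*^$|\\\\?./'])", "\\\\\\1", term),
                   "(?![A-Za-z])")
      m <- gregexpr(re, text, perl = TRUE, ignore.case = TRUE)[[1]]
      hits <- sum(m > 0)
      if (hits > 0) {
        n_masked <<- n_masked + hits
        text <- gsub(re, policy$replacement, text, perl = TRUE, ignore.case = TRUE)
      }
    }
    text
  }
  note$sections <- lapply(note$sections, mask_text)
  n_masked <- 0L  # count replacements once, over the canonical full text
  note$text <- mask_text(note$text)
  if (length(note$tokens)) note$tokens <- tokenize_text(note$text)
  note$masked_terms <- (note$masked_terms %||% 0L) + n_masked
  note
}

#' Corpus-level normalization report
#'
#' @param records_before,records_after Corpora before and after
#'   [normalize_note()] / [mask_diagnostic_language()].
#' @return List with token count mean/SD before and after, abbreviation
#'   expansions and masked term counts.
#' @export
normalization_report <- function(records_before, records_after) {
  count_tokens <- function(recs) {
    unlist(lapply(recs, function(r) vapply(r$notes, function(n) {
      length(if (length(n$tokens)) n$tokens else tokenize_text(n$text))
    }, numeric(1))))
  }
  tb <- count_tokens(records_before); ta <- count_tokens(records_after)
  sum_field <- function(recs, f) {
    sum(unlist(lapply(recs, function(r)
      vapply(r$notes, function(n) n[[f]] %||% 0L, numeric(1)))))
  }
  list(tokens_before = c(mean = mean(tb), sd = sd(tb)),
       tokens_after = c(mean = mean(ta), sd = sd(ta)),
       abbreviations_expanded = sum_field(records_after, "abbreviations_expanded"),
       masked_terms = sum_field(records_after, "masked_terms"))
}

#' Patient-atomic ADASYN oversampling
#'
#' Balances class counts in a training split by duplicating whole patient
#' records of minority classes. Sampling weights follow the ADASYN density
#' rule on patient-level psycholinguistic mean vectors: patients whose
#' k-nearest neighbours contain more out-of-class patients are more likely
#' to be copied. Copies are verbatim (note sequences byte-identical to the
#' source), receive ids `<orig>_syn<k>` and `provenance = "oversampled"`.
#' No synthetic intermediate visits or note-level blending are created.
#'
#' @param records Training-split patient records.
#' @param features Optional patient-by-feature matrix (rows named by patient
#'   id); defaults to the 9-dimensional patient-mean psycholinguistic
#'   vectors.
#' @param seed Integer seed.
#' @param k Neighbourhood size for the density weights.
#' @param splits Optional [split_patients()] assignment; when supplied,
#'   every record must be in the train split (leakage guard).
#' @return Records plus oversampled copies, approximately class-balanced.
#' @export
adasyn_patient_oversample <- function(records, features = NULL, seed = 1L,
                                      k = 5L, splits = NULL) {
  if (!is.null(splits)) {
    sp <- splits$split[match(vapply(records, function(r) r$patient_id, character(1)),
                             splits$patient_id)]
    if (any(sp != "train", na.rm = TRUE)) {
      stopf("ADASYN may only be applied to the training split")
    }
  }
  labs <- vapply(records, function(r) r$label, character(1))
  counts <- table(labs)
  n_max <- max(counts)
  if (is.null(features)) features <- patient_psych_matrix(records)
  feats <- scale(features)
  feats[is.na(feats)] <- 0
  out <- records
  withr::with_seed(seed, {
    for (cl in names(counts)) {
      G <- n_max - counts[[cl]]
      if (G == 0) next
      idx <- which(labs == cl)
      if (length(idx) < 2) stopf("class %s has a single patient; ADASYN density undefined", cl)
      kk <- min(k, nrow(feats) - 1L)
      r <- vapply(idx, function(i) {
        d <- sqrt(rowSums((feats - matrix(feats[i, ], nrow(feats), ncol(feats),
                                          byrow = TRUE))^2))
        nb <- order(d)[2:(kk + 1L)]
        mean(labs[nb] != cl)
      }, numeric(1))
      w <- if (sum(r) == 0) rep(1 / length(idx), length(idx)) else r / sum(r)
      g <- apportion(G * w)
      for (j in seq_along(idx)) {
        rec <- records[[idx[j]]]
        for (s in seq_len(g[j])) {
          cp <- rec
          cp$patient_id <- sprintf("%s_syn%d", rec$patient_id, s)
          cp$provenance <- "oversampled"
          out[[length(out) + 1L]] <- cp
        }
      }
    }
  })
  out
}

#' Augment training notes
#'
#' Only the bundled synonym-substitution method is implemented (a toy
#' synonym lexicon applied within patient boundaries, appending one variant
#' record per source patient). Back-translation and masked-LM perturbation
#' are registered as adapter stubs that raise until an external adapter is
#' configured.
#'
#' @param records Training-split patient records.
#' @param methods Subset of `c("synonym", "backtranslation", "mlm")`.
#' @param synonyms Named vector term -> synonym.
#' @param splits Optional split assignment; any non-train record is fatal.
#' @return Records plus augmented variants (`provenance = "augmented"`).
#' @export
augment_training_notes <- function(records, methods = "synonym",
                                   synonyms = default_synonyms(),
                                   splits = NULL) {
  if (!is.null(splits)) {
    sp <- splits$split[match(vapply(records, function(r) r$patient_id, character(1)),
                             splits$patient_id)]
    if (any(sp != "train", na.rm = TRUE)) {
      stopf("augmentation may only be applied to the training split")
    }
  }
  bad <- setdiff(methods, c("synonym", "backtranslation", "mlm"))
  if (length(bad)) stopf("unknown augmentation method(s): %s", paste(bad, collapse = ", "))
  if (any(c("backtranslation", "mlm") %in% methods)) {
    stopf("adapter not configured: %s requires an external model adapter",
          intersect(c("backtranslation", "mlm"), methods)[1])
  }
  out <- records
  for (rec in records) {
    cp <- rec
    cp$patient_id <- paste0(rec$patient_id, "_aug1")
    cp$provenance <- "augmented"
    cp$notes <- lapply(rec$notes, function(nt) {
      sub_all <- function(text) {
        for (term in names(synonyms)) {
          text <- gsub(paste0("(?<![A-Za-z])", term, "(?![A-Za-z])"),
                       synonyms[[term]], text, perl = TRUE, ignore.case = TRUE)
        }
        text
      }
      nt$sections <- lapply(nt$sections, sub_all)
      nt$text <- sub_all(nt$text)
      if (length(nt$tokens)) nt$tokens <- tokenize_text(nt$text)
      nt
    })
    out[[length(out) + 1L]] <- cp
  }
  out
}
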
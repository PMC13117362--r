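# Closed lexica used by the heuristic linguistic adapter and the synthetic
# corpus generator. The extractor and the generator deliberately share these
# lists so that generated text is segmented and tagged unambiguously.

# Function words: articles, prepositions, auxiliaries, coordinators, common
# adverbs and negators. Pronouns are kept in their own list (they are also
# function words for the content/function split, see is_function_token()).
FUNCTION_WORDS <- c(
  "a", "an", "the", "of", "to", "in", "on", "at", "by", "for", "with",
  "from", "into", "over", "under", "and", "or", "but", "nor", "so", "as",
  "is", "are", "was", "were", "be", "been", "being", "am", "has", "have",
  "had", "do", "does", "did", "will", "would", "can", "could", "may",
  "might", "shall", "should", "must", "not", "no", "yes", "very", "quite",
  "again", "still", "also", "then", "there", "here", "now", "today", "up",
  "down", "out", "off", "about", "per"
)

PRONOUNS <- c(
  "he", "she", "it", "they", "them", "him", "her", "his", "hers", "its",
  "their", "theirs", "this", "these", "those"
)

SUBORDINATORS <- c(
  "because", "although", "while", "since", "if", "when", "after", "before",
  "unless", "whereas", "until"
)

# Content stems for synthetic note realization; pluralized programmatically.
.CONTENT_STEMS <- c(
  "patient", "nurse", "doctor", "daughter", "son", "wife", "husband",
  "caregiver", "family", "ward", "room", "bed", "chair", "walker", "cane",
  "meal", "breakfast", "lunch", "dinner", "appetite", "sleep", "night",
  "morning", "afternoon", "evening", "week", "month", "year", "visit",
  "clinic", "hospital", "home", "garden", "kitchen", "bathroom", "stair",
  "medication", "tablet", "dose", "vital", "pressure", "pulse", "weight",
  "temperature", "mood", "memory", "attention", "speech", "word", "name",
  "story", "question", "answer", "task", "test", "score", "plan", "goal",
  "routine", "schedule", "appointment", "therapy", "exercise", "walk",
  "transfer", "balance", "fall", "injury", "pain", "headache", "fatigue",
  "energy", "strength", "hand", "arm", "leg", "foot", "head", "eye", "ear",
  "voice", "hearing", "vision", "glasses", "dental", "skin", "wound",
  "bruise", "infection", "fever", "cough", "breath", "heart", "lung",
  "kidney", "liver", "stomach", "bowel", "bladder", "diet", "fluid",
  "water", "juice", "coffee", "tea", "snack", "portion", "tray", "spoon",
  "fork", "plate", "cup", "glass", "shirt", "button", "shoe", "sock",
  "jacket", "blanket", "pillow", "light", "window", "door", "hallway",
  "corridor", "elevator", "television", "radio", "newspaper", "book",
  "letter", "phone", "call", "message", "neighbor", "friend", "church",
  "market", "store", "bank", "bus", "car", "driver", "street", "park",
  "bench", "birthday", "holiday", "photo", "album", "music", "song",
  "puzzle", "game", "card", "craft", "paint", "brush"
)

.VERB_STEMS <- c(
  "reported", "denied", "described", "recalled", "remembered", "forgot",
  "repeated", "asked", "answered", "mentioned", "stated", "noted",
  "observed", "completed", "finished", "started", "attempted", "managed",
  "required", "requested", "refused", "accepted", "enjoyed", "tolerated",
  "walked", "moved", "rested", "slept", "ate", "drank", "dressed",
  "washed", "bathed", "cooked", "cleaned", "shopped", "visited", "called",
  "talked", "listened", "watched", "read", "wrote", "played", "smiled",
  "laughed", "cried", "paused", "hesitated", "wandered", "searched",
  "misplaced", "followed", "ignored", "recognized", "greeted", "thanked",
  "improved", "declined", "remained", "appeared", "seemed", "looked"
)

content_word_pool <- function(variant = c("base", "shifted")) {
  variant <- match.arg(variant)
  nouns <- c(.CONTENT_STEMS, paste0(.CONTENT_STEMS, "s"))
  pool <- unique(c(nouns, .VERB_STEMS))
  if (variant == "shifted") {
    # A disjoint surface vocabulary for distribution-shift experiments:
    # same semantics slots, different word forms.
    pool <- paste0(pool, "x")
  }
  setdiff(pool, c(FUNCTION_WORDS, PRONOUNS, SUBORDINATORS))
}

is_function_token <- function(tokens) {
  tokens %in% c(FUNCTION_WORDS, PRONOUNS, SUBORDINATORS)
}

#' Load the bundled toy concept lexicon
#'
#' Returns the small dictionary of clinical concept phrases bundled with the
#' package (cognition, independence and care-dependence domains, plus a few
#' explicitly diagnostic phrases used only to exercise masking). Real UMLS
#' dictionaries can be supplied in the same three/four column TSV format:
#' `phrase<TAB>concept_id<TAB>is_diagnostic[<TAB>domain]`.
#'
#' @param path Optional path to a lexicon TSV; default is the bundled file.
#' @return A data.frame with columns `phrase`, `concept_id`, `is_diagnostic`,
#'   `domain`.
#' @export
read_concept_lexicon <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "concept_lexicon.tsv", package = "cognitrace")
  }
  if (!file.exists(path)) stopf("concept lexicon not found: %s", path)
  lex <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("phrase", "concept_id", "is_diagnostic")
  if (!all(need %in% names(lex))) {
    stopf("lexicon must have columns: %s", paste(need, collapse = ", "))
  }
  if (nrow(lex) == 0) stopf("concept lexicon is empty")
  lex$phrase <- tolower(lex$phrase)
  if (is.null(lex$domain)) lex$domain <- "other"
  lex
}

default_mask_terms <- function() {
  path <- system.file("extdata", "mask_terms.txt", package = "cognitrace")
  terms <- readLines(path, warn = FALSE)
  terms[nzchar(terms)]
}

default_abbreviations <- function() {
  path <- system.file("extdata", "abbreviations.tsv", package = "cognitrace")
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stats::setNames(tab$expansion, tab$short)
}

default_synonyms <- function() {
  path <- system.file("extdata", "synonyms.tsv", package = "cognitrace")
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stats::setNames(tab$synonym, tab$term)
}
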
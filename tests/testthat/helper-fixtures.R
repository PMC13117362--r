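# Shared fixtures, built in code and cached for the session.

.fx <- new.env(parent = emptyenv())

fixture_corpus_small <- function() {
  if (is.null(.fx$corpus_small)) {
    .fx$corpus_small <- generate_corpus(10, seed = 41L)
  }
  .fx$corpus_small
}

fixture_splits_small <- function() {
  if (is.null(.fx$splits_small)) {
    .fx$splits_small <- split_patients(fixture_corpus_small(), seed = 42L)
  }
  .fx$splits_small
}

fixture_features_small <- function() {
  if (is.null(.fx$features_small)) {
    cfg <- cognitrace_config()
    params <- build_model_params(cfg, seed = 43L)
    .fx$features_small <- compute_patient_features(fixture_corpus_small(),
                                                   params, cfg)
  }
  .fx$features_small
}

fixture_model_small <- function() {
  if (is.null(.fx$model_small)) {
    .fx$model_small <- suppressMessages(train_cognitrace(
      fixture_corpus_small(), fixture_splits_small(),
      cognitrace_config(), seed = 43L, features = fixture_features_small()))
  }
  .fx$model_small
}

# A hand-written two-patient corpus on disk (JSONL + TSV).
write_tiny_corpus <- function(dir) {
  notes <- c(
    '{"note_id":"n1","patient_id":"p1","timestamp":"2015-01-10","sections":{"history":"patient was alert.","assessment":"memory loss noted."},"text":"patient was alert. memory loss noted."}',
    '{"note_id":"n3","patient_id":"p1","timestamp":"2015-09-01","sections":{"assessment":"patient walked unaided."},"text":"patient walked unaided."}',
    '{"note_id":"n2","patient_id":"p1","timestamp":"2015-03-15","sections":{"assessment":"appetite was good."},"text":"appetite was good."}',
    '{"note_id":"m1","patient_id":"p2","timestamp":"2016-02-02","sections":{"assessment":"confusion observed at night."},"text":"confusion observed at night."}',
    '{"note_id":"m2","patient_id":"p2","timestamp":"2016-06-20","sections":{"assessment":"needs supervision for meals."},"text":"needs supervision for meals."}',
    '{"note_id":"m3","patient_id":"p2","timestamp":"2017-01-05","sections":{"assessment":"wandering episodes reported."},"text":"wandering episodes reported."}'
  )
  np <- file.path(dir, "notes.jsonl")
  lp <- file.path(dir, "labels.tsv")
  writeLines(notes, np)
  writeLines(c("patient_id\tlabel", "p1\tNormal", "p2\tAD"), lp)
  list(notes = np, labels = lp)
}

# Build a note object from raw text without file IO.
mknote <- function(text, id = "n1", pid = "p1", ts = "2015-01-01") {
  note(id, pid, ts, sections = list(assessment = text), text = text)
}

# Large fixtures for the acceptance suite (generated once per run).
fixture_corpus300 <- function() {
  if (is.null(.fx$corpus300)) {
    .fx$corpus300 <- generate_corpus(100, seed = 131L)
  }
  .fx$corpus300
}

fixture_features300 <- function(variant = "full") {
  key <- paste0("features300_", variant)
  if (is.null(.fx[[key]])) {
    cfg <- cognitrace_config(variant = variant)
    params <- build_model_params(cfg, seed = 137L)
    .fx[[key]] <- compute_patient_features(fixture_corpus300(), params, cfg)
  }
  .fx[[key]]
}
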
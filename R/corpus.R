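# Corpus data model and leakage-safe patient-level splitting.
#
# A corpus is a list of patient records; the patient is the atomic unit for
# splitting, resampling and evaluation. Notes carry a calendar timestamp
# (day granularity for all gap arithmetic) and a section map with names
# drawn from a declared vocabulary plus "other".

SECTION_NAMES <- c("history", "medications", "assessment")

#' Construct a single clinical note
#'
#' @param note_id,patient_id Opaque identifier strings.
#' @param timestamp ISO-8601 date or date-time string, or a `Date`.
#' @param sections Named list of section texts (names from
#'   `history`/`medications`/`assessment`, others folded into `other`).
#' @param text Full text; defaults to the concatenated sections.
#' @param tokens Optional pre-computed token vector (filled by
#'   [normalize_note()] otherwise).
#' @return A `note` object.
#' @export
note <- function(note_id, patient_id, timestamp, sections = list(), text = NULL,
                 tokens = character(0)) {
  ts <- parse_day(timestamp)
  if (is.na(ts)) stopf("note %s: unparseable timestamp '%s'", note_id, timestamp)
  if (length(sections)) {
    bad <- !(names(sections) %in% SECTION_NAMES)
    if (any(bad)) {
      other <- paste(unlist(sections[bad]), collapse = " ")
      sections <- sections[!bad]
      sections$other <- other
    }
  }
  if (is.null(text)) text <- paste(unlist(sections), collapse = " ")
  if (!nzchar(trimws(text))) stopf("note %s: empty text", note_id)
  structure(list(note_id = as.character(note_id),
                 patient_id = as.character(patient_id),
                 timestamp = ts, sections = sections,
                 text = text, tokens = tokens),
            class = "note")
}

parse_day <- function(x) {
  if (inherits(x, "Date")) return(x)
  d <- suppressWarnings(as.Date(substr(as.character(x), 1, 10), format = "%Y-%m-%d"))
  d
}

#' Construct a patient record
#'
#' Notes are sorted by ascending timestamp with ties broken by lexicographic
#' note id, so ordering is deterministic.
#'
#' @param patient_id Identifier string.
#' @param notes List of [note()] objects for this patient.
#' @param label One of `"Normal"`, `"MCI"`, `"AD"`.
#' @param diagnosis_date Optional reference date for temporal truncation;
#'   defaults to the final note date when absent.
#' @param provenance `"observed"` or `"oversampled"`.
#' @return A `patient_record` object with a `span_days` field.
#' @export
patient_record <- function(patient_id, notes, label,
                           diagnosis_date = NULL, provenance = "observed") {
  if (!label %in% CLASSES) stopf("unknown label '%s' for patient %s", label, patient_id)
  if (length(notes) < 1) stopf("patient %s has no notes", patient_id)
  ord <- order(vapply(notes, function(n) as.numeric(n$timestamp), numeric(1)),
               vapply(notes, function(n) n$note_id, character(1)))
  notes <- notes[ord]
  ts <- vapply(notes, function(n) as.numeric(n$timestamp), numeric(1))
  structure(list(patient_id = as.character(patient_id), notes = notes,
                 label = label,
                 diagnosis_date = if (is.null(diagnosis_date)) NULL else parse_day(diagnosis_date),
                 provenance = provenance,
                 span_days = as.integer(max(ts) - min(ts))),
            class = "patient_record")
}

#' Read a longitudinal note corpus
#'
#' Reads notes from a JSON-lines file (one object per line with fields
#' `note_id`, `patient_id`, `timestamp`, `sections`, `text`) and patient
#' labels from a TSV with header `patient_id<TAB>label` (an optional
#' `diagnosis_date` column overrides the truncation reference; other extra
#' columns are preserved but ignored).
#'
#' @param notes_path Path to the notes JSONL file.
#' @param labels_path Path to the labels TSV file.
#' @return A list of [patient_record()] objects sorted by patient id, with
#'   attributes `n_dropped` (malformed lines) and `line_errors` (messages
#'   with line numbers).
#' @export
read_corpus <- function(notes_path, labels_path) {
  if (!file.exists(notes_path)) stopf("notes file not found: %s", notes_path)
  if (!file.exists(labels_path)) stopf("labels file not found: %s", labels_path)
  labels <- utils::read.delim(labels_path, stringsAsFactors = FALSE)
  if (!all(c("patient_id", "label") %in% names(labels))) {
    stopf("labels TSV must have columns patient_id and label")
  }
  labels$patient_id <- as.character(labels$patient_id)
  bad_lab <- setdiff(unique(labels$label), CLASSES)
  if (length(bad_lab)) stopf("unknown label string(s): %s", paste(bad_lab, collapse = ", "))

  lines <- readLines(notes_path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  notes <- vector("list", length(lines))
  errors <- character(0)
  for (i in seq_along(lines)) {
    obj <- tryCatch(jsonlite::fromJSON(lines[[i]]), error = function(e) NULL)
    if (is.null(obj) || is.null(obj$note_id) || is.null(obj$patient_id) ||
        is.null(obj$timestamp) || is.null(obj$text)) {
      errors <- c(errors, sprintf("line %d: malformed note record", i))
      next
    }
    nt <- tryCatch(
      note(obj$note_id, obj$patient_id, obj$timestamp,
           sections = as.list(obj$sections %||% list()), text = obj$text),
      error = function(e) {
        errors <<- c(errors, sprintf("line %d: %s", i, conditionMessage(e)))
        NULL
      })
    notes[[i]] <- nt
  }
  notes <- Filter(Negate(is.null), notes)

  pid <- vapply(notes, function(n) n$patient_id, character(1))
  missing <- setdiff(unique(pid), labels$patient_id)
  if (length(missing)) {
    stopf("note(s) for patient(s) absent from labels table: %s",
          paste(missing, collapse = ", "))
  }
  has_dx <- "diagnosis_date" %in% names(labels)
  recs <- lapply(sort(unique(pid)), function(p) {
    row <- labels[match(p, labels$patient_id), ]
    patient_record(p, notes[pid == p], row$label,
                   diagnosis_date = if (has_dx) row$diagnosis_date else NULL)
  })
  attr(recs, "n_dropped") <- length(errors)
  attr(recs, "line_errors") <- errors
  recs
}

#' Write a corpus back to JSONL + TSV
#'
#' Inverse of [read_corpus()]; round-trips are content-identical for valid
#' inputs.
#'
#' @param records List of patient records.
#' @param notes_path,labels_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_corpus <- function(records, notes_path, labels_path) {
  con <- file(notes_path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (rec in records) {
    for (nt in rec$notes) {
      writeLines(jsonlite::toJSON(list(
        note_id = nt$note_id, patient_id = nt$patient_id,
        timestamp = format(nt$timestamp, "%Y-%m-%d"),
        sections = nt$sections, text = nt$text
      ), auto_unbox = TRUE), con)
    }
  }
  lab <- data.frame(
    patient_id = vapply(records, function(r) r$patient_id, character(1)),
    label = vapply(records, function(r) r$label, character(1))
  )
  utils::write.table(lab, labels_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(notes_path, labels_path))
}

#' Stratified patient-level train/validation/test split
#'
#' Assigns every patient to exactly one of train/val/test, stratified by
#' class so per-split class fractions are within one patient of the targets.
#' Deterministic given `seed`; no patient ever straddles splits.
#'
#' @param records List of patient records.
#' @param fractions Numeric length-3 vector summing to 1 (train, val, test).
#' @param seed Integer seed.
#' @return A `split_assignment` data.frame (`patient_id`, `split`) with a
#'   `report` attribute of per-class counts per split.
#' @export
split_patients <- function(records, fractions = c(0.70, 0.15, 0.15), seed = 1L) {
  stopifnot(length(fractions) == 3, abs(sum(fractions) - 1) < 1e-8)
  labs <- vapply(records, function(r) r$label, character(1))
  ids <- vapply(records, function(r) r$patient_id, character(1))
  for (cl in intersect(CLASSES, unique(labs))) {
    if (sum(labs == cl) < 3) stopf("class %s has fewer patients than splits", cl)
  }
  split_names <- c("train", "val", "test")
  out <- withr::with_seed(seed, {
    pieces <- lapply(split(ids, labs), function(p) {
      p <- sample(p)
      counts <- apportion(fractions * length(p))
      # apportion guarantees sum == length(p) since fractions sum to 1
      data.frame(patient_id = p,
                 split = rep(split_names, counts),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, pieces)
  })
  rownames(out) <- NULL
  out <- out[match(ids, out$patient_id), ]
  rownames(out) <- NULL
  report <- table(label = labs[match(out$patient_id, ids)], split = out$split)
  structure(out, report = report, class = c("split_assignment", "data.frame"))
}

#' Restrict a record to notes well before the reference diagnosis date
#'
#' Keeps only notes recorded at least `min_gap_days` before the reference
#' date (the patient's `diagnosis_date` if present, otherwise the final note
#' date). Used for temporal-truncation stress tests that remove label
#' proximity effects.
#'
#' @param record A patient record.
#' @param min_gap_days Non-negative integer gap in days.
#' @return The truncated record; may have zero notes, in which case the
#'   `empty` attribute is `TRUE` and downstream consumers must drop it.
#' @export
truncate_before_label <- function(record, min_gap_days) {
  stopifnot(min_gap_days >= 0)
  ref <- record$diagnosis_date %||%
    record$notes[[length(record$notes)]]$timestamp
  keep <- vapply(record$notes, function(n) {
    as.numeric(ref - n$timestamp) >= min_gap_days
  }, logical(1))
  out <- record
  out$notes <- record$notes[keep]
  if (length(out$notes)) {
    ts <- vapply(out$notes, function(n) as.numeric(n$timestamp), numeric(1))
    out$span_days <- as.integer(max(ts) - min(ts))
    attr(out, "empty") <- FALSE
  } else {
    out$span_days <- 0L
    attr(out, "empty") <- TRUE
  }
  out
}

#' @export
print.patient_record <- function(x, ...) {
  cat(sprintf("<patient %s: %d notes over %d days, label %s%s>\n",
              x$patient_id, length(x$notes), x$span_days, x$label,
              if (identical(x$provenance, "oversampled")) ", oversampled" else ""))
  invisible(x)
}

corpus_labels <- function(records) {
  stats::setNames(vapply(records, function(r) r$label, character(1)),
                  vapply(records, function(r) r$patient_id, character(1)))
}
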
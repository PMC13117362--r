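# Seeded synthetic longitudinal note corpus generator.
#
# The generator is the test substrate standing in for restricted clinical
# corpora. Each class has a psycholinguistic profile (means and SDs); notes
# are realized as template clause sequences over a closed lexicon so the
# heuristic segmenter parses them unambiguously. Four features are
# calibration-exact by construction (TTR, MLU, subordination index,
# referential clarity): the realized token stream hits the per-note target
# up to rounding, and rounding residues are apportioned across the corpus so
# class means track the configured means to well within sampling tolerance.
# The remaining features (MATTR, content/function ratio, parse depth,
# entity overlap, lexical cohesion) are emergent properties of the same
# token stream; the content/function split is steered toward its target.

#' Default class-conditional generator profiles
#'
#' Per-class target means and standard deviations for the nine
#' psycholinguistic biomarkers, concept-domain mixture weights
#' (cognition / independence / care-dependence vocabulary), the
#' notes-per-patient distribution (mean 15.1, SD 7.4) and the
#' longitudinal span range (1-6 years). `drift` is `"stable"` for Normal
#' and `"linear"` (progressive within-patient decline) for MCI and AD.
#'
#' @return Named list of class profiles (`Normal`, `MCI`, `AD`).
#' @export
default_class_profiles <- function() {
  feat <- function(means, sds) list(mean = stats::setNames(means, PSYCH_FEATURES),
                                    sd = stats::setNames(sds, PSYCH_FEATURES))
  list(
    Normal = c(feat(
      c(ttr = 0.71, mattr = 0.69, content_function_ratio = 0.48, mlu = 14.2,
        parse_depth = 6.5, subordination_index = 0.31, entity_overlap = 0.55,
        lexical_cohesion = 0.73, referential_clarity = 0.92),
      c(0.08, 0.07, 0.05, 3.5, 1.2, 0.07, 0.10, 0.08, 0.05)),
      list(mixture = c(cognition = 0.15, independence = 0.70, care = 0.15),
           drift = "stable")),
    MCI = c(feat(
      c(ttr = 0.64, mattr = 0.62, content_function_ratio = 0.43, mlu = 12.1,
        parse_depth = 5.8, subordination_index = 0.27, entity_overlap = 0.45,
        lexical_cohesion = 0.67, referential_clarity = 0.88),
      c(0.10, 0.09, 0.06, 3.2, 1.1, 0.06, 0.10, 0.09, 0.06)),
      list(mixture = c(cognition = 0.35, independence = 0.40, care = 0.25),
           drift = "linear")),
    AD = c(feat(
      c(ttr = 0.56, mattr = 0.54, content_function_ratio = 0.37, mlu = 9.8,
        parse_depth = 4.9, subordination_index = 0.21, entity_overlap = 0.35,
        lexical_cohesion = 0.58, referential_clarity = 0.81),
      c(0.12, 0.11, 0.07, 2.9, 1.0, 0.05, 0.10, 0.10, 0.08)),
      list(mixture = c(cognition = 0.35, independence = 0.15, care = 0.50),
           drift = "linear"))
  ) |> lapply(function(p) {
    p$notes_per_patient <- c(mean = 15.1, sd = 7.4)
    p$span_years <- c(1, 6)
    p$noise_frac <- 0.6   # visit-noise SD as a fraction of the profile SD
    p
  })
}

validate_profiles <- function(profiles) {
  for (cl in names(profiles)) {
    p <- profiles[[cl]]
    if (any(p$sd <= 0)) stopf("profile %s: SDs must be positive", cl)
    ratios <- c("ttr", "mattr", "content_function_ratio",
                "subordination_index", "entity_overlap", "referential_clarity")
    if (any(p$mean[ratios] <= 0 | p$mean[ratios] > 1)) {
      stopf("profile %s: ratio feature mean outside (0, 1]", cl)
    }
    if (p$mean["mlu"] <= 0) stopf("profile %s: MLU mean must be positive", cl)
    if (abs(sum(p$mixture) - 1) > 1e-8 || any(p$mixture < 0)) {
      stopf("profile %s: concept mixture must be a simplex", cl)
    }
  }
  invisible(TRUE)
}

# Feasible ranges used to clamp per-note targets after drift + noise.
.TARGET_RANGE <- list(
  ttr = c(0.20, 0.95), mlu = c(4, 30), subordination_index = c(0, 0.8),
  referential_clarity = c(0, 1), content_function_ratio = c(0.10, 0.90)
)

.PRONOUNS_PER_NOTE <- 5L

# Per-note drift targets for one patient: linear interpolation from a
# healthier-than-class start toward a symmetric end point, so the mean over
# visits equals the class mean; "stable" keeps the class mean throughout.
drift_targets <- function(profile, normal_mean, T) {
  f <- names(profile$mean)
  if (identical(profile$drift, "stable") || T == 1L) {
    lam <- rep(0.5, T)
  } else {
    lam <- (seq_len(T) - 1) / (T - 1)
  }
  half <- 0.5 * (normal_mean - profile$mean)  # healthier direction offset
  start <- profile$mean + if (identical(profile$drift, "stable")) 0 else half
  end <- profile$mean - if (identical(profile$drift, "stable")) 0 else half
  t(vapply(lam, function(l) start + l * (end - start), numeric(length(f))))
}

# ---------------------------------------------------------------------------
# Note realization

# sample() misbehaves on length-1 numeric vectors; these are safe variants
sample1 <- function(x) x[sample.int(length(x), 1L)]
resample <- function(x, size) x[sample.int(length(x), size)]

draw_zipf <- function(used) {
  # repeat draw weighted by 1/rank of first use
  n <- length(used)
  if (n == 1L) return(used[1L])
  used[sample.int(n, 1L, prob = 1 / seq_len(n))]
}

realize_note <- function(tt, A, P, mixture, concept_split, pools) {
  C <- max(sample(6:10, 1L), A + 3L)
  T_tok <- max(round(C * tt$mlu), 2L * C + 4L)
  CC <- C - A
  S <- clamp(round(tt$subordination_index * C), 0L, floor(CC / 2))

  # clause lengths summing exactly to T_tok
  lens <- rep(T_tok %/% C, C)
  extra <- T_tok - sum(lens)
  if (extra > 0) lens[seq_len(extra)] <- lens[seq_len(extra)] + 1L

  # sentence layout: A ambiguous single-clause sentences, then CC - 2S
  # single-clause content sentences, then S two-clause sentences whose
  # second clause is subordinate
  sent_of_clause <- integer(C)
  subflag <- logical(C)
  si <- 0L; j <- 0L
  for (i in seq_len(A)) { si <- si + 1L; j <- j + 1L; sent_of_clause[j] <- si }
  n_single <- CC - 2L * S
  for (i in seq_len(n_single)) { si <- si + 1L; j <- j + 1L; sent_of_clause[j] <- si }
  for (i in seq_len(S)) {
    si <- si + 1L
    j <- j + 1L; sent_of_clause[j] <- si
    j <- j + 1L; sent_of_clause[j] <- si; subflag[j] <- TRUE
  }
  n_sent <- si
  is_amb <- seq_len(C) <= A

  toks <- lapply(lens, function(L) rep(NA_character_, L))
  used <- character(0)          # first-use order, all categories
  used_content <- character(0)
  used_function <- character(0)
  note_down <- function(w, content) {
    if (!(w %in% used)) used <<- c(used, w)
    if (content) {
      if (!(w %in% used_content)) used_content <<- c(used_content, w)
    } else if (w %in% FUNCTION_WORDS && !(w %in% used_function)) {
      # pronouns and subordinators never enter the repeat pool: their counts
      # and positions are structural (referential clarity, subordination)
      used_function <<- c(used_function, w)
    }
  }
  place <- function(j, pos, w, content) { toks[[j]][pos] <<- w; note_down(w, content) }
  next_free <- function(j) which(is.na(toks[[j]]))

  # ambiguous sentences: pronoun first, function-only fillers later
  for (j in which(is_amb)) place(j, 1L, sample1(PRONOUNS), FALSE)
  # subordinators open their clause
  for (j in which(subflag)) place(j, 1L, sample1(SUBORDINATORS), FALSE)
  # one content anchor (candidate antecedent) per content clause
  for (j in which(!is_amb)) {
    pos <- next_free(j)[1L]
    unused <- setdiff(pools$nouns, used)
    w <- if (length(unused)) sample1(unused) else draw_zipf(used_content)
    place(j, pos, w, TRUE)
  }
  # unambiguous pronouns: only in content sentences from the second one on,
  # so an antecedent is always present within the search window
  U <- P - A
  first_content_sent <- A + 1L
  elig <- which(!is_amb & sent_of_clause >= first_content_sent + 1L)
  if (U > 0) {
    if (length(elig) == 0) elig <- which(!is_amb)[-1L]
    hosts <- resample(rep(elig, length.out = max(U, length(elig))), U)
    for (h in hosts) {
      pos <- next_free(h)
      if (length(pos) == 0) { h <- elig[which.max(lens[elig])]; pos <- next_free(h) }
      place(h, pos[1L], sample1(PRONOUNS), FALSE)
    }
  }
  # concept phrases from the class mixture, into clauses with capacity
  n_con <- sample(2:4, 1L)
  concepts_used <- character(0)
  for (i in seq_len(n_con)) {
    dom <- names(mixture)[sample.int(length(mixture), 1L, prob = mixture)]
    cand <- concept_split[[dom]]
    if (is.null(cand) || nrow(cand) == 0) next
    row <- cand[sample.int(nrow(cand), 1L), ]
    ph <- tokenize_text(row$phrase)
    host <- which(!is_amb & vapply(seq_len(C), function(j)
      sum(is.na(toks[[j]])), integer(1)) >= length(ph))
    if (length(host) == 0) next
    j <- sample1(host)
    pos <- next_free(j)[seq_along(ph)]
    for (k in seq_along(ph)) place(j, pos[k], ph[k], !is_function_token(ph[k]))
    concepts_used <- c(concepts_used, row$concept_id)
  }

  # fill remaining slots to hit the distinct-type and content-ratio targets
  all_tok <- unlist(toks)
  n_forced <- sum(!is.na(all_tok))
  D_target <- clamp(round(tt$ttr * T_tok), length(used), T_tok)
  new_needed <- D_target - length(used)
  content_target <- round(tt$content_function_ratio * T_tok)
  content_now <- sum(!is_function_token(all_tok[!is.na(all_tok)]))

  free <- do.call(rbind, lapply(seq_len(C), function(j) {
    pos <- next_free(j)
    if (length(pos) == 0) return(NULL)
    data.frame(j = j, pos = pos, amb = is_amb[j])
  }))
  if (!is.null(free) && nrow(free) > 0) {
    free <- free[sample.int(nrow(free)), ]
    n_free <- nrow(free)
    content_slots <- clamp(content_target - content_now, 0L, sum(!free$amb))
    # mark which free slots carry content words (never in ambiguous clauses)
    free$content <- FALSE
    idx <- which(!free$amb)
    if (content_slots > 0) free$content[idx[seq_len(content_slots)]] <- TRUE
    # mark which free slots introduce new types
    new_flags <- rep(FALSE, n_free)
    if (new_needed > 0) new_flags[seq_len(min(new_needed, n_free))] <- TRUE
    for (r in seq_len(n_free)) {
      want_content <- free$content[r]
      w <- NA_character_
      if (new_flags[r]) {
        pool <- if (want_content) setdiff(pools$content, used)
                else setdiff(pools$functions, used)
        if (length(pool) == 0 && want_content) pool <- setdiff(pools$functions, used)
        if (length(pool)) w <- sample1(pool)
      }
      if (is.na(w)) {  # repeat an already-used word of the right category
        src <- if (want_content) used_content else used_function
        if (length(src) == 0) src <- if (want_content) pools$content else pools$functions
        w <- draw_zipf(src)
      }
      place(free$j[r], free$pos[r], w, want_content)
    }
  }

  # assemble text: clauses joined with ", " inside a sentence, ". " between
  sent_text <- vapply(seq_len(n_sent), function(s) {
    paste(vapply(which(sent_of_clause == s),
                 function(j) paste(toks[[j]], collapse = " "), character(1)),
          collapse = ", ")
  }, character(1))
  list(sentences = sent_text, concepts = concepts_used,
       n_tokens = T_tok, n_clauses = C)
}

sections_from_sentences <- function(sent_text) {
  n <- length(sent_text)
  if (n < 3) {
    return(list(assessment = paste0(paste(sent_text, collapse = ". "), ".")))
  }
  h <- max(1L, round(0.3 * n))
  list(
    history = paste0(paste(sent_text[seq_len(h)], collapse = ". "), "."),
    medications = paste0(sent_text[h + 1L], "."),
    assessment = paste0(paste(sent_text[seq(h + 2L, n)], collapse = ". "), ".")
  )
}

# ---------------------------------------------------------------------------
# Class-level generation

generate_class_records <- function(class, profile, normal_mean, seed,
                                   n_patients = NULL, n_notes = NULL,
                                   pool_variant = "base", lexicon = NULL,
                                   id_prefix = NULL) {
  stopifnot(!is.null(n_patients) || !is.null(n_notes))
  lexicon <- lexicon %||% read_concept_lexicon()
  lexicon <- lexicon[lexicon$is_diagnostic == 0, ]
  if (pool_variant == "shifted") {
    # disjoint surface vocabulary and concept inventory for the shifted
    # cohort: same structure, different word forms and concept ids
    lexicon$phrase <- gsub("([a-z']+)", "\\1x", lexicon$phrase)
    lexicon$concept_id <- paste0(lexicon$concept_id, "B")
  }
  concept_split <- split(lexicon, lexicon$domain)
  content <- content_word_pool(pool_variant)
  pools <- list(
    nouns = content[!content %in% .VERB_STEMS],
    content = content,
    functions = FUNCTION_WORDS   # excludes pronouns and subordinators
  )
  id_prefix <- id_prefix %||% paste0("P_", class, "_")

  withr::with_seed(seed, {
    # patient structures
    npp <- profile$notes_per_patient
    if (!is.null(n_patients)) {
      Ts <- clamp(round(rnorm(n_patients, npp["mean"], npp["sd"])), 3L, 40L)
    } else {
      Ts <- integer(0)
      while (sum(Ts) < n_notes) {
        Ts <- c(Ts, clamp(round(rnorm(1L, npp["mean"], npp["sd"])), 3L, 40L))
      }
      overshoot <- sum(Ts) - n_notes
      Ts[length(Ts)] <- Ts[length(Ts)] - overshoot
      if (Ts[length(Ts)] < 1L) {
        Ts <- Ts[-length(Ts)]
        Ts[length(Ts)] <- Ts[length(Ts)] + n_notes - sum(Ts)
      }
      n_patients <- length(Ts)
    }
    N <- sum(Ts)

    # per-note drift targets, then corpus-stratified visit noise per feature
    targ <- do.call(rbind, lapply(Ts, function(T) drift_targets(profile, normal_mean, T)))
    colnames(targ) <- PSYCH_FEATURES
    for (f in PSYCH_FEATURES) {
      targ[, f] <- targ[, f] + stratified_normal(N, profile$noise_frac * profile$sd[[f]])
      rng <- .TARGET_RANGE[[f]]
      if (!is.null(rng)) targ[, f] <- clamp(targ[, f], rng[1], rng[2])
    }

    # ambiguous-pronoun counts: largest-remainder apportionment across the
    # class corpus so the mean referential clarity matches its target
    P <- .PRONOUNS_PER_NOTE
    A <- apportion(clamp((1 - targ[, "referential_clarity"]) * P, 0, P))
    A <- clamp(A, 0L, P)

    # per-visit concept mixture drift (vocabulary shifts toward care terms)
    mix0 <- profile$mixture

    recs <- vector("list", n_patients)
    note_i <- 0L
    base_day <- as.Date("2010-01-01")
    for (pi in seq_len(n_patients)) {
      T <- Ts[pi]
      pid <- sprintf("%s%04d", id_prefix, pi)
      span <- round(runif(1, profile$span_years[1], profile$span_years[2]) * 365)
      days <- if (T == 1L) 0L else
        c(0L, sort(sample(seq_len(span - 1L), T - 2L)), span)
      t0 <- base_day + sample.int(1461L, 1L)
      notes <- vector("list", T)
      for (t in seq_len(T)) {
        note_i <- note_i + 1L
        tt <- as.list(targ[note_i, ])
        lam <- if (T == 1L) 0.5 else (t - 1) / (T - 1)
        mix <- mix0
        if (!identical(profile$drift, "stable")) {
          shift <- 0.3 * lam * mix["independence"]
          mix["independence"] <- mix["independence"] - shift
          mix["care"] <- mix["care"] + shift
        }
        rn <- realize_note(tt, A[note_i], P, mix, concept_split, pools)
        secs <- sections_from_sentences(rn$sentences)
        notes[[t]] <- note(sprintf("%s_n%02d", pid, t), pid, t0 + days[t],
                           sections = secs)
      }
      recs[[pi]] <- patient_record(pid, notes, class)
    }
    recs
  })
}

#' Generate a synthetic longitudinal corpus
#'
#' Generates `n_per_class` patients per class with the class-conditional
#' psycholinguistic profiles (defaults from [default_class_profiles()]),
#' progressive within-patient drift for MCI/AD, concept-vocabulary drift,
#' and optional label noise. Byte-identical output under a fixed seed.
#'
#' @param n_per_class Integer (same count per class) or named vector over
#'   `Normal`/`MCI`/`AD`.
#' @param profiles Class profiles; see [default_class_profiles()].
#' @param seed Integer seed.
#' @param label_noise Fraction of patient labels to perturb (0 disables).
#' @param covariates If `TRUE`, attach a per-patient molecular covariate
#'   table (hippocampal volume etc.) as the `covariates` attribute; these
#'   values are emitted for completeness and consumed by nothing downstream.
#' @param pool_variant `"base"` or `"shifted"` surface vocabulary.
#' @param lexicon Optional concept lexicon data.frame.
#' @return List of patient records (attributes: `labels`, optionally
#'   `covariates`, `flipped`).
#' @export
generate_corpus <- function(n_per_class, profiles = default_class_profiles(),
                            seed = 1L, label_noise = 0, covariates = FALSE,
                            pool_variant = "base", lexicon = NULL) {
  validate_profiles(profiles)
  if (length(n_per_class) == 1L && is.null(names(n_per_class))) {
    n_per_class <- stats::setNames(rep(n_per_class, 3), CLASSES)
  }
  normal_mean <- profiles$Normal$mean
  recs <- list()
  for (cl in CLASSES) {
    n <- if (cl %in% names(n_per_class)) n_per_class[[cl]] else 0
    if (n == 0) next
    recs <- c(recs, generate_class_records(
      cl, profiles[[cl]], normal_mean, seed = derive_seed(seed, cl),
      n_patients = n, pool_variant = pool_variant, lexicon = lexicon))
  }
  labels <- corpus_labels(recs)
  if (label_noise > 0) {
    labels <- inject_label_noise(labels, label_noise, derive_seed(seed, "noise"))
    for (i in seq_along(recs)) recs[[i]]$label <- labels[[recs[[i]]$patient_id]]
    attr(recs, "flipped") <- attr(labels, "flipped")
  }
  attr(recs, "labels") <- labels
  if (covariates) attr(recs, "covariates") <- molecular_covariates(recs, seed)
  recs
}

#' Generate a fixed number of notes for one class
#'
#' Convenience entry point for note-level calibration studies: patients are
#' generated with the usual longitudinal structure until exactly `n_notes`
#' notes exist.
#'
#' @param class One of `"Normal"`, `"MCI"`, `"AD"`.
#' @param n_notes Number of notes to generate.
#' @param profiles Class profiles.
#' @param seed Integer seed.
#' @return List of patient records totalling `n_notes` notes.
#' @export
generate_class_notes <- function(class, n_notes,
                                 profiles = default_class_profiles(), seed = 1L) {
  validate_profiles(profiles)
  stopifnot(class %in% CLASSES)
  generate_class_records(class, profiles[[class]], profiles$Normal$mean,
                         seed = derive_seed(seed, class), n_notes = n_notes)
}

# Molecular covariate rows (never consumed by the model).
molecular_covariates <- function(records, seed) {
  tab <- list(
    Normal = c(hippocampal_volume = 3.8, amyloid_beta = 42.5, tau = 18.3,
               cortical_thickness = 2.6, fdg_pet = 1.35, fa = 0.52),
    MCI = c(hippocampal_volume = 3.1, amyloid_beta = 65.2, tau = 29.7,
            cortical_thickness = 2.2, fdg_pet = 1.10, fa = 0.46),
    AD = c(hippocampal_volume = 2.4, amyloid_beta = 88.7, tau = 41.5,
           cortical_thickness = 1.8, fdg_pet = 0.85, fa = 0.39))
  sds <- list(
    Normal = c(0.4, 5.1, 3.2, 0.3, 0.12, 0.05),
    MCI = c(0.5, 6.3, 4.1, 0.3, 0.15, 0.06),
    AD = c(0.6, 7.4, 5.0, 0.2, 0.14, 0.07))
  withr::with_seed(derive_seed(seed, "covariates"), {
    rows <- lapply(records, function(r) {
      m <- tab[[r$label]]; s <- sds[[r$label]]
      vals <- rnorm(length(m), m, s)
      c(list(patient_id = r$patient_id), as.list(stats::setNames(vals, names(m))))
    })
    do.call(rbind, lapply(rows, as.data.frame))
  })
}

#' Perturb a fraction of patient labels
#'
#' Reassigns exactly `round(rate * n)` randomly chosen patients to a
#' uniformly drawn *different* class — the label-noise sensitivity protocol.
#'
#' @param labels Named character vector (patient id -> label).
#' @param rate Fraction in \[0, 1\].
#' @param seed Integer seed.
#' @return Labels with a `flipped` attribute listing perturbed patient ids.
#' @export
inject_label_noise <- function(labels, rate, seed = 1L) {
  stopifnot(rate >= 0, rate <= 1)
  n_flip <- round(rate * length(labels))
  if (n_flip == 0) { attr(labels, "flipped") <- character(0); return(labels) }
  withr::with_seed(seed, {
    idx <- sample(seq_along(labels), n_flip)
    for (i in idx) {
      labels[i] <- sample(setdiff(CLASSES, labels[i]), 1L)
    }
  })
  attr(labels, "flipped") <- names(labels)[idx]
  labels
}

#' Generate a distribution-shifted cohort
#'
#' Produces a second corpus under a perturbed generating distribution for
#' zero-shot evaluation and embedding-alignment exercises. The shift spec
#' can move feature means, scale note length, and swap the surface
#' vocabulary pool (disjoint word forms, same structure).
#'
#' @param n_per_class As in [generate_corpus()].
#' @param shift List with optional elements `feature_deltas` (named numeric
#'   added to every class mean), `mlu_factor` (multiplies MLU means), and
#'   `vocab_swap` (logical).
#' @param profiles Base profiles.
#' @param seed Integer seed.
#' @return List of patient records.
#' @export
shifted_cohort <- function(n_per_class, shift = list(),
                           profiles = default_class_profiles(), seed = 2L) {
  deltas <- shift$feature_deltas %||% numeric(0)
  for (cl in names(profiles)) {
    for (f in names(deltas)) {
      profiles[[cl]]$mean[[f]] <- profiles[[cl]]$mean[[f]] + deltas[[f]]
    }
    if (!is.null(shift$mlu_factor)) {
      profiles[[cl]]$mean[["mlu"]] <- profiles[[cl]]$mean[["mlu"]] * shift$mlu_factor
    }
  }
  generate_corpus(n_per_class, profiles = profiles, seed = seed,
                  pool_variant = if (isTRUE(shift$vocab_swap)) "shifted" else "base")
}
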
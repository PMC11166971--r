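# Data model for annotated diagnosis dialogues.
#
# A corpus is a list of dyadic dialogues. Each dialogue carries a disease
# label and an ordered list of turns alternating patient/doctor, starting
# with the patient's self-report. Patient turns may carry an intent tag:
# "Symptom" (the utterance names at least one symptom) or "Affirmative"
# (the patient agrees with the doctor but names no symptom). Symptom names
# are normalized to lowercase canonical identifiers.

SPEAKERS <- c("patient", "doctor")
INTENTS <- c("Symptom", "Affirmative")

#' Construct an utterance
#'
#' @param speaker "patient" or "doctor".
#' @param text Utterance text.
#' @param intent Optional intent tag for patient turns: "Symptom" if the
#'   utterance names a symptom, "Affirmative" if the patient agrees with the
#'   doctor without naming one. Must be `NULL` on doctor turns.
#' @param symptoms Character vector of symptom names mentioned in the
#'   utterance (annotated slots); normalized to lowercase.
#' @return A list of class `kiddi_utterance`.
#' @export
utterance <- function(speaker, text, intent = NULL, symptoms = character()) {
  symptoms <- if (length(symptoms)) normalize_name(as.character(symptoms)) else character()
  out <- structure(
    list(speaker = speaker, text = as.character(text),
         intent = intent, symptoms = symptoms),
    class = "kiddi_utterance"
  )
  out
}

#' Construct a dialogue
#'
#' @param id Dialogue identifier string.
#' @param disease Gold disease label (normalized to lowercase).
#' @param turns List of [utterance()] objects, patient first, strictly
#'   alternating patient/doctor.
#' @return A list of class `kiddi_dialogue`.
#' @export
dialogue <- function(id, disease, turns) {
  structure(
    list(id = as.character(id), disease = normalize_name(disease), turns = turns),
    class = "kiddi_dialogue"
  )
}

#' Construct and validate a corpus
#'
#' Validates every dialogue (turn alternation, intent rules) and builds
#' lexicographic symptom/disease vocabularies so node and class indices are
#' stable across runs. Vocabularies may be supplied as supersets of what the
#' dialogues mention (e.g. the full symptom inventory of a generator).
#'
#' @param dialogues List of [dialogue()] objects.
#' @param symptom_vocab,disease_vocab Optional character vectors; must
#'   contain every name mentioned in the dialogues. Defaults to the sorted
#'   set of mentioned names.
#' @return A list of class `kiddi_corpus` with fields `dialogues`,
#'   `symptom_vocab`, `disease_vocab`.
#' @export
corpus <- function(dialogues, symptom_vocab = NULL, disease_vocab = NULL) {
  mentioned_sym <- character()
  mentioned_dis <- character()
  for (d in dialogues) {
    validate_dialogue(d)
    mentioned_dis <- c(mentioned_dis, d$disease)
    for (t in d$turns) mentioned_sym <- c(mentioned_sym, t$symptoms)
  }
  mentioned_sym <- sort_c(mentioned_sym)
  mentioned_dis <- sort_c(mentioned_dis)
  symptom_vocab <- if (is.null(symptom_vocab)) mentioned_sym else
    sort_c(normalize_name(symptom_vocab))
  disease_vocab <- if (is.null(disease_vocab)) mentioned_dis else
    sort_c(normalize_name(disease_vocab))
  missing_s <- setdiff(mentioned_sym, symptom_vocab)
  if (length(missing_s))
    stopf("symptom_vocab is missing mentioned symptom(s): %s",
          paste(missing_s, collapse = ", "))
  missing_d <- setdiff(mentioned_dis, disease_vocab)
  if (length(missing_d))
    stopf("disease_vocab is missing mentioned disease(s): %s",
          paste(missing_d, collapse = ", "))
  structure(
    list(dialogues = dialogues, symptom_vocab = symptom_vocab,
         disease_vocab = disease_vocab),
    class = "kiddi_corpus"
  )
}

validate_dialogue <- function(d) {
  if (!length(d$id)) stopf("dialogue without id")
  if (!length(d$turns)) stopf("dialogue '%s': no turns", d$id)
  for (i in seq_along(d$turns)) {
    t <- d$turns[[i]]
    if (!t$speaker %in% SPEAKERS)
      stopf("dialogue '%s', turn %d: invalid speaker '%s'", d$id, i, t$speaker)
    expected <- if (i %% 2 == 1L) "patient" else "doctor"
    if (t$speaker != expected)
      stopf("dialogue '%s', turn %d: expected %s turn (turns must alternate starting with the patient), got %s",
            d$id, i, expected, t$speaker)
    if (!is.null(t$intent)) {
      if (t$speaker == "doctor")
        stopf("dialogue '%s', turn %d: field 'intent' is not allowed on doctor turns", d$id, i)
      if (!t$intent %in% INTENTS)
        stopf("dialogue '%s', turn %d: invalid intent '%s'", d$id, i, t$intent)
      if (t$intent == "Symptom" && !length(t$symptoms))
        stopf("dialogue '%s', turn %d: intent 'Symptom' requires a non-empty symptom list", d$id, i)
      if (t$intent == "Affirmative" && length(t$symptoms))
        stopf("dialogue '%s', turn %d: intent 'Affirmative' requires an empty symptom list", d$id, i)
    }
  }
  invisible(d)
}

#' @export
print.kiddi_corpus <- function(x, ...) {
  s <- corpus_stats(x)
  cat(sprintf("<kiddi_corpus> %d dialogues, %d utterances, %d diseases, %d symptoms\n",
              s$n_dialogues, s$n_utterances, s$n_diseases, s$n_symptoms))
  invisible(x)
}

# ---- serialization ----------------------------------------------------------

dialogue_to_list <- function(d) {
  turns <- lapply(d$turns, function(t) {
    out <- list()
    if (!is.null(t$intent)) out$intent <- t$intent
    out$speaker <- t$speaker
    out$symptoms <- as.list(t$symptoms)
    out$text <- t$text
    out
  })
  list(disease = d$disease, id = d$id, turns = turns)
}

dialogue_from_list <- function(x, idx) {
  id <- x$id %||% stopf("dialogue #%d: missing field 'id'", idx)
  disease <- x$disease %||% stopf("dialogue '%s': missing field 'disease'", id)
  turns_raw <- x$turns %||% stopf("dialogue '%s': missing field 'turns'", id)
  turns <- lapply(turns_raw, function(t) {
    if (is.null(t$speaker)) stopf("dialogue '%s': turn missing field 'speaker'", id)
    if (is.null(t$text)) stopf("dialogue '%s': turn missing field 'text'", id)
    utterance(t$speaker, t$text, intent = t$intent,
              symptoms = unlist(t$symptoms) %||% character())
  })
  dialogue(id, disease, turns)
}

#' Read a dialogue corpus from a JSON file
#'
#' The file format is a JSON object with a `dialogues` array; each dialogue
#' has `id`, `disease` and `turns` (each turn: `speaker`, `text`, optional
#' `intent`, `symptoms`). Optional `symptom_vocab` / `disease_vocab` arrays
#' allow the vocabulary to be a superset of what the dialogues mention.
#' A schema document ships in `inst/extdata/corpus-schema.json`.
#'
#' @param path Path to a corpus JSON file.
#' @return A validated `kiddi_corpus`; errors name the offending dialogue
#'   and field.
#' @export
read_corpus <- function(path) {
  if (!file.exists(path)) stopf("corpus file not found: %s", path)
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(raw$dialogues)) stopf("corpus file '%s': missing field 'dialogues'", path)
  dialogues <- lapply(seq_along(raw$dialogues), function(i)
    dialogue_from_list(raw$dialogues[[i]], i))
  corpus(dialogues,
         symptom_vocab = unlist(raw$symptom_vocab) %||% NULL,
         disease_vocab = unlist(raw$disease_vocab) %||% NULL)
}

#' Write a corpus to a JSON file
#'
#' Keys are emitted in sorted order and the output is byte-stable for a
#' given corpus, so serialized corpora can be diffed and content-hashed.
#' `write_corpus()` followed by [read_corpus()] is the identity on the data
#' model.
#'
#' @param corpus A `kiddi_corpus`.
#' @param path Output path.
#' @export
write_corpus <- function(corpus, path) {
  stopifnot(inherits(corpus, "kiddi_corpus"))
  body <- list(
    dialogues = lapply(corpus$dialogues, dialogue_to_list),
    disease_vocab = as.list(corpus$disease_vocab),
    symptom_vocab = as.list(corpus$symptom_vocab)
  )
  # keys sorted at every level by construction; dialogues < disease_vocab is
  # not alphabetical, so reorder the top level explicitly
  body <- body[sort_c(names(body))]
  json <- jsonlite::toJSON(body, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(json, con, useBytes = TRUE)
  invisible(path)
}

# ---- splitting --------------------------------------------------------------

largest_remainder <- function(n, fractions) {
  raw <- fractions * n
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    ord <- order(raw - base, decreasing = TRUE)
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1L
  }
  as.integer(base)
}

#' Split a corpus into train / validation / test partitions
#'
#' Stratifies by disease where per-class counts permit and falls back to a
#' seeded random allocation for the remainder; the partition is always
#' disjoint, exhaustive, and deterministic given the seed. Split sizes
#' follow the fractions by largest-remainder rounding. All three partitions
#' keep the parent corpus vocabularies so class and node indices are shared.
#'
#' @param corpus A `kiddi_corpus`.
#' @param fractions Numeric triple summing to 1 (default `c(0.7, 0.1, 0.2)`).
#' @param seed Integer seed.
#' @return Named list of corpora: `train`, `validation`, `test`.
#' @export
split_corpus <- function(corpus, fractions = c(0.7, 0.1, 0.2), seed = 0L) {
  stopifnot(inherits(corpus, "kiddi_corpus"))
  if (length(fractions) != 3L) stopf("fractions must have length 3")
  if (any(fractions < 0)) stopf("fractions must be non-negative")
  if (abs(sum(fractions) - 1) > 1e-9) stopf("fractions must sum to 1")
  n <- length(corpus$dialogues)
  targets <- largest_remainder(n, fractions)
  labels <- vapply(corpus$dialogues, function(d) d$disease, character(1))

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  assign_split <- integer(n)
  for (dis in sort_c(labels)) {
    idx <- which(labels == dis)
    idx <- idx[sample.int(length(idx))]
    alloc <- largest_remainder(length(idx), fractions)
    assign_split[idx] <- rep.int(1:3, alloc)
  }
  # per-class rounding can drift from the global targets; rebalance by
  # moving single dialogues from over- to under-filled partitions
  repeat {
    counts <- tabulate(assign_split, nbins = 3L)
    over <- which(counts > targets)
    under <- which(counts < targets)
    if (!length(over)) break
    src <- over[[1L]]
    dst <- under[[1L]]
    pool <- which(assign_split == src)
    mv <- pool[sample.int(length(pool), 1L)]
    assign_split[mv] <- dst
  }

  make <- function(k) corpus(corpus$dialogues[assign_split == k],
                             symptom_vocab = corpus$symptom_vocab,
                             disease_vocab = corpus$disease_vocab)
  list(train = make(1L), validation = make(2L), test = make(3L))
}

#' Descriptive corpus statistics
#'
#' @param corpus A `kiddi_corpus`.
#' @return Named list: number of dialogues, number of utterances, average
#'   dialogue length in turns, number of diseases, number of symptoms.
#' @export
corpus_stats <- function(corpus) {
  stopifnot(inherits(corpus, "kiddi_corpus"))
  n_dlg <- length(corpus$dialogues)
  n_utt <- sum(vapply(corpus$dialogues, function(d) length(d$turns), integer(1)))
  list(
    n_dialogues = n_dlg,
    n_utterances = n_utt,
    avg_dialogue_length = if (n_dlg) n_utt / n_dlg else 0,
    n_diseases = length(corpus$disease_vocab),
    n_symptoms = length(corpus$symptom_vocab)
  )
}
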
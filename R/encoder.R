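# Pluggable utterance encoder.
#
# The model core is encoder-agnostic: serialization turns a dialogue into a
# token sequence with sentinel tokens marking the self-report span and the
# speaker of each utterance, and `encode()` maps a token sequence to a
# fixed-width vector. The reference encoder ("reference_small") is a small
# trainable bag-of-embeddings: learned token embeddings, mean-pooled, then
# affine-transformed to width d2. It is deliberately simple so its gradient
# is exact and training runs at desk scale; a pretrained transformer can be
# plugged in behind the same contract ("pretrained_adapter", first-position
# pooled output).

TOK_SR_START <- "[sr_start]"
TOK_SR_END <- "[sr_end]"
TOK_PAT <- "[pat]"
TOK_DOC <- "[doc]"
TOK_UNK <- "[unk]"
SPECIAL_TOKENS <- c(TOK_SR_START, TOK_SR_END, TOK_PAT, TOK_DOC, TOK_UNK)

#' Encoder configuration
#'
#' @param d2 Width of utterance encodings (self-report `S`, dialogue `C`).
#' @param d1 Width of node features (entity-name encodings are projected
#'   from d2 to d1).
#' @param max_sequence_length Maximum token-sequence length; longer
#'   sequences are truncated (self-reports keep both sentinels, dialogues
#'   are cut at the tail).
#' @param encoder_kind `"reference_small"` (the built-in trainable
#'   bag-of-embeddings encoder) or `"pretrained_adapter"` (caller supplies
#'   an `adapter_fn(tokens)` returning a width-d2 vector).
#' @param adapter_fn Encoding function for the adapter slot.
#' @return A list of class `kiddi_encoder_config`.
#' @export
encoder_config <- function(d2 = 768L, d1 = 384L, max_sequence_length = 512L,
                           encoder_kind = c("reference_small",
                                            "pretrained_adapter"),
                           adapter_fn = NULL) {
  if (!is_count(d2) || !is_count(d1)) stopf("d1 and d2 must be positive integers")
  if (!is_count(max_sequence_length, min = 8L))
    stopf("max_sequence_length must be at least 8")
  encoder_kind <- match.arg(encoder_kind)
  if (encoder_kind == "pretrained_adapter" && !is.function(adapter_fn))
    stopf("pretrained_adapter requires an adapter_fn")
  structure(list(d2 = as.integer(d2), d1 = as.integer(d1),
                 max_sequence_length = as.integer(max_sequence_length),
                 encoder_kind = encoder_kind, adapter_fn = adapter_fn),
            class = "kiddi_encoder_config")
}

#' Whitespace tokenizer with lowercase folding
#'
#' Lowercases, strips everything but alphanumerics, and splits on
#' whitespace. Swappable behind the serialization contract.
#'
#' @param text Character scalar.
#' @return Character vector of tokens (possibly empty).
#' @export
tokenize_text <- function(text) {
  x <- gsub("[^a-z0-9 ]", " ", tolower(text))
  toks <- strsplit(trimws(x), "[[:space:]]+")[[1]]
  toks[nzchar(toks)]
}

#' Serialize the self-report of a dialogue
#'
#' The self-report is the first patient utterance. The token sequence is
#' `[sr_start] <tokens> [sr_end]`, truncated to `max_sequence_length`
#' keeping both sentinels.
#'
#' @param dialogue A `kiddi_dialogue`.
#' @param config An [encoder_config()] (or any list with
#'   `max_sequence_length`).
#' @return Character vector of tokens.
#' @export
serialize_self_report <- function(dialogue, config = encoder_config()) {
  toks <- tokenize_text(dialogue$turns[[1]]$text)
  seq <- c(TOK_SR_START, toks, TOK_SR_END)
  m <- config$max_sequence_length
  if (length(seq) > m) seq <- c(seq[seq_len(m - 1L)], TOK_SR_END)
  seq
}

#' Serialize the full dialogue
#'
#' Turns in conversational order, each patient utterance prefixed by
#' `[pat]` and each doctor utterance by `[doc]`; the interleaved order is
#' kept because turn-level discourse is the signal of interest. Sequences
#' longer than `max_sequence_length` are truncated at the tail.
#'
#' @inheritParams serialize_self_report
#' @return Character vector of tokens.
#' @export
serialize_dialogue <- function(dialogue, config = encoder_config()) {
  seq <- unlist(lapply(dialogue$turns, function(t) {
    c(if (t$speaker == "patient") TOK_PAT else TOK_DOC, tokenize_text(t$text))
  }))
  utils::head(seq, config$max_sequence_length)
}

#' Build the token vocabulary of a corpus
#'
#' All tokens appearing in any utterance plus the tokens of every symptom
#' and disease name (so entity-name encodings never fall back to the
#' unknown token on the training vocabulary), plus the special tokens.
#' Lexicographic order, specials first, so token indices are stable.
#'
#' @param corpus A `kiddi_corpus`.
#' @return Character vector; the unknown token is always present.
#' @export
build_token_vocab <- function(corpus) {
  stopifnot(inherits(corpus, "kiddi_corpus"))
  toks <- character()
  for (d in corpus$dialogues)
    for (t in d$turns) toks <- c(toks, tokenize_text(t$text))
  for (nm in c(corpus$symptom_vocab, corpus$disease_vocab))
    toks <- c(toks, tokenize_text(nm))
  c(SPECIAL_TOKENS, sort_c(setdiff(toks, SPECIAL_TOKENS)))
}

tokens_to_ids <- function(tokens, token_vocab) {
  ids <- match(tokens, token_vocab)
  ids[is.na(ids)] <- match(TOK_UNK, token_vocab)
  ids
}

# mean-pooled embedding + affine map; cache the pooled vector for backprop
encode_ids <- function(ids, params) {
  d_emb <- ncol(params$E)
  m <- if (length(ids) == 0) rep(0, d_emb)
  else if (length(ids) == 1) params$E[ids, ]
  else colMeans(params$E[ids, , drop = FALSE])
  list(v = drop(params$W_enc %*% m) + params$b_enc, m = m)
}

#' Encode a token sequence
#'
#' Reference encoder: learned token embeddings are mean-pooled and passed
#' through an affine map to width d2. Unknown tokens map to the reserved
#' unknown id; the empty sequence yields the learned null vector (the
#' affine bias). Deterministic given parameters, and invariant under token
#' permutation (a property of mean pooling).
#'
#' @param tokens Character vector of tokens.
#' @param model A model object from [init_model()] (or a checkpoint's
#'   `model`), which carries the encoder parameters and token vocabulary.
#' @return Numeric vector of width d2.
#' @export
encode <- function(tokens, model) {
  cfg <- model$config
  if (!is.null(cfg$adapter_fn)) return(cfg$adapter_fn(tokens))
  encode_ids(tokens_to_ids(tokens, model$token_vocab), model$params)$v
}

#' Encode an entity name as a node feature
#'
#' The name is tokenized, encoded like any token sequence, and projected by
#' a learned d2-to-d1 map; identical names give identical vectors.
#'
#' @param name Symptom or disease name.
#' @inheritParams encode
#' @return Numeric vector of width d1.
#' @export
encode_entity_name <- function(name, model) {
  v <- encode(tokenize_text(name), model)
  drop(model$params$W_proj %*% v) + model$params$b_proj
}
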
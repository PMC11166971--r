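# Model core: graph attention over the joint graph, mean-pool graph
# embedding, additive attention fusing the graph embedding (query) with the
# self-report and dialogue encodings (values), and a softmax disease
# classifier. Forward passes cache every intermediate so the backward pass
# (gradients.R) is exact; `forward()` is pure given parameters, so
# evaluation is bitwise reproducible.

MODEL_MODES <- c("full", "sre_only", "de_only", "knowledge_only",
                 "sre_linear", "de_linear", "sre_knowledge", "de_knowledge")

#' Model configuration
#'
#' Defaults follow the reference operating point of the architecture: a
#' 768-wide utterance encoding (d2), 384-wide graph features (d1) split
#' over 3 concatenated attention heads, 2 GAT layers, a 64-wide additive
#' attention projection (d3), attention dropout 0.5, LeakyReLU slope 0.2.
#'
#' @param d2 Utterance encoding width.
#' @param d1 Node feature / graph embedding width; must be divisible by
#'   `n_heads`.
#' @param d3 Additive-attention projection width.
#' @param n_layers Number of GAT layers.
#' @param n_heads Attention heads per GAT layer (concatenated, each of
#'   width `d1 / n_heads`, so layer width is preserved).
#' @param leaky_slope Negative slope of LeakyReLU.
#' @param dropout Dropout rate applied to GAT attention coefficients during
#'   training only.
#' @param max_sequence_length Token-sequence cap for serialization.
#' @return A list of class `kiddi_model_config`.
#' @export
model_config <- function(d2 = 768L, d1 = 384L, d3 = 64L, n_layers = 2L,
                         n_heads = 3L, leaky_slope = 0.2, dropout = 0.5,
                         max_sequence_length = 512L) {
  if (!is_count(d1) || !is_count(d2) || !is_count(d3))
    stopf("d1, d2, d3 must be positive integers")
  if (!is_count(n_layers) || !is_count(n_heads))
    stopf("n_layers and n_heads must be positive integers")
  if (d1 %% n_heads != 0)
    stopf("d1 (%d) must be divisible by n_heads (%d)", d1, n_heads)
  if (!is.numeric(leaky_slope) || leaky_slope <= 0)
    stopf("leaky_slope must be positive")
  if (!is_prob(dropout)) stopf("dropout must be in [0, 1]")
  structure(list(d2 = as.integer(d2), d1 = as.integer(d1), d3 = as.integer(d3),
                 n_layers = as.integer(n_layers), n_heads = as.integer(n_heads),
                 leaky_slope = leaky_slope, dropout = dropout,
                 max_sequence_length = as.integer(max_sequence_length)),
            class = "kiddi_model_config")
}

leaky <- function(x, slope) ifelse(x > 0, x, slope * x)
dleaky <- function(x, slope) ifelse(x > 0, 1, slope)

glorot <- function(nr, nc) {
  matrix(stats::rnorm(nr * nc, sd = sqrt(2 / (nr + nc))), nr, nc)
}

#' Initialize a model
#'
#' Creates all trainable parameter tables: token embeddings, the encoder
#' affine map, the d2-to-d1 entity projection, per-layer per-head GAT
#' weights, additive-attention weights, and the classifier head. The
#' classifier input width depends on the wiring `mode` (see
#' [train_config()] for the available modes).
#'
#' @param config A [model_config()].
#' @param token_vocab Token vocabulary (see [build_token_vocab()]).
#' @param disease_vocab Disease label vocabulary (class space).
#' @param mode Wiring mode, one of `r paste(MODEL_MODES, collapse = ", ")`.
#' @param distill_config A [distillation_config()].
#' @param seed Integer seed for the parameter draw.
#' @return A list of class `kiddi_model`: `params`, `config`, `mode`,
#'   `token_vocab`, `disease_vocab`, `distill_config`.
#' @export
init_model <- function(config, token_vocab, disease_vocab, mode = "full",
                       distill_config = distillation_config(), seed = 0L) {
  stopifnot(inherits(config, "kiddi_model_config"))
  mode <- match.arg(mode, MODEL_MODES)
  set.seed(seed)
  d1 <- config$d1; d2 <- config$d2; d3 <- config$d3
  dh <- d1 %/% config$n_heads
  n <- length(disease_vocab)
  if (n < 1) stopf("disease vocabulary is empty")
  zdim <- classifier_input_dim(config, mode)
  params <- list(
    E = matrix(stats::rnorm(length(token_vocab) * d2, sd = 0.1),
               length(token_vocab), d2),
    W_enc = glorot(d2, d2), b_enc = numeric(d2),
    W_proj = glorot(d1, d2), b_proj = numeric(d1),
    gat = lapply(seq_len(config$n_layers), function(l)
      lapply(seq_len(config$n_heads), function(h)
        list(W = glorot(dh, d1), a = stats::rnorm(2 * dh, sd = sqrt(1 / dh))))),
    W1 = glorot(d3, d2), W2 = glorot(d3, d1), v = stats::rnorm(d3, sd = sqrt(1 / d3)),
    Wc = glorot(n, zdim), bc = numeric(n)
  )
  structure(list(params = params, config = config, mode = mode,
                 token_vocab = token_vocab, disease_vocab = disease_vocab,
                 distill_config = distill_config),
            class = "kiddi_model")
}

classifier_input_dim <- function(config, mode) {
  switch(mode,
         full = , sre_knowledge = , de_knowledge = ,
         sre_linear = , de_linear = config$d1 + config$d2,
         knowledge_only = config$d1,
         sre_only = , de_only = config$d2)
}

mode_uses_gat <- function(mode)
  mode %in% c("full", "knowledge_only", "sre_knowledge", "de_knowledge")
mode_uses_linear <- function(mode) mode %in% c("sre_linear", "de_linear")
mode_text_kind <- function(mode)
  switch(mode, full = "attention",
         sre_only = , sre_linear = , sre_knowledge = "sre",
         de_only = , de_linear = , de_knowledge = "de",
         knowledge_only = "none")

# ---- GAT layer --------------------------------------------------------------

gat_layer_fwd <- function(H, adj, layer_params, slope, dropout,
                          training = FALSE) {
  n <- nrow(H)
  outs <- vector("list", length(layer_params))
  caches <- vector("list", length(layer_params))
  for (h in seq_along(layer_params)) {
    W <- layer_params[[h]]$W
    a <- layer_params[[h]]$a
    dh <- nrow(W)
    Z <- H %*% t(W)
    f <- drop(Z %*% a[seq_len(dh)])
    g <- drop(Z %*% a[dh + seq_len(dh)])
    Mraw <- outer(f, rep(1, n)) + outer(rep(1, n), g)
    Ml <- leaky(Mraw, slope)
    shift <- apply(ifelse(adj, Ml, -Inf), 1, max)
    Mexp <- exp(Ml - shift)
    Mexp[!adj] <- 0
    A <- Mexp / rowSums(Mexp)
    D <- NULL
    Atil <- A
    if (training && dropout > 0) {
      keep <- matrix(stats::runif(n * n) >= dropout, n, n)
      D <- matrix(0, n, n)
      D[adj & keep] <- 1 / (1 - dropout)
      Atil <- A * D
    }
    outs[[h]] <- Atil %*% Z
    caches[[h]] <- list(Z = Z, Mraw = Mraw, A = A, D = D, Atil = Atil)
  }
  P <- do.call(cbind, outs)
  list(H = leaky(P, slope), P = P, heads = caches, H_in = H)
}

gat_layer_bwd <- function(dH_out, cache, layer_params, adj, slope) {
  dP <- dH_out * dleaky(cache$P, slope)
  n <- nrow(dP)
  dH_in <- matrix(0, n, ncol(cache$H_in))
  grads <- vector("list", length(layer_params))
  col0 <- 0L
  for (h in seq_along(layer_params)) {
    W <- layer_params[[h]]$W
    a <- layer_params[[h]]$a
    dh <- nrow(W)
    hc <- cache$heads[[h]]
    dO <- dP[, col0 + seq_len(dh), drop = FALSE]
    col0 <- col0 + dh
    dAtil <- dO %*% t(hc$Z)
    dAtil[!adj] <- 0
    dZ <- t(hc$Atil) %*% dO
    dA <- if (is.null(hc$D)) dAtil else dAtil * hc$D
    rs <- rowSums(dA * hc$A)
    dMl <- hc$A * (dA - rs)          # rs recycles down rows: row-wise shift
    dMraw <- dMl * dleaky(hc$Mraw, slope)
    df <- rowSums(dMraw)
    dg <- colSums(dMraw)
    dZ <- dZ + outer(df, a[seq_len(dh)]) + outer(dg, a[dh + seq_len(dh)])
    dH_in <- dH_in + dZ %*% W
    grads[[h]] <- list(W = t(dZ) %*% cache$H_in,
                       a = c(drop(t(hc$Z) %*% df), drop(t(hc$Z) %*% dg)))
  }
  list(dH = dH_in, grads = grads)
}

#' Apply one graph-attention layer
#'
#' Per head: projected features `Z = H W'`, attention logits
#' `LeakyReLU(a . [z_i || z_j])` over the first-hop neighborhood (with
#' self-loops), row-softmax attention weights, attention-weighted sums;
#' heads are concatenated and a LeakyReLU is applied. Dropout hits the
#' attention coefficients only, and only when `training = TRUE`.
#'
#' @param features Node x d1 feature matrix.
#' @param adjacency Logical node x node adjacency matrix including
#'   self-loops (see [jg_adjacency()]).
#' @param layer_params List of per-head parameter lists `list(W, a)` (one
#'   layer of `init_model()`'s `params$gat`).
#' @param leaky_slope LeakyReLU negative slope.
#' @param dropout Attention dropout rate.
#' @param training Whether dropout is active.
#' @return Updated node x d1 feature matrix.
#' @export
gat_layer <- function(features, adjacency, layer_params, leaky_slope = 0.2,
                      dropout = 0, training = FALSE) {
  stopifnot(nrow(features) == nrow(adjacency), nrow(adjacency) == ncol(adjacency))
  gat_layer_fwd(features, adjacency, layer_params, leaky_slope, dropout,
                training)$H
}

#' Mean-pool node features into a graph embedding
#'
#' Arithmetic mean over all nodes (dialog node included); permutation
#' invariant over node order.
#'
#' @param features Node x d1 feature matrix with at least one row.
#' @return Numeric vector of width d1.
#' @export
mean_pool <- function(features) {
  if (!is.matrix(features) || nrow(features) < 1)
    stopf("mean_pool requires a feature matrix with at least one node")
  colMeans(features)
}

# ---- additive attention -----------------------------------------------------

att_fwd <- function(s, h1, h2, params) {
  u1 <- drop(params$W1 %*% h1) + drop(params$W2 %*% s)
  u2 <- drop(params$W1 %*% h2) + drop(params$W2 %*% s)
  t1 <- tanh(u1)
  t2 <- tanh(u2)
  e <- c(sum(params$v * t1), sum(params$v * t2))
  alpha <- softmax_vec(e)
  list(context = alpha[1] * h1 + alpha[2] * h2, alpha = alpha, e = e,
       t1 = t1, t2 = t2)
}

att_bwd <- function(dcontext, cache, params, s, h1, h2) {
  alpha <- cache$alpha
  dh1 <- alpha[1] * dcontext
  dh2 <- alpha[2] * dcontext
  dalpha <- c(sum(dcontext * h1), sum(dcontext * h2))
  de <- alpha * (dalpha - sum(dalpha * alpha))
  dv <- de[1] * cache$t1 + de[2] * cache$t2
  du1 <- de[1] * params$v * (1 - cache$t1^2)
  du2 <- de[2] * params$v * (1 - cache$t2^2)
  dW1 <- outer(du1, h1) + outer(du2, h2)
  dW2 <- outer(du1 + du2, s)
  dh1 <- dh1 + drop(crossprod(params$W1, du1))
  dh2 <- dh2 + drop(crossprod(params$W1, du2))
  ds <- drop(crossprod(params$W2, du1 + du2))
  list(dh1 = dh1, dh2 = dh2, ds = ds, dW1 = dW1, dW2 = dW2, dv = dv)
}

#' Additive attention over self-report and dialogue encodings
#'
#' Scores `e_i = v' tanh(W1 h_i + W2 s)` with the graph embedding `s` as
#' query and the self-report (`h1`) and dialogue (`h2`) encodings as
#' values; `alpha = softmax(e)`; `context = alpha_1 h1 + alpha_2 h2`. The
#' attention weights are returned for inspection (which channel the model
#' trusted for a given case).
#'
#' @param s Graph embedding, width d1.
#' @param h1,h2 Self-report and dialogue encodings, width d2.
#' @param params List with `W1` (d3 x d2), `W2` (d3 x d1), `v` (d3).
#' @return List with `context` (width d2), `alpha` (the two weights,
#'   summing to 1) and `scores` (the raw `e`).
#' @export
additive_attention <- function(s, h1, h2, params) {
  out <- att_fwd(s, h1, h2, params)
  list(context = out$context, alpha = out$alpha, scores = out$e)
}

#' Softmax disease classifier
#'
#' `probs = softmax(W [s; context] + b)`. Entries are positive and sum to
#' one; the prediction is the argmax with ties broken by the lowest class
#' index.
#'
#' @param s Graph embedding (or, in reduced wirings, whatever fills the
#'   knowledge slot); may be `NULL`.
#' @param context Attended text encoding; may be `NULL`.
#' @param params List with `Wc` (n x input width) and `bc` (n).
#' @return Named probability vector over diseases (names taken from
#'   `rownames(params$Wc)` when present).
#' @export
classify <- function(s, context, params) {
  z <- c(s, context)
  if (length(z) != ncol(params$Wc))
    stopf("classifier input width %d does not match parameters (%d)",
          length(z), ncol(params$Wc))
  p <- softmax_vec(drop(params$Wc %*% z) + params$bc)
  names(p) <- rownames(params$Wc)
  p
}

#' Categorical cross-entropy loss
#'
#' `L = -sum_i log p_i(y_i)` summed over the batch; predicted probabilities
#' are clamped at 1e-12 inside the log for stability.
#'
#' @param predicted Probability matrix (examples x classes) or a single
#'   probability vector.
#' @param labels Integer class indices (length = number of examples).
#' @return Non-negative scalar.
#' @export
cross_entropy_loss <- function(predicted, labels) {
  if (is.null(dim(predicted))) predicted <- matrix(predicted, nrow = 1)
  stopifnot(nrow(predicted) == length(labels))
  p <- predicted[cbind(seq_along(labels), as.integer(labels))]
  -sum(log(pmax(p, 1e-12)))
}

# ---- full forward pass ------------------------------------------------------

prepare_example <- function(dialogue, kg, model) {
  cfg <- model$config
  dcfg <- model$distill_config
  lexicon <- if (dcfg$symptom_source == "learned_tagger") kg$symptoms else NULL
  symptoms <- extract_symptoms(dialogue, dcfg, lexicon = lexicon)
  jg <- build_joint_graph(kg, symptoms, dcfg)
  node_ids <- lapply(seq_len(nrow(jg$nodes)), function(k) {
    if (jg$nodes$type[k] == "dialog") return(NULL)
    tokens_to_ids(tokenize_text(jg$nodes$name[k]), model$token_vocab)
  })
  list(
    id = dialogue$id,
    sr_ids = tokens_to_ids(serialize_self_report(dialogue, cfg), model$token_vocab),
    dlg_ids = tokens_to_ids(serialize_dialogue(dialogue, cfg), model$token_vocab),
    label = match(dialogue$disease, model$disease_vocab),
    jg = jg, adj = jg_adjacency(jg), node_ids = node_ids
  )
}

forward_example <- function(ex, model, training = FALSE) {
  params <- model$params
  cfg <- model$config
  mode <- model$mode
  use_gat <- mode_uses_gat(mode)
  use_linear <- mode_uses_linear(mode)
  text_kind <- mode_text_kind(mode)
  need_S <- text_kind %in% c("attention", "sre")
  need_C <- text_kind %in% c("attention", "de") || use_gat

  S_e <- if (need_S) encode_ids(ex$sr_ids, params)
  C_e <- if (need_C) encode_ids(ex$dlg_ids, params)

  ent_enc <- NULL
  ent_feat <- NULL
  n_nodes <- nrow(ex$jg$nodes)
  if (use_gat || use_linear) {
    ent_idx <- which(ex$jg$nodes$type != "dialog")
    ent_enc <- lapply(ent_idx, function(k) encode_ids(ex$node_ids[[k]], params))
    ent_feat <- lapply(ent_enc, function(e)
      drop(params$W_proj %*% e$v) + params$b_proj)
  }

  s_vec <- NULL
  layers <- NULL
  kvec <- NULL
  if (use_gat) {
    H <- matrix(0, n_nodes, cfg$d1)
    H[1, ] <- drop(params$W_proj %*% C_e$v) + params$b_proj
    ent_idx <- which(ex$jg$nodes$type != "dialog")
    for (j in seq_along(ent_idx)) H[ent_idx[j], ] <- ent_feat[[j]]
    layers <- vector("list", cfg$n_layers)
    Hl <- H
    for (l in seq_len(cfg$n_layers)) {
      layers[[l]] <- gat_layer_fwd(Hl, ex$adj, params$gat[[l]], cfg$leaky_slope,
                                   cfg$dropout, training)
      Hl <- layers[[l]]$H
    }
    s_vec <- colMeans(Hl)
    H0 <- H
  } else if (use_linear) {
    kvec <- if (length(ent_feat)) Reduce(`+`, ent_feat) / length(ent_feat)
            else numeric(cfg$d1)
  }

  att <- NULL
  text_vec <- switch(text_kind,
    attention = {
      att <- att_fwd(s_vec, S_e$v, C_e$v, params)
      att$context
    },
    sre = S_e$v,
    de = C_e$v,
    none = NULL)

  kpart <- if (use_gat) s_vec else if (use_linear) kvec else NULL
  z <- c(kpart, text_vec)
  logits <- drop(params$Wc %*% z) + params$bc
  probs <- softmax_vec(logits)
  loss <- if (is.na(ex$label)) NA_real_ else -log(max(probs[ex$label], 1e-12))

  list(probs = probs, loss = loss, alpha = att$alpha, s = s_vec, kvec = kvec,
       z = z, att = att, S_e = S_e, C_e = C_e, ent_enc = ent_enc,
       ent_feat = ent_feat, layers = layers,
       H0 = if (use_gat) H0 else NULL,
       text_kind = text_kind, use_gat = use_gat, use_linear = use_linear)
}

#' Run the full diagnosis pipeline on one dialogue
#'
#' Serializes and encodes the self-report and dialogue, resolves the
#' symptom set, builds and filters the joint graph, applies the GAT stack,
#' mean-pools the graph embedding, fuses channels per the model's wiring
#' mode, and classifies. Deterministic given parameters (dropout off).
#'
#' @param dialogue A `kiddi_dialogue`.
#' @param kg A `kiddi_kg`.
#' @param model A `kiddi_model` (from [init_model()] or a trained
#'   checkpoint's `$model`).
#' @param training Whether attention dropout is active.
#' @return List: `probs` (named probability vector over diseases),
#'   `prediction` (disease name), `alpha` (additive-attention weights, or
#'   `NULL` for wirings without the fusion layer), `graph_embedding`.
#' @export
forward <- function(dialogue, kg, model, training = FALSE) {
  ex <- prepare_example(dialogue, kg, model)
  fwd <- forward_example(ex, model, training = training)
  probs <- fwd$probs
  names(probs) <- model$disease_vocab
  list(probs = probs,
       prediction = model$disease_vocab[[which.max(probs)]],
       alpha = fwd$alpha,
       graph_embedding = fwd$s)
}
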
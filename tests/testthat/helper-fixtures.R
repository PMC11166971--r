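# Shared fixtures: tiny hand-built corpora and a desk-scale model
# configuration used across test files.

# A two-dialogue corpus with known counts, built by hand.
tiny_corpus <- function() {
  d1 <- dialogue("d1", "flu", list(
    utterance("patient", "I have fever and cough.", intent = "Symptom",
              symptoms = c("fever", "cough")),
    utterance("doctor", "Do you have a headache?", symptoms = "headache"),
    utterance("patient", "Yes I do.", intent = "Affirmative")
  ))
  d2 <- dialogue("d2", "cold", list(
    utterance("patient", "I have a cough.", intent = "Symptom",
              symptoms = "cough"),
    utterance("doctor", "Any fever?", symptoms = "fever"),
    utterance("patient", "No, not really.")
  ))
  corpus(list(d1, d2))
}

# Small model configuration keeping desk-scale training in seconds.
small_model_config <- function(...) {
  model_config(d2 = 32L, d1 = 24L, d3 = 8L, n_layers = 2L, n_heads = 3L,
               dropout = 0.5, max_sequence_length = 256L, ...)
}

small_train_config <- function(epochs = 6L, seed = 0L, ...) {
  train_config(epochs = epochs, learning_rate = 3e-3, seed = seed, ...)
}

quick_corpus <- function(seed = 0L, n_dialogues = 100L, n_diseases = 5L,
                         n_symptoms = 20L, ...) {
  generate_corpus(generator_config(n_diseases = n_diseases,
                                   n_symptoms = n_symptoms,
                                   n_dialogues = n_dialogues, seed = seed, ...))
}

# Random small joint-graph topology + features for GAT tests.
random_graph_case <- function(seed, max_nodes = 6L, d1 = 6L) {
  set.seed(seed)
  n <- sample(1:max_nodes, 1)
  adj <- diag(n) > 0
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (stats::runif(1) < 0.5) adj[i, j] <- adj[j, i] <- TRUE
    }
  }
  H <- matrix(stats::rnorm(n * d1), n, d1)
  list(adj = adj, H = H, n = n)
}

random_gat_params <- function(seed, n_heads, d1, dh = d1 %/% n_heads) {
  set.seed(seed + 1000L)
  lapply(seq_len(n_heads), function(h)
    list(W = matrix(stats::rnorm(dh * d1), dh, d1),
         a = stats::rnorm(2 * dh)))
}

# Independent nested-loop oracle for the knowledge graph: literal
# evaluation of the sf-idf and co-occurrence formulas, one pair at a time.
kg_oracle <- function(corp) {
  S <- corp$symptom_vocab
  D <- corp$disease_vocab
  sets <- lapply(corp$dialogues, extract_symptoms)
  labs <- vapply(corp$dialogues, function(d) d$disease, character(1))
  n_sd <- matrix(0, length(S), length(D), dimnames = list(S, D))
  for (s in S) for (d in D) {
    for (i in seq_along(sets)) {
      if (labs[i] == d && s %in% sets[[i]]) n_sd[s, d] <- n_sd[s, d] + 1
    }
  }
  n_ss <- matrix(0, length(S), length(S), dimnames = list(S, S))
  for (a in S) for (b in S) {
    if (a == b) next
    for (i in seq_along(sets)) {
      if (a %in% sets[[i]] && b %in% sets[[i]]) n_ss[a, b] <- n_ss[a, b] + 1
    }
  }
  sf <- function(s, d) if (sum(n_sd[, d]) == 0) 0 else n_sd[s, d] / sum(n_sd[, d])
  idf <- function(s) log(length(D) / sum(n_sd[s, ] > 0))
  ss <- function(a, b) n_ss[a, b] / sum(n_ss[a, ])
  list(n_sd = n_sd, n_ss = n_ss, sf = sf, idf = idf, ss = ss)
}

# Literal per-node GAT oracle: evaluates the attention equations with
# nested loops, independently of the package's vectorized implementation.
gat_oracle <- function(H, adj, layer_params, slope) {
  n <- nrow(H)
  outs <- list()
  for (hp in layer_params) {
    W <- hp$W
    a <- hp$a
    O <- matrix(0, n, nrow(W))
    for (i in seq_len(n)) {
      Ni <- which(adj[i, ])
      scores <- numeric(length(Ni))
      for (k in seq_along(Ni)) {
        zz <- c(W %*% H[i, ], W %*% H[Ni[k], ])
        s <- sum(a * zz)
        scores[k] <- ifelse(s > 0, s, slope * s)
      }
      alpha <- exp(scores - max(scores))
      alpha <- alpha / sum(alpha)
      acc <- numeric(nrow(W))
      for (k in seq_along(Ni)) acc <- acc + alpha[k] * drop(W %*% H[Ni[k], ])
      O[i, ] <- acc
    }
    outs[[length(outs) + 1]] <- O
  }
  P <- do.call(cbind, outs)
  ifelse(P > 0, P, slope * P)
}
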
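test_that("a single node with self-loop reduces to LeakyReLU(W h)", {
  d1 <- 4
  params <- random_gat_params(1, n_heads = 1, d1 = d1, dh = d1)
  H <- matrix(rnorm(d1), 1, d1)
  out <- gat_layer(H, matrix(TRUE, 1, 1), params, leaky_slope = 0.2)
  z <- drop(params[[1]]$W %*% H[1, ])
  expect_equal(drop(out), ifelse(z > 0, z, 0.2 * z), tolerance = 1e-12)
})

test_that("gat_layer matches the dense per-node oracle on random graphs", {
  for (seed in 0:99) {
    case <- random_graph_case(seed, max_nodes = 6, d1 = 6)
    n_heads <- if (seed %% 2 == 0) 1L else 2L
    params <- random_gat_params(seed, n_heads = n_heads, d1 = 6)
    got <- gat_layer(case$H, case$adj, params, leaky_slope = 0.2)
    want <- gat_oracle(case$H, case$adj, params, slope = 0.2)
    expect_equal(got, want, tolerance = 1e-6)
  }
})

test_that("attention rows are simplex vectors over the neighborhood", {
  case <- random_graph_case(5, max_nodes = 6, d1 = 6)
  params <- random_gat_params(5, n_heads = 2, d1 = 6)
  fwd <- kiddi:::gat_layer_fwd(case$H, case$adj, params, 0.2, 0, FALSE)
  for (hc in fwd$heads) {
    expect_equal(unname(rowSums(hc$A)), rep(1, case$n), tolerance = 1e-12)
    expect_true(all(hc$A >= 0))
    expect_true(all(hc$A[!case$adj] == 0))
  }
})

test_that("mean_pool averages node features and is permutation invariant", {
  X <- matrix(rnorm(20), 5, 4)
  expect_equal(mean_pool(X), colMeans(X))
  expect_equal(mean_pool(X[sample(5), ]), mean_pool(X))
  x <- rnorm(4)
  expect_equal(mean_pool(rbind(x, x, x)), x, ignore_attr = TRUE)
  expect_equal(mean_pool(rbind(x, -x)), rep(0, 4), ignore_attr = TRUE)
  expect_error(mean_pool(matrix(numeric(), 0, 3)), "at least one node")
})

test_that("additive attention reproduces hand-computed values", {
  # identical values: symmetric scores, alpha = (1/2, 1/2), context = h1
  params <- list(W1 = matrix(rnorm(6), 3, 2), W2 = matrix(rnorm(6), 3, 2),
                 v = rnorm(3))
  h <- c(0.3, -0.7)
  s <- c(0.1, 0.2)
  out <- additive_attention(s, h, h, params)
  expect_equal(out$alpha, c(0.5, 0.5))
  expect_equal(out$context, h)
  expect_equal(sum(out$alpha), 1)

  # fixed tiny weights, worked through by hand:
  # e_1 = tanh(1 + 2) , e_2 = tanh(2 + 2), alpha = softmax(e)
  params1 <- list(W1 = matrix(1, 1, 2), W2 = matrix(1, 1, 2), v = 1)
  out1 <- additive_attention(c(1, 1), c(1, 0), c(0, 2), params1)
  expect_equal(out1$scores, c(0.995054753687, 0.999329299739), tolerance = 1e-10)
  expect_equal(out1$alpha, c(0.498931365114, 0.501068634886), tolerance = 1e-10)
  expect_equal(out1$context, c(0.498931365114, 1.002137269772), tolerance = 1e-10)
})

test_that("classify yields a valid distribution with softmax invariances", {
  params <- list(Wc = matrix(0, 4, 6), bc = numeric(4))
  p <- classify(rnorm(2), rnorm(4), params)
  expect_equal(unname(p), rep(0.25, 4))

  set.seed(1)
  params2 <- list(Wc = matrix(rnorm(24), 4, 6), bc = rnorm(4))
  z_s <- rnorm(2)
  z_c <- rnorm(4)
  p2 <- classify(z_s, z_c, params2)
  expect_equal(sum(p2), 1, tolerance = 1e-6)
  expect_true(all(p2 > 0))
  # adding a constant to every logit leaves the distribution unchanged
  params3 <- params2
  params3$bc <- params2$bc + 5
  expect_equal(classify(z_s, z_c, params3), p2, tolerance = 1e-12)
  expect_error(classify(rnorm(3), z_c, params2), "width")
})

test_that("cross-entropy has its closed-form values and matches a scalar loop", {
  onehot <- diag(3)
  expect_equal(cross_entropy_loss(onehot, 1:3), 0)
  expect_equal(cross_entropy_loss(rep(1 / 7, 7), 3), log(7))
  expect_equal(cross_entropy_loss(rep(1 / 7, 7), 3), 1.945910149055, tolerance = 1e-10)

  set.seed(2)
  m <- 6; n <- 4
  logits <- matrix(rnorm(m * n), m, n)
  probs <- t(apply(logits, 1, function(r) exp(r) / sum(exp(r))))
  labels <- sample(n, m, replace = TRUE)
  loop <- 0
  for (i in 1:m) for (j in 1:n) {
    y <- as.numeric(labels[i] == j)
    loop <- loop - y * log(probs[i, j])
  }
  expect_equal(cross_entropy_loss(probs, labels), loop, tolerance = 1e-12)
  # zero probability at the true label is clamped, not infinite
  expect_true(is.finite(cross_entropy_loss(c(1, 0), 2)))
})

test_that("forward handles the degenerate dialog-node-only graph", {
  gen <- quick_corpus(seed = 1, n_dialogues = 10)
  kg <- build_graph(gen$corpus)
  model <- init_model(small_model_config(), build_token_vocab(gen$corpus),
                      gen$corpus$disease_vocab, mode = "full", seed = 0)
  bare <- dialogue("bare", "dis01", list(utterance("patient", "I feel unwell")))
  out <- forward(bare, kg, model)
  expect_equal(sum(out$probs), 1, tolerance = 1e-6)
  expect_true(all(out$probs > 0))
  expect_length(out$graph_embedding, small_model_config()$d1)
})

test_that("forward is deterministic given parameters with dropout off", {
  gen <- quick_corpus(seed = 1, n_dialogues = 10)
  kg <- build_graph(gen$corpus)
  model <- init_model(small_model_config(), build_token_vocab(gen$corpus),
                      gen$corpus$disease_vocab, mode = "full", seed = 0)
  d <- gen$corpus$dialogues[[1]]
  expect_identical(forward(d, kg, model), forward(d, kg, model))
  expect_equal(sum(forward(d, kg, model)$alpha), 1, tolerance = 1e-12)
})

test_that("analytic gradients match finite differences in every wiring mode", {
  gen <- quick_corpus(seed = 3, n_dialogues = 12, n_diseases = 4,
                      n_symptoms = 16)
  kg <- build_graph(gen$corpus)
  mc <- model_config(d2 = 10, d1 = 6, d3 = 4, n_layers = 2, n_heads = 2,
                     dropout = 0)
  tv <- build_token_vocab(gen$corpus)

  pluck <- function(x, path) { for (k in path) x <- x[[k]]; x }
  poke <- function(x, path, val) {
    if (length(path) == 1) { x[[path[[1]]]] <- val; return(x) }
    x[[path[[1]]]] <- poke(x[[path[[1]]]], path[-1], val)
    x
  }
  paths <- list(list("E"), list("W_enc"), list("b_enc"), list("W_proj"),
                list("b_proj"), list("gat", 1, 1, "W"), list("gat", 1, 2, "a"),
                list("gat", 2, 1, "W"), list("W1"), list("W2"), list("v"),
                list("Wc"), list("bc"))
  eps <- 1e-6
  set.seed(99)
  for (mode in c("full", "sre_only", "de_only", "knowledge_only",
                 "sre_linear", "de_linear", "sre_knowledge", "de_knowledge")) {
    model <- init_model(mc, tv, gen$corpus$disease_vocab, mode = mode, seed = 7)
    ex <- kiddi:::prepare_example(gen$corpus$dialogues[[2]], kg, model)
    fw <- kiddi:::forward_example(ex, model, training = FALSE)
    gr <- kiddi:::backward_example(ex, fw, model)
    loss_at <- function(params) {
      m2 <- model
      m2$params <- params
      kiddi:::forward_example(ex, m2, training = FALSE)$loss
    }
    for (p in paths) {
      arr <- pluck(model$params, p)
      i <- sample(length(arr), 1)
      up <- arr; up[i] <- up[i] + eps
      dn <- arr; dn[i] <- dn[i] - eps
      num <- (loss_at(poke(model$params, p, up)) -
                loss_at(poke(model$params, p, dn))) / (2 * eps)
      expect_equal(pluck(gr, p)[i], num, tolerance = 1e-4,
                   label = sprintf("grad %s (mode %s)",
                                   paste(unlist(p), collapse = "$"), mode))
    }
  }
})
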